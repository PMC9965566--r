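# Generator profile: mild-to-moderate myopia study arm (SE in (-6, -0.5] D).
# Calibration constants (se/beta/mvd coupling terms) are versioned here,
# not in code.
name: mild_moderate
group: mild_moderate
n_eyes: 110
seed_offset: 2000
grid:
  width_px: 400
  height_px: 400
  pixel_pitch_um: 11.25
covariates:
  se: {mean: 0.63063, sd: 3.40, lower: -6.0, upper: -0.5}
  al: {mean: 24.36, sd: 1.15, se_corr: -0.817}
  age: {mean: 32.30, sd: 12.84, lower: 18.0, upper: 40.0}
  female_prob: 0.2818
quality:
  score_probs: [0.10, 0.20, 0.30, 0.25, 0.15]
zones:
  disc_radius_px: 53
  wobble: {amplitude_px: 5.0, harmonics: 4}
  ppa_beta_area: {mean_mm2: 0.562, se_coef: 0.000112, sdlog: 0.038375, min_mm2: 0.06}
  ppa_alpha:
    presence_prob: 0.35
    area: {mean_mm2: 0.235, sdlog: 0.45, min_mm2: 0.05}
mvd:
  presence_prob: 0.951220
  coupling:
    intercept_log: -2.384959
    log_beta_coef: 1.895780
    al_coef: 0.009634
    age_coef: 0.028563
    sigma_log: 0.037285
  min_region_px: 21
  regions_per_700px: 1.0
  max_regions: 6
  grey: {min: 15, max: 45, pixel_sd: 3}
  alpha:
    presence_prob_given_alpha: 0.63
    area: {mean_mm2: 0.055, sdlog: 0.5}
background: {mean_grey: 150, speckle_sd: 15, correlation_px: 2}
vessels:
  n_trees: 4
  width_px: [4.5, 7.0]
  grey: [210, 250]
  steps: [80, 160]
disc_render: {grey_mean: 80, grey_sd: 6}
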