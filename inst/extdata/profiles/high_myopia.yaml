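# Generator profile: high myopia study arm (SE in [-10, -6] D).
# Calibration constants (se/beta/mvd coupling terms) are versioned here,
# not in code.
name: high_myopia
group: high
n_eyes: 95
seed_offset: 1000
grid:
  width_px: 400
  height_px: 400
  pixel_pitch_um: 11.25
covariates:
  se: {mean: -0.65669, sd: 3.07775, lower: -10.0, upper: -6.0}
  al: {mean: 26.65, sd: 0.88, se_corr: -0.817}
  age: {mean: 36.21, sd: 14.28, lower: 18.0, upper: 40.0}
  female_prob: 0.3368
quality:
  score_probs: [0.10, 0.20, 0.30, 0.25, 0.15]
zones:
  disc_radius_px: 53
  wobble: {amplitude_px: 5.0, harmonics: 4}
  ppa_beta_area: {mean_mm2: 1.221, se_coef: 0.216016, sdlog: 0.331168, min_mm2: 0.06}
  ppa_alpha:
    presence_prob: 0.70
    area: {mean_mm2: 0.336, sdlog: 0.45, min_mm2: 0.05}
mvd:
  presence_prob: 0.951220
  coupling:
    intercept_log: -1.652181
    log_beta_coef: 1.895780
    al_coef: 0.009634
    age_coef: 0.028563
    sigma_log: 0.005863
  min_region_px: 21
  regions_per_700px: 1.0
  max_regions: 6
  grey: {min: 15, max: 45, pixel_sd: 3}
  alpha:
    presence_prob_given_alpha: 0.818
    area: {mean_mm2: 0.068, sdlog: 0.5}
background: {mean_grey: 150, speckle_sd: 15, correlation_px: 2}
vessels:
  n_trees: 4
  width_px: [4.5, 7.0]
  grey: [210, 250]
  steps: [80, 160]
disc_render: {grey_mean: 80, grey_sd: 6}
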