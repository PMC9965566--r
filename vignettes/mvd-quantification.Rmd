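---
title: "Quantifying peripapillary choriocapillaris dropout from en-face OCTA"
author: "mvdquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying peripapillary choriocapillaris dropout from en-face OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvdquant)
```

## The measurement problem

En-face OCTA of the choroid layer below the retinal pigment epithelium
renders perfused choriocapillaris as a bright speckled field. Where flow is
locally absent — microvascular dropout (MvD), also called flow voids — the
image is dark. In myopic eyes these voids concentrate in the zones of
peripapillary atrophy (PPA) around the optic disc: the β-zone adjacent to
the disc (RPE absent) and the α-zone peripheral to it (irregular RPE).

`mvdquant` turns one such image plus zone masks into per-eye quantities and
a cohort analysis. The detection rule is deliberately simple and global:

> an MvD region is a connected set of valid pixels with grey value
> strictly below 50 (8-bit scale) whose pixel count strictly exceeds 20,
> evaluated inside the PPA zones after large vessels have been excluded.

With the default acquisition — a 4.5 × 4.5 mm cube scanned as 400 clusters
per side — one pixel is 11.25 µm on a side, so areas follow by pixel
counting: one pixel = 126.5625 µm², and a 400 × 400 field = 20.25 mm².

## Pipeline stages and their parameters

| parameter | default | unit | role |
|---|---|---|---|
| `pixel_pitch_um` | 11.25 | µm | physical pixel side; only constant linking px to mm² |
| `grey_threshold` | 50 | grey value | dropout rule, strict `<` |
| `min_area_px` | 20 | px | dropout rule, strict `>` |
| `connectivity` | 8 | — | component adjacency (4 available; oracle tests run both) |
| `signal_threshold` | 50 | grey value | flow-density rule, `>=` |
| `vessel_bright_threshold` | 180 | grey value | large-vessel brightness |
| `vessel_min_length_px` / `vessel_min_width_px` | 30 / 4 | px | large-vessel geometry |
| `vessel_elongation_min` | 3 | — | rejects compact bright clusters |

Choices worth spelling out:

* **Strict inequalities.** "Less than 50" and "exceeding 20 pixels" are read
  literally: a pixel at grey 50 is not dark, a 20-px component is not a
  region. Both constants are configuration values, so the closed-boundary
  alternative is one flag away.
* **8-connectivity** is the default because dropout blobs are irregular and
  diagonal contact reads as contiguous in these images; every
  oracle-equivalence test runs both connectivities.
* **Zone clipping before labeling** (default): a dark structure spilling
  out of the PPA masks is measured only inside them. The alternative
  (label first, then intersect) is available as `clipZonesFirst = FALSE`;
  the two differ when one dark component crosses a zone boundary in several
  places.
* **Vessel pixels are invalidated, not inpainted.** Inpainting would
  fabricate grey values that feed an absolute threshold. A consequence the
  tests pin down: an excluded vessel can split one dark structure into two
  regions, each then area-filtered on its own, and growing the vessel mask
  can never increase the measured dropout area.
* **Vessel geometry by moments.** The skeleton length of a bright component
  is estimated as `sqrt(12 * var)` along its principal axis — exact for a
  straight ribbon, adequate for gently curving vessels — and width as
  area/length. This keeps the stage transparent and testable against the
  generator's vessel truth (≥ 95% pixel recovery, no detection farther than
  3 px from a true vessel).
* **Flow density** is reported as a pixel count (plus a normalized
  fraction). The quantity is "area occupied by blood signal": valid zone
  pixels at or above the signal threshold.
* **Grey scale is fixed 8-bit.** Other PNG bit depths are rejected rather
  than rescaled, because rescaling would silently shift the grey-50 rule.
  Multi-channel PNGs are accepted only when the colour channels are
  identical. Zone masks must be exactly {0, 255} and pairwise disjoint;
  overlap is an error, never resolved silently.
* **Coordinates** are (row, column) with origin at the top-left corner,
  1-based as is idiomatic in R.

## Cohort layer

Eyes are grouped by spherical equivalent: SE ≤ −6.0 D is high myopia,
−6.0 < SE ≤ −0.5 D mild-to-moderate; the shared −6.0 D endpoint goes to the
high group, the conventional definition. Quality control retains eyes with
scan quality ≥ 6/10 and no artifact flags (double-vessel pattern, motion,
segmentation errors over more than three lines); each exclusion carries its
reason. Group comparisons use the two-sided Student t-test (Welch
available), correlations the Spearman test with average ranks for ties, and
the regression layer reports both per-predictor simple fits — summarized by
the signed Pearson r and its p-value, which is how such analyses are
commonly printed — and a joint OLS fit of MvD area on age, SE, AL and PPA-β
area. Two-sided tests at α = 0.05 throughout, no multiple-testing
correction, matching the analysis style the pipeline mirrors. Eyes with no
detected dropout contribute 0 mm² to area means and remain in the cohort;
presence is reported separately as prevalence. Eyes are treated as
independent analysis units.

Degenerate inputs are first-class: constant variables yield descriptives
with NA test statistics rather than failures, constant vectors are an
explicit undefined-correlation error (never a silent 0), an empty zone
yields density 0 with a warning flag, and a near-collinear joint design
(condition number above 1e8) attaches a warning.

## The synthetic cohort generator

No public dataset accompanies this kind of study, so the package ships a
generator whose two packaged profiles, `high_myopia` (n = 95) and
`mild_moderate` (n = 110), emulate the image and covariate structure of a
young-adult myopia cohort. Per eye:

* **SE** is drawn from a normal distribution truncated to the group's
  inclusion interval. The underlying parameters are solved so the realized
  (truncated) moments match the group targets (−7.14 ± 0.927 D high,
  −2.51 D mild). Two distributional facts are worth recording: an SD of
  0.927 D is close to the largest any unimodal law can achieve with mean
  −7.14 on [−10, −6], so the realized density is near-flat and tilted
  toward −6 D; and an SD of 2.10 D is arithmetically impossible on an
  interval of width 5.5 (the uniform maximum is 1.59), so the mild profile
  matches the mean and realizes an SD of 1.42 D.
* **AL** is linear in standardized SE (within-group correlation −0.82) with
  Gaussian residuals, giving 26.65 ± 0.88 mm and 24.36 ± 1.15 mm.
* **Age** is a truncated normal on the 18–40-year inclusion window; sex is
  Bernoulli at the group's female fraction.
* **PPA-β area** is lognormal around the group mean (1.221 / 0.562 mm²)
  with an SE term; **PPA-α** is present with group probability and has its
  own lognormal area.
* **Total MvD area**, behind a per-eye presence gate (p = 195/205), is
  **log-linear in PPA-β area** with small AL and age terms and lognormal
  noise, floored at one minimal detectable region (21 px) and capped at 60%
  of the β zone. The pixel budget is split into up to six connected regions
  of ≥ 21 px each.

The log-scale coupling is the package's own design choice: an additive
linear coupling with the mild group's small mean (0.089 mm²) puts
substantial probability below zero, and truncating it distorts exactly the
means and correlations the coupling exists to induce. Log-linear is the
simplest monotone coupling that respects positivity.

Rendering realizes the truth as an image: smoothed white-noise speckle
(mean 150, SD 15, correlation length 2 px — comfortably above the grey-50
threshold so texture alone cannot trigger the detector), a wobbled disc,
the β annulus grown outward from the disc boundary in perturbed-distance
order (hence β is adjacent to the disc and α, grown next in the same
ordering, is peripheral to β at every angle), α as a crescent of workable
radial thickness, straight-ish bright vessel trees (grey 210–250, widths
4.5–7 px) radiating from the disc margin, and dropout regions grown as
random connected blobs of exactly the planned pixel counts, painted last
with grey values in [15, 45] so every planted pixel is below threshold by
construction. Planted regions are kept mutually non-adjacent, so each is
one detected component, and vessels never overwrite dropout — consequently
detection recovers planted totals pixel-for-pixel on vessel-free eyes, and
never exceeds truth with vessels enabled. That exactness is what makes the
generator a usable oracle for the whole pipeline.

### Calibration

The free coupling constants (SE→β slope, β lognormal SDs, the log-β
coefficient, AL and age coefficients, per-group noise SDs, intercepts) are
frozen in `inst/extdata/profiles/*.yaml`, not in code. They were fit by
simulating the covariate-level model — including pixel rounding, floors and
the presence gate, which the image stage then reproduces exactly — and
minimizing squared bias plus sampling variance of the eight cohort
statistics the profiles are meant to reproduce (per-group MvD and β-area
means, prevalence, and the pooled correlations of MvD area with β area, SE
and AL) at the study's own group sizes. Group means are pinned exactly by
the intercepts; the correlations center within ~0.01 of their targets.

Two consequences are documented rather than hidden. First, the printed
group SDs of MvD and β area cannot all hold simultaneously with a pooled
MvD–β correlation of 0.894 under any homogeneous monotone coupling, so the
calibration prioritizes means and correlations and lets group SDs fall out
(the high arm carries most of the β-area spread). Second, with n = 95/110
fixed, the cohort statistics have irreducible sampling noise (SD ≈ 0.025
mm² for the high-arm MvD mean, ≈ 0.04 for the correlations); a single
cohort realization therefore scatters around the calibration targets by a
few percent, which is visible when `scripts/acceptance.R` is run under
different seeds.

### What the generator does and does not emulate

It emulates: covariate moments and their coupling structure, zone geometry
and adjacency, planted dropout with exact ground truth, bright vessel
trees, stationary correlated speckle. It does **not** emulate: physical OCT
speckle statistics, projection or motion artifacts (artifact flags can be
set synthetically but are never rendered), optic-disc tilt,
optical-magnification effects of axial length, or inter-eye correlation
within subjects (one eye per synthetic subject). Passing tests on synthetic
cohorts therefore validate the measurement chain's correctness and
calibration, not the clinical performance of the thresholds on real
scanner output.

## Numerical and testing notes

Determinism: every cohort-level entry point takes an integer seed; per-eye
streams are derived from it, so eye *i* is reproducible in isolation and
written cohorts are byte-identical across runs. Truncated-normal sampling
is inverse-CDF; its moment formulas compute tail masses in whichever tail
keeps floating-point precision. Component labeling is frontier
breadth-first search; the suite checks it against an independently written
stack-based flood fill on random grids (both connectivities) and against
`EBImage::bwlabel` for the 4-connected case. Region ordering is total
(area descending, then centroid row, then column), so outputs are stable.
Problem sizes in the default test run: 200 random 64 × 64 oracle images,
50 vessel-free + 20 vesseled synthetic eyes for recovery, and one full
205-eye cohort for the calibration check.

## Limitations

* The detection rule is a single global threshold; it is the measurement
  being reproduced, not a claim that 50/20 px is optimal for other devices
  or fields of view.
* The vessel stage is a transparent brightness/elongation rule, suitable
  for the generator's vessels and auditable on real data, but it is not a
  tuned vesselness filter; on clinical images its three parameters may need
  adjustment, which is why they are configuration values.
* Zone masks are consumed as given (in practice they come from manual
  contouring); the package does not segment PPA zones from images.
* Densities are pixel counts whose absolute scale depends on the zone size
  and signal threshold; compare them only within a fixed configuration.
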