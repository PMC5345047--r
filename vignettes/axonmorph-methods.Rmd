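---
title: "Methods: automated axon morphometry and cross-assay phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated axon morphometry and cross-assay phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmorph)
```

## Scope

`axonmorph` implements a complete desk-scale phenotyping analysis for
knockout studies of peripheral-nerve myelination: an automated morphometry
engine for brightfield images of p-phenylenediamine-stained nerve
cross-sections (myelin stains dark), per-animal endpoints (axon density,
lumen and myelin sheath areas, g-ratio), behavioral scoring (acoustic
startle and prepulse inhibition, odor habituation, hot plate, balance beam),
densitometric normalization of immunoblot bands, Kaplan–Meier survival
analysis with a Gehan–Breslow generalized Wilcoxon comparison, and
factorial/mixed-design ANOVA with Tukey HSD post-hocs. Because studies of
this kind rarely deposit raw images or colony records, every input class has
a ground-truthed synthetic generator, and the package's correctness claims
are exactly the properties its test suite computes on that synthetic data.

## The segmentation model

A myelinated axon in cross-section is modeled as an annulus: a bright lumen
surrounded by a dark myelin ring on a bright background. `detect_axons()`
composes three stages.

**Background correction** (`preprocess()`). The RGB raster is converted to
luminance (Rec. 601 weights) and a rolling-ball background estimate is
subtracted: a grayscale morphological opening with a non-flat hemispherical
ball (height `sqrt(r^2 - d^2)` gray levels at offset `d`). The opening never
exceeds the input, so the corrected image is non-negative; it is ~0 on flat
background and on structures wider than the ball, and bright exactly where
small bright structures — candidate lumina — sit. The ball radius
(`rolling_ball_radius_px`, default 18) must exceed the largest expected
lumen radius, or large lumina are absorbed into the background estimate;
with the generator's default calibers (lumen radii ≤ 3.5 µm ≈ 15 px at
0.23 µm/px) 18 px leaves a margin. The opening is exact (no shrink/expand
approximation); a brute-force ball-kernel opening on a 64×64 crop is the
test oracle.

**Candidate segmentation** (`segment_candidates()`). The corrected image is
Gaussian-smoothed (`gaussian_sigma_px`, default 1.5) and thresholded; Otsu's
method is the parameter-free default, a fixed threshold can be configured.
Merged candidates are split where the Laplacian of the smoothed image is
strongly positive (`log_split_max`, default 5 gray levels/px²; intensity
saddles between touching lumina respond positively, flat lumen interiors sit
near 0), and the split seeds are grown back over the candidate mask by a
seeded watershed on the smoothed intensity landscape (`EBImage::propagate`).
Pixels are screened in HSI space (bi-cone definitions: I = (R+G+B)/3,
S = 1 − min/I): the stain is achromatic, so candidate pixels with
saturation above `hsi_saturation_max` (default 0.25) are excluded. A uniform
image yields an empty labeling with a warning, never an exception.

**Object filtering** (`filter_objects()`). Candidates are screened in a
fixed order, and every removal is logged with a reason code:

1. `size` — lumen area outside `[min_lumen_area_um2, max_lumen_area_um2]`
   (defaults 1–80 µm²; 1 µm² is below the smallest myelinated calibers, so
   the floor removes noise objects, not axons).
2. `shape` — circularity `4πA/P²` below `min_shape_factor` (default 0.4).
   The perimeter is a Cauchy–Crofton estimate from boundary intercepts in
   four directions, `P = (π/8)(n0 + n90 + (n45+n135)/√2)`, which keeps the
   statistic reproducible bit-exactly; rasterized disks score ≥ 0.97.
3. `intensity` — mean lumen luminance deviating more than
   `max_mean_lumen_intensity_deviation` (default 60 gray levels) from the
   global mean over all candidate lumen pixels.
4. `no_myelin_ring` — the band `ring_width_px` (default 2 px) outside the
   lumen must be covered by myelin-class pixels to at least
   `ring_completeness` (default 0.7). The band must not be wider than the
   thinnest expected sheath (≈ `lumen_radius·(1/g − 1)` px); 2 px suits the
   default caliber distribution.

The myelin class itself is defined on the raw luminance (so thin sheaths are
not washed out by smoothing) as the dark class of a three-class Otsu split —
the luminance histogram of a stained section is trimodal (dark myelin,
intermediate lumen, bright background) and a single Otsu split would land
between background and everything else. Dark pixels inside a lumen label are
reassigned to the ring (candidate labels overrun the blurred lumen/sheath
edge by design of the low threshold), and per-axon myelin areas are measured
by growing the surviving lumen seeds over the myelin mask with the same
seeded watershed, i.e. a constrained morphological reconstruction. On
default-noise synthetic images this keeps both per-axon lumen and myelin
areas within ~1 % of the generating truth on average, and per-axon g-ratios
unbiased to within ±0.01.

The chain contains no randomness: a fixed image and configuration give an
identical object list on every run. Detections whose lumen centroid falls
outside the ROI polygon are dropped and counted in the QC summary.
Coordinates are R-native: `(row, col)`, 1-based, pixel centers at integers;
areas are pixel counts times `pixel_size_um²`.

## Morphometry endpoints

Diameters derive from areas under the circularity assumption,
`d = 2·sqrt(A/π)` (`circular_equivalent_diameter()`), and the g-ratio is the
inner/outer diameter ratio, algebraically
`g = sqrt(A_inner / (A_inner + A_myelin))` (`axon_g_ratio()`). Both are
exact arithmetic contracts, tested against algebraic round-trips at 1e-12
relative error.

`summarize_animal()` reduces 1–3 sections per animal to a single record:
per-section means are computed first and then averaged with **equal weight**
(sections are treated as technical replicates; axon-count weighting would
let one well-sampled section dominate). The primary per-animal g-ratio is
the **mean of per-axon g-ratios**, the most literal reading of an "average
g-ratio"; the alternative ratio of circular-equivalent diameters of the mean
areas (`g_ratio_of_means = sqrt(mean A_inner / mean A_outer)`) is exported
alongside for sensitivity checks — the two differ only by a Jensen gap.
A total sample below `min_axons` (default 4000) sets a warning flag but
never excludes the animal: the threshold is a sampling target, not a
validity bound. The per-animal record is the unit of observation for all
downstream statistics.

`match_to_ground_truth()` scores detections against generator truth by
one-to-one greedy matching (detection centroid inside the true lumen circle,
nearest center first), reporting recall, precision and per-matched-axon area
errors; precision is undefined (`NULL`) when there are no detections.

## Synthetic data: what it emulates, and what it does not

`generate_nerve_image()` places non-overlapping concentric-circle annuli by
rejection sampling (outer circles separated by at least `min_gap_px`; a hard
cap of 10,000 failed placements per axon raises an explicit "unplaceable
density" error rather than silently under-filling). Ground-truth areas are
analytic (`πr²`, scaled), not rasterized counts. Defaults model a
whole-slide scan at 0.23 µm/px: lumen radii lognormal with mean 1.5 µm and
sd 0.5 µm, truncated to [0.7, 3.5] µm (myelinated-fiber calibers; the upper
bound also keeps every annulus well under the background-correction ball);
g-ratios normal 0.65 ± 0.05 truncated to (0,1); gray levels 70 (myelin),
165 (lumen), 195 (background); i.i.d. Gaussian channel noise with sd 8.
Published studies of this kind do not report per-axon size distributions,
so these are the package's own realism choices, fixed here.

The generator deliberately omits several features of real sections: ellipse
or irregular profiles (profiles are circles, matching the circularity
assumption of the diameter formula), unmyelinated axons, Schwann-cell nuclei
and vascular structures, focus gradients, and stain variability beyond
global Gaussian noise. Passing the recall/precision suite therefore
demonstrates that the operator chain is implemented correctly and is
well-calibrated for annular geometry — not that it would reach the same
recall on arbitrary real-world histology.

Behavioral generators mirror the standard session designs: startle sessions
with 4-trial pulse-alone blocks at start and end (flagged and excluded from
baseline), 16 middle-block pulse-alone trials and 10 trials per prepulse
level in pseudorandom order, reading vectors of 65 or 100 one-millisecond
samples, and per-level inhibition weights k/L so the top level carries the
programmed effect exactly; odor sessions with the A,A,A,B,B,B,C schedule,
multiplicative within-odor habituation and proportional dishabituation
recovery at odor switches, plus a configurable fraction of non-engaged
animals (≤ 2 investigations) to exercise the exclusion rule. Survival
cohorts draw ages from a piecewise-exponential hazard with its change-point
fixed at day 29 — the same cut the post-weaning subgroup analysis uses — so
the simulator is aligned with the analysis it feeds. All generators route
their randomness through one per-call seed; identical parameters and seed
give bit-identical output.

## Behavioral and survival scoring

`percent_ppi()` computes `%PPI = 100·(PA − PP)/PA` per prepulse level, with
`PA` the mean startle magnitude (mean of the reading vector) over the 16
middle-block pulse-alone trials only — the start/end blocks measure startle
habituation, not baseline. The formula is the field-standard definition;
negative values (facilitation) are reported unclipped, and a zero baseline
yields `NA` with a warning. `odor_scores()` pairs mean(T1,T4) against
mean(T3,T6) for habituation and mean(T3,T6) against mean(T4,T7) for
dishabituation, excluding sessions with two or fewer investigations.
`hotplate_latency()` clips at the 30 s cutoff then averages up to three
trials; `footslip_score()` averages slip counts per 80 cm traverse;
`densitometry_normalize()` divides target by loading band and rescales so
the control-genotype mean is exactly 1.

`kaplan_meier()` is the product-limit estimator (via `survival::survfit`)
with the standard tie convention — deaths precede censorings, so an animal
censored at an age is still at risk for that age's deaths. The group
comparison is the **Gehan–Breslow** generalized Wilcoxon: a weighted
log-rank with weight equal to the number at risk, emphasizing early deaths.
"Generalized Wilcoxon" has variants (Peto–Prentice, Tarone–Ware); Gehan is
the default reading of the phrase, is stated in the output metadata, and no
installed package provides exactly this weight (`survival::survdiff` with
`rho = 1` is Peto–Peto), so the statistic is computed directly from the
hypergeometric terms; the singular case falls back to a generalized inverse
with a warning. `postwean_subset()` drops all records below 29 days — deaths
and censorings alike — without shifting the remaining ages. Left truncation
is not modeled: animals are observed from birth, as in a breeding-colony
database.

## Group statistics

`two_way_anova()` computes Type-II sums of squares by explicit model
comparison of `lm` fits — on balanced designs this coincides with the
classical partition, on unbalanced designs it is the conventional choice
when interactions are weak; a vanishing residual yields an infinite F rather
than an error, and empty cells raise an error naming the cells.
`mixed_anova()` is the univariate repeated-measures decomposition (between
effect against the subject-within-group stratum; within and interaction
against the subject×within residual), chosen over a likelihood-based mixed
model because it reproduces the classical df bookkeeping — between
`F(g−1, n−g)`, within `F(k−1, (k−1)(n−g))` — that studies of this design
report. Sphericity is assumed; no Greenhouse–Geisser correction is applied
(none is silently applied anywhere). `tukey_hsd()` reports
studentized-range-adjusted p-values (via `stats::TukeyHSD`) plus the
Tukey–Kramer `q` statistic, flagging the zero-variance degenerate case.

## Numerical choices and edge cases

* Thresholds: Otsu default for candidates; three-class Otsu (exhaustive
  256-bin search) for the stain class; both deterministic.
* Watershed/propagate tie-breaks are those of `EBImage::propagate`
  (deterministic raster order); seeds come from connected components after
  the Laplacian split.
* Shape factor is capped at 1 (Crofton perimeters of near-circular pixel
  sets can slightly undershoot).
* Filtering is monotone: tightening any single bound never increases the
  number of survivors (each criterion is evaluated independently).
* `rtrunc` rejection sampling guards against degenerate truncation windows;
  zero-sd distributions degenerate to their mean exactly, which the tests
  use to pin radii to integer pixel values.
* Gehan variance terms skip event times with a single animal at risk
  (0/0 hypergeometric), and χ² is floored at 0 against rounding.

## Problem sizes used by the test suite

The acceptance-grade checks run at sizes chosen to finish comfortably on one
CPU: detection recall on five 2048² images with ~750 axons each (the
full-scale study condition); per-animal g recovery on cohorts of 7+7 animals
with one 512² section (~60 axons) each; ANOVA detection power on 100
replicate cohorts at 256²/~24 axons per animal (per-animal standard error of
the mean g at that sampling is ≈ 0.01, an order below the 0.10 group
effect); survival calibration on 1000 replicate cohorts of 200 animals per
genotype; formula round-trips on 1000 random draws. The methods themselves
are size-agnostic.

## Known limitations

* The morphometry engine targets transverse brightfield sections; electron
  micrographs, longitudinal sections and fluorescence are out of scope.
* Only myelinated axons are in the data model: a lumen without a closed
  dark ring is rejected by design, matching per-myelinated-axon endpoints.
* The segmentation defaults are calibrated for ~0.23 µm/px scans; other
  magnifications need rescaled radii, sigmas and area bounds.
* The extreme-responder balancing re-analysis sometimes applied to startle
  data is not implemented: its trimming rule is underdetermined, and no
  stable contract could be tested.
* Litter structure, maternal effects and health-alert euthanasia models are
  not part of the survival simulator.
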