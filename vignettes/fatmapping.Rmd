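---
title: "Radial fat-mapping of paraspinal muscles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial fat-mapping of paraspinal muscles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatmapr)
```

## The problem

Conventional summaries of paraspinal muscle quality report a single
overall mean fat-infiltration percentage (FI%) per muscle, discarding
where within the muscle the fat accumulates. Because the multifidus,
erector spinae and psoas are structured radially around the spinal
motion segment — with the shortest, most stability-critical multifidus
fascicles lying closest to the disc — the *radial* distribution of FI
carries mechanistic information that a single mean cannot.

`fatmapr` quantifies that distribution. For each muscle it builds a
"fat-map": the mean FI% in concentric one-pixel annuli centred on the
approximate centre of rotation (CoR) of the L4L5 motion segment,
smoothed and normalized to 0–100% of the muscle's radial width, and
compares groups of such curves with one-dimensional statistical
parametric mapping (SPM).

## The procedure

1. **CoR localization.** The CoR is approximated at the centre of the
   posterior quarter of the disc's mid-sagittal anteroposterior
   diameter, i.e. at `posterior + 0.125 * (anterior - posterior)`. The
   two disc endpoints are supplied per subject in the cohort CSV; the
   construction is affine, so it is equivariant under rotation and
   translation of the image.
2. **Annulus means.** Every mask pixel whose centre lies at distance
   `d` from the CoR is assigned to annulus `floor(d)` — half-open bins
   `[k, k+1)` in pixel units, so annuli are exactly one pixel wide and
   partition the mask. The annulus value is the arithmetic mean FI%
   over its non-missing pixels. Pixels marked missing (no signal,
   outside the body) are excluded from every mean rather than treated
   as zeros, which would bias annuli that graze the body outline.
3. **Smoothing.** A three-point moving average; the innermost and
   outermost occupied annuli use the one-sided two-point mean. Annuli
   interior to the occupied span that contain no muscle pixel are first
   filled by linear interpolation between their nearest occupied
   neighbours: the SPM stage needs a gap-free continuum, and a narrow
   muscle can miss an annulus entirely at oblique angles.
4. **Distance normalization.** The smoothed curve is linearly
   interpolated onto `n_nodes` equally spaced nodes spanning the
   occupied annulus range, so that node 0 is the innermost occupied
   annulus and node 100 the outermost. Endpoint values are preserved
   exactly. The default `n_nodes = 101` gives one node per percent of
   radial width, a natural resolution for curves that are reported in
   percent.
5. **Group inference.** At every node the standard pooled-variance
   two-sample t statistic is computed, giving the field SPM{t}. The
   residual curves (subject minus group mean) estimate the field's
   smoothness, expressed as a full width at half maximum (FWHM) in
   nodes; the critical threshold t\* is the random-field-theory (RFT)
   value a smooth null field of that FWHM exceeds anywhere with
   probability alpha. Contiguous supra-threshold runs are reported as
   clusters with sub-node interpolated spans and cluster-level
   p-values.

## The statistical model

For `Q` nodes and residual smoothness `FWHM`, the field carries
`resels = (Q - 1) / FWHM` resolution elements. The threshold solves

```
alpha = 1 - exp(-(EC0(u) + resels * EC1(u)))
EC0(u) = P(T_df > u)
EC1(u) = sqrt(4 ln 2) / (2 pi) * (1 + u^2/df)^(-(df-1)/2)
```

the expected-Euler-characteristic approximation to the exceedance
probability of the field maximum, solved numerically to an alpha
residual below 1e-8. Two notes on this form:

* As `resels -> 0` the threshold tends to the t quantile at
  `-log(1 - alpha)` (0.0513 for alpha 0.05), about 0.8% below the
  scalar critical value `qt(1 - alpha, df)`. This is a property of the
  exponential (Poisson-clumping) form, not a defect; the package's
  limit test asserts agreement with the scalar value to 1% for this
  reason.
* Sidedness defaults to two-sided: the threshold is computed at
  `alpha / 2` per tail and positive and negative clusters are reported
  with their sign. One-sided variants are available.

Smoothness is estimated from the residuals by the standard gradient
ratio: at each node, resels-per-node `= sqrt(sum(dR^2) / sum(R^2) /
(4 ln 2))` with central-difference gradients (one-sided at the ends),
and `FWHM` is the reciprocal of the node-wise mean, clamped to
`[1, 10 Q]`. Exactly constant residuals have no finite smoothness and
raise a distinct error rather than returning the clamp value.

Cluster p-values use the expected-extent exponential approximation:
with `m` the expected cluster count at `u` and `n0` the expected
cluster extent, a cluster of `k` node units has
`p = 1 - exp(-m * exp(-k / n0))`, doubled and capped at 1 in two-sided
mode. Set-level inference is not implemented. Comparisons across
muscles or stratifications are deliberately *not* corrected for
multiplicity — each comparison is tested at its own alpha, matching
the per-comparison convention of SPM analyses in this field.

The whole-muscle overall mean FI% is compared with a hand-rolled
pooled-variance unpaired t-test (it is part of the package's tested
surface; `stats::t.test(var.equal = TRUE)` serves as the independent
oracle in the test suite).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_nodes` | 101 | nodes | one node per percent of radial width |
| `alpha` | 0.05 | — | conventional family-wise level |
| `deep_cut` / `superficial_cut` | 33.3 / 66.7 | % width | equal tertiles; the deep/intermediate/superficial split is qualitative in the literature, so the cuts are configurable |
| Pfirrmann threshold | 3 | grade | high (>3) vs low (≤3) degeneration |
| VAS threshold | 6 | score | high (>6) vs low (≤6) pain |
| `sided` | two-sided | — | directional excesses are reported via cluster signs |

Left/right muscles segmented as separate masks are analysed separately
and their normalized curves averaged per subject before group
inference; a merged mask is analysed as one region. Pooling pixels
across sides would weight the wider side more, whereas averaging
curves treats the two sides as repeated measurements of one radial
pattern.

## The phantom generator

`generate_cohort()` builds a fully synthetic cohort with analytic
ground truth. Muscles are annular sectors around a fixed CoR, so every
pixel's normalized radial depth has a closed form. Each subject's true
curve — a baseline (superficial plateau plus Gaussian deep peak), plus
a Gaussian effect bump for patients in the target muscle, plus smooth
subject-specific noise generated in the depth domain — is painted
piecewise-constant onto the one-pixel radial shells. Two design
choices make the generator an exact oracle rather than a realistic
simulator:

* FI is constant within each shell, so the pipeline's annulus means
  recover the painted values exactly with no angular averaging error.
* The painted shell values are the *moving-average preimage* of the
  target curve (computed with an SVD pseudo-inverse; the smoothing
  operator has an alternating near-null mode at some lengths that
  smooth targets do not excite). After the pipeline's three-point
  smoothing, the extracted curve lands on the intended truth at every
  shell centre, so zero-noise extraction errors reduce to
  interpolation error, below 0.5 FI points at the default geometry.

Noise is generated on the 101-node depth grid (white Gaussian noise
convolved with a Gaussian kernel, variance-renormalized node by node)
and painted through the same preimage, guaranteeing the smooth,
stationary residual fields the RFT model assumes.

Defaults are the study conditions: 40 patients and 21 controls, 1.3 mm
in-plane resolution, age/BMI/sex distributions matching the cohort
description, an effect bump in the multifidus at 15% depth with
amplitude 8 FI points and FWHM 15%, and noise of SD 5 FI points with
smoothness FWHM 15 nodes. Baseline magnitudes (multifidus peaking near
50 FI% in the deep region, erector spinae slightly higher, psoas low
and flat) qualitatively mimic reported peak statistics but are
configuration keys, not asserted values. Metadata prevalences for CEP
damage, Modic changes and Pfirrmann grades are not published for this
design; the defaults (e.g. CEP 60% in patients vs 25% in controls) are
plausible round numbers chosen once to exercise every stratification
rule.

What the phantom does **not** emulate: anatomy (muscle outlines are
sectors, not muscles), scanner physics (no bias fields, chemical-shift
artifacts or Rician noise), segmentation error, and between-subject
geometric variability (all subjects share one CoR and mask set).
Passing tests therefore demonstrate that the *pipeline* is correct and
calibrated, not that the method is robust to real-world segmentation
or acquisition error.

## Numerical choices and degenerate inputs

* Annulus bins are half-open `[k, k+1)`; a pixel exactly on an integer
  radius belongs to the outer bin, and no pixel is counted twice.
* Peak ties break toward the smallest depth, so a constant curve
  reports its peak at 0% (deep): when there is no distinguished
  maximum the convention favours the CoR-adjacent region that the
  deep-peak analyses target.
* Zero pooled variance at any node aborts the t-field with the node
  named; this arises only from degenerate (e.g. noise-free duplicated)
  input.
* `rft_threshold` brackets its root by doubling and solves with
  `uniroot` at tolerance 1e-12, verifying the achieved alpha residual.
* Masks stored as grayscale are binarized at 0.5; empty masks are
  flagged unusable and the subject is dropped from that muscle's
  comparisons only.
* All Monte-Carlo routines take an explicit seed and are reproducible;
  the pipeline itself contains no randomness.

## Problem sizes used in the tests

The test suite validates calibration with 5000 simulated null cohorts
(n = 20 per group, 101 nodes, noise FWHM 10 nodes) for the family-wise
error rate and the threshold-versus-Monte-Carlo cross-check, and 200
repetitions for parameter recovery under the default effect and noise
conditions; these sizes give 99% binomial bands comfortably narrower
than the effects being checked while keeping the whole suite around a
minute. Phantom-image tests use cohorts of 4–8 subjects at the default
160x160 geometry; extraction accuracy is independent of cohort size.

## Known limitations

* Single axial slice at the L4L5 disc centre; no volumetric fat
  mapping or cross-sectional-area metrics.
* Gaussian RFT inference only; no permutation (nonparametric) SPM, and
  no ANOVA/regression fields.
* The smoothness estimator and cluster p-value conventions follow
  standard 1D RFT practice; exact numerical equivalence with any
  particular external SPM implementation is not claimed — the contract
  is calibration against the stated alpha, which the Monte-Carlo
  suite verifies.
* Cluster spans are reported with sub-node linear interpolation of the
  threshold crossings; at 101 nodes the induced uncertainty is well
  under one percent of radial width.
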