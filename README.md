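# fatmapr

Radial fat-mapping of paraspinal muscle fat infiltration, with
one-dimensional statistical parametric mapping (SPM) for group
comparisons.

## What it does, and for whom

Fat infiltration (FI%) of the lumbar paraspinal muscles — multifidus,
erector spinae, psoas — is usually summarised as one mean per muscle,
which hides *where* in the muscle the fat sits. For researchers
studying chronic low back pain and degenerative disc pathology,
`fatmapr` turns a water-fat MRI slice and muscle segmentations into a
spatial **fat-map**: the mean FI% in concentric one-pixel annuli around
the centre of rotation (CoR) of the L4L5 motion segment, smoothed with
a three-point moving average and distance-normalized to 0–100% of the
muscle's radial width. Cohorts of such curves are then compared
node-by-node.

The core statistics: at each of `Q` nodes the pooled-variance
two-sample t statistic forms the field SPM{t}; the residual curves give
the field smoothness FWHM; and the critical threshold `t*` solves the
random-field-theory (RFT) expected-Euler-characteristic equation

    alpha = 1 - exp(-(EC0(u) + resels * EC1(u))),   resels = (Q-1)/FWHM

with `EC0` the t upper tail and `EC1` the 1D EC density, so that a
smooth null field exceeds `t*` anywhere with probability `alpha`.
Contiguous supra-threshold runs are reported as clusters with
interpolated spans and RFT cluster-level p-values. Whole-muscle overall
mean FI% is compared with plain unpaired t-tests, and curve peaks are
summarised by magnitude, radial depth, and deep / intermediate /
superficial region.

A synthetic phantom generator (annular-sector muscles with analytic
radial ground truth) makes every stage testable without patient data.

## Worked example

Generate a phantom cohort at the study's scale (40 patients, 21
controls, with a patient-only multifidus effect of 8 FI points at 15%
radial depth over smooth noise of SD 5) and run the full analysis:

```r
library(fatmapr)

cfg <- synthetic_cohort_config(seed = 42)        # study-scale defaults
d <- file.path(tempdir(), "cohort42")
generate_cohort(cfg, d)

report <- run_analysis(list(data_dir = d, seed = 42))
report
#> <fatmap_report> 3 muscles, 61 subjects
#>   multifidus (deep-peak prevalence 100.0%)
#>     group: overall dFI = 0.45 (p = 0.54), 1 cluster(s)
#>   erector_spinae (deep-peak prevalence 100.0%)
#>     group: overall dFI = 0.04 (p = 0.949), 0 cluster(s)
#>   psoas (deep-peak prevalence 27.9%)
#>     group: overall dFI = -0.12 (p = 0.842), 0 cluster(s)

report$results$multifidus$group$spm
#> <spm_result> multifidus / group (n=40 vs 21), df=59, FWHM=15.8 nodes, t*=3.057 (two.sided alpha=0.05)
#>   cluster 1: 6.4-21.8% (A > B), p = 0.005077
```

Reading the output: the multifidus fat-maps differ between patients and
controls in a cluster spanning 6.4–21.8% of the radial width — the deep
region, containing the true simulated effect centre at 15% — while the
overall mean FI% (a 0.45-point difference, p = 0.54) misses the
localized effect entirely. The untouched erector spinae and psoas show
no clusters, and the deep-peak prevalences (100% for multifidus and
erector spinae, 28% for psoas) reflect the deep-peaked versus flat
baseline shapes.

Real data enter the same way: a directory with one fat-fraction NIfTI
(or water/fat channel pair via `compute_fat_fraction()`) and one mask
per muscle per subject, plus a `cohort.csv` with group, VAS/ODI,
CEP/Pfirrmann/Modic gradings and the two disc endpoints per subject.
Stratified comparisons (`stratification_rule("pfirrmann")`, VAS > 6 vs
≤ 6, CEP within patients, ...) plug into the `comparisons` key of
`run_analysis()`. A thin command-line wrapper lives at
`inst/cli/fatmap.R` (`simulate`, `extract`, `spm`, `peaks`, `run`).

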