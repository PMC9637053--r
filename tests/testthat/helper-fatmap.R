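# Shared fixtures: all test data is generated in code.

make_slice <- function(values, spacing = 1, id = "s1") {
  fat_fraction_slice(values, pixel_spacing = spacing, subject_id = id)
}

# Direct radial_profile constructor for unit tests of the curve
# operations (bypasses the imaging stage).
make_profile <- function(mean_fi, pixel_count = NULL, muscle = "multifidus",
                         smoothed = FALSE) {
  if (is.null(pixel_count)) pixel_count <- ifelse(is.na(mean_fi), 0L, 1L)
  structure(
    list(annulus = seq_along(mean_fi) - 1L, mean_fi = as.numeric(mean_fi),
         pixel_count = as.integer(pixel_count), muscle = muscle,
         side = "merged", subject_id = "s1",
         cor = structure(c(0, 0), class = "cor_point"), smoothed = smoothed),
    class = "radial_profile")
}

# Brute-force oracle: per-annulus mean FI by an explicit loop over all
# pixels, grouping by floor(distance to the CoR).
brute_annulus_means <- function(values, mask, cor) {
  acc <- list()
  for (i in seq_len(nrow(values))) for (j in seq_len(ncol(values))) {
    if (!mask[i, j] || is.na(values[i, j])) next
    k <- floor(sqrt((i - cor[1])^2 + (j - cor[2])^2))
    key <- as.character(k)
    acc[[key]] <- c(acc[[key]], values[i, j])
  }
  ks <- sort(as.integer(names(acc)))
  list(annulus = ks,
       mean_fi = vapply(as.character(ks), function(k) mean(acc[[k]]),
                        numeric(1)))
}

# Small default-geometry phantom cohort written to a temp dir.
tiny_cohort <- function(n_patients = 4L, n_controls = 4L, noise_sd = 5,
                        effect_amplitude = 8, seed = 1L) {
  cfg <- synthetic_cohort_config(
    n_patients = n_patients, n_controls = n_controls,
    effect = list(muscle = "multifidus", center = 15, fwhm = 15,
                  amplitude = effect_amplitude),
    noise = list(sd = noise_sd, fwhm = 15), seed = seed)
  d <- withr::local_tempdir(.local_envir = parent.frame())
  gen <- generate_cohort(cfg, d)
  list(dir = d, gen = gen, cfg = cfg)
}
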