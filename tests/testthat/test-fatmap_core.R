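test_that("annulus means match a brute-force per-pixel loop", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- matrix(runif(225, 0, 100), 15, 15)
    m <- matrix(runif(225) < 0.5, 15, 15)
    if (!any(m)) next
    cor <- structure(runif(2, 3, 12), class = "cor_point")
    p <- build_radial_profile(make_slice(v), muscle_mask(m, "multifidus"), cor)
    oracle <- brute_annulus_means(v, m, cor)
    occ <- which(!is.na(p$mean_fi)) - 1L
    expect_equal(occ, oracle$annulus)
    expect_equal(p$mean_fi[occ + 1L], oracle$mean_fi, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("every mask pixel lands in exactly one annulus (partition)", {
  set.seed(11)
  v <- matrix(runif(225, 0, 100), 15, 15)
  m <- matrix(runif(225) < 0.4, 15, 15)
  cor <- structure(c(7.2, 8.9), class = "cor_point")
  p <- build_radial_profile(make_slice(v), muscle_mask(m, "psoas"), cor)
  expect_identical(sum(p$pixel_count), sum(m))
})

test_that("a uniform FI field yields constant occupied annuli", {
  m <- matrix(FALSE, 12, 12); m[3:9, 4:10] <- TRUE
  p <- build_radial_profile(make_slice(matrix(37, 12, 12)),
                            muscle_mask(m, "erector_spinae"),
                            structure(c(6, 6), class = "cor_point"))
  expect_true(all(p$mean_fi[!is.na(p$mean_fi)] == 37))
})

test_that("a single mask pixel occupies only its floor-distance annulus", {
  m <- matrix(FALSE, 9, 9)
  m[5, 8] <- TRUE                      # distance 2.5 from CoR below
  v <- matrix(0, 9, 9); v[5, 8] <- 40
  p <- build_radial_profile(make_slice(v), muscle_mask(m, "multifidus"),
                            structure(c(5, 5.5), class = "cor_point"))
  expect_equal(p$mean_fi[3], 40)       # annulus index 2
  expect_true(all(is.na(p$mean_fi[-3])))
})

test_that("empty and all-missing masks are rejected", {
  v <- matrix(50, 6, 6)
  cor <- structure(c(3, 3), class = "cor_point")
  m0 <- suppressWarnings(muscle_mask(matrix(FALSE, 6, 6), "psoas"))
  expect_error(build_radial_profile(make_slice(v), m0, cor), "empty mask")
  vna <- matrix(NA_real_, 6, 6); vna[1, 1] <- 10
  m1 <- matrix(FALSE, 6, 6); m1[4:6, 4:6] <- TRUE
  expect_error(build_radial_profile(make_slice(vna),
                                    muscle_mask(m1, "psoas"), cor),
               "missing")
})

test_that("overall mean FI equals the weighted mean of annulus means", {
  half <- matrix(c(0, 50), 10, 10)
  m <- matrix(TRUE, 10, 10)
  expect_equal(overall_mean_fi(make_slice(half), muscle_mask(m, "psoas")), 25)
  expect_equal(overall_mean_fi(make_slice(matrix(20, 5, 5)),
                               muscle_mask(matrix(TRUE, 5, 5), "psoas")), 20)
  # conservation identity on random masks, pre-smoothing
  set.seed(3)
  for (rep in 1:5) {
    v <- matrix(runif(144, 0, 100), 12, 12)
    mm <- matrix(runif(144) < 0.6, 12, 12)
    cor <- structure(runif(2, 2, 10), class = "cor_point")
    p <- build_radial_profile(make_slice(v), muscle_mask(mm, "multifidus"), cor)
    w <- p$pixel_count[!is.na(p$mean_fi)]
    expect_equal(sum(w * p$mean_fi[!is.na(p$mean_fi)]) / sum(w),
                 overall_mean_fi(make_slice(v), muscle_mask(mm, "multifidus")),
                 tolerance = 1e-9)
  }
})

test_that("three-point moving average follows the stated edge policy", {
  expect_equal(smooth_profile(make_profile(rep(12, 6)))$mean_fi, rep(12, 6))
  expect_equal(smooth_profile(make_profile(c(0, 30, 0)))$mean_fi[2], 10)
  expect_equal(smooth_profile(make_profile(c(10, 20, 30, 40)))$mean_fi,
               c(15, 20, 30, 35))
})

test_that("interior gaps are linearly interpolated before smoothing", {
  p <- make_profile(c(NA, 10, NA, 30, NA))   # leading/trailing NA stay
  s <- smooth_profile(p)
  # gap filled to 20, then smoothed: [15, 20, 25] over annuli 1..3
  expect_equal(s$mean_fi, c(NA, 15, 20, 25, NA))
  expect_equal(s$pixel_count[3], 0L)
})

test_that("normalization preserves linearity and endpoints", {
  ramp <- make_profile(seq(0, 50, by = 5), smoothed = TRUE)
  np <- normalize_profile(ramp, 101)
  expect_equal(np$fi, 0.5 * (0:100), tolerance = 1e-12)
  set.seed(4)
  arb <- make_profile(runif(17, 5, 80), smoothed = TRUE)
  np2 <- normalize_profile(arb, 101)
  expect_equal(np2$fi[1], arb$mean_fi[1])
  expect_equal(np2$fi[101], arb$mean_fi[17])
})

test_that("normalization matches an independent piecewise-linear oracle", {
  set.seed(5)
  vals <- runif(23, 0, 90)
  np <- normalize_profile(make_profile(vals, smoothed = TRUE), 101)
  # brute-force evaluation at each node position
  pos <- seq(1, 23, length.out = 101)
  oracle <- vapply(pos, function(x) {
    i <- min(floor(x), 22)
    vals[i] + (x - i) * (vals[i + 1] - vals[i])
  }, numeric(1))
  expect_equal(np$fi, oracle, tolerance = 1e-12)
})

test_that("normalizing a node-aligned curve with the same node count is identity", {
  set.seed(6)
  vals <- runif(101, 0, 60)
  np <- normalize_profile(make_profile(vals, smoothed = TRUE), 101)
  expect_equal(np$fi, vals, tolerance = 1e-9)
})

test_that("normalization needs at least two occupied annuli", {
  expect_error(normalize_profile(make_profile(c(NA, 42, NA)), 101),
               "at least 2")
})

test_that("curves and peaks scale with the FI field (equivariance)", {
  set.seed(8)
  v <- matrix(runif(144, 0, 20), 12, 12)
  m <- matrix(FALSE, 12, 12); m[3:10, 3:10] <- TRUE
  cor <- structure(c(6, 6), class = "cor_point")
  go <- function(vv) {
    p <- normalize_profile(smooth_profile(build_radial_profile(
      make_slice(vv), muscle_mask(m, "multifidus"), cor)), 51)
    list(fi = p$fi, peak = detect_peak(p)$peak_fi)
  }
  a <- go(v); b <- go(3 * v)
  expect_equal(b$fi, 3 * a$fi, tolerance = 1e-12)
  expect_equal(b$peak, 3 * a$peak, tolerance = 1e-12)
})

test_that("peak detection reports magnitude, depth and region with deep tie-break", {
  fi <- rep(10, 101); fi[17] <- 49.3
  pk <- detect_peak(normalized_profile(fi))
  expect_equal(pk$peak_fi, 49.3)
  expect_equal(pk$peak_depth, 16)
  expect_equal(pk$region, "deep")

  flat <- detect_peak(normalized_profile(rep(25, 101)))
  expect_equal(flat$peak_depth, 0)     # ties break toward the CoR
  expect_equal(flat$region, "deep")

  two <- rep(5, 101); two[c(11, 81)] <- 60
  expect_equal(detect_peak(normalized_profile(two))$peak_depth, 10)

  mid <- rep(5, 101); mid[51] <- 30
  expect_equal(detect_peak(normalized_profile(mid))$region, "intermediate")
  sup <- rep(5, 101); sup[91] <- 30
  expect_equal(detect_peak(normalized_profile(sup))$region, "superficial")
})

test_that("peak prevalence counts the fraction of subjects peaking in a region", {
  deep1 <- rep(5, 101); deep1[6] <- 50
  sup1 <- rep(5, 101); sup1[91] <- 50
  all_deep <- replicate(4, normalized_profile(deep1), simplify = FALSE)
  expect_equal(peak_prevalence(all_deep, region = "deep"), 1.0)
  mix <- c(list(normalized_profile(deep1)),
           replicate(3, normalized_profile(sup1), simplify = FALSE))
  expect_equal(peak_prevalence(mix, region = "deep"), 0.25)
  expect_error(peak_prevalence(list(), region = "deep"), "no profiles")
})
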