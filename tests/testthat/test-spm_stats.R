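test_that("the t-field is zero when both groups hold the same curves", {
  set.seed(1)
  A <- matrix(rnorm(5 * 40), 5, 40)
  tf <- t_field(A, A)
  expect_equal(tf$t, rep(0, 40), tolerance = 1e-12)
  expect_equal(tf$df, 8)
})

test_that("a single-node t-field reproduces the hand two-sample t", {
  tf <- t_field(matrix(c(1, 2, 3), 3, 1), matrix(c(4, 5, 6), 3, 1))
  # means 2 vs 5, pooled SD 1, SE sqrt(2/3)
  expect_equal(tf$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tf$df, 4)
})

test_that("the t-field equals scalar two-sample t-tests run per node", {
  set.seed(2)
  A <- matrix(rnorm(8 * 25, 50, 10), 8, 25)
  B <- matrix(rnorm(6 * 25, 48, 12), 6, 25)
  tf <- t_field(A, B)
  oracle <- vapply(1:25, function(j)
    unname(stats::t.test(A[, j], B[, j], var.equal = TRUE)$statistic),
    numeric(1))
  expect_equal(tf$t, oracle, tolerance = 1e-10)
})

test_that("zero pooled variance is rejected naming the node", {
  A <- matrix(1, 3, 4); A[, 2] <- c(1, 2, 3)
  B <- matrix(1, 3, 4); B[, 2] <- c(0, 1, 2)
  expect_error(t_field(A, B), "node 1")
  expect_error(t_field(matrix(1, 3, 4), matrix(2, 4, 5)),
               "different node grids")
})

test_that("smoothness estimates are scale invariant and track the truth", {
  set.seed(3)
  R <- fatmapr:::.smooth_curves(200, 101, 20)
  est <- estimate_fwhm(R)
  expect_lt(abs(est - 20) / 20, 0.25)          # recovery within 25%
  expect_equal(estimate_fwhm(5000 * R), est, tolerance = 1e-12)
  set.seed(4)
  white <- matrix(rnorm(200 * 101), 200, 101)
  expect_lt(estimate_fwhm(white), 3)           # white-noise limit
  expect_error(estimate_fwhm(matrix(c(1, 2, 3), 3, 8)),
               class = "fatmapr_infinite_smoothness")
})

test_that("the RFT threshold approaches the scalar t critical value as resels -> 0", {
  u <- rft_threshold(38, 101, 1e9, 0.05)
  expect_lt(abs(u - qt(0.95, 38)) / qt(0.95, 38), 0.01)
})

test_that("the RFT threshold is monotone in resels and alpha", {
  u1 <- rft_threshold(38, 101, 10, 0.05)
  u2 <- rft_threshold(38, 101, 5, 0.05)    # resels doubled
  expect_gt(u2, u1)
  u3 <- rft_threshold(38, 101, 10, 0.01)
  expect_gt(u3, u1)
  expect_gt(rft_threshold(38, 201, 10, 0.05), u1)
})

test_that("cluster extraction finds contiguous supra-threshold runs", {
  nodes <- seq(0, 100, length.out = 101)
  base <- list(df = 38, fwhm = 10, alpha = 0.05, sided = "two.sided",
               nodes = nodes, t_star = 3)
  below <- base; below$t <- rep(1, 101)
  expect_equal(nrow(find_clusters(below)), 0)

  one <- base; one$t <- rep(0, 101); one$t[14:18] <- 4  # nodes 13-17%
  cl <- find_clusters(one)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$extent, 5L)
  expect_lt(cl$start_percent, 13); expect_gt(cl$start_percent, 12)
  expect_gt(cl$end_percent, 17); expect_lt(cl$end_percent, 18)
  expect_true(cl$p_value > 0 && cl$p_value <= 1)

  two <- base; two$t <- rep(0, 101)
  two$t[11:16] <- 5; two$t[61:70] <- -5   # one positive, one negative bump
  cl2 <- find_clusters(two)
  expect_equal(nrow(cl2), 2)
  expect_true(all(diff(cl2$start_percent) > 0))   # sorted
  expect_equal(cl2$sign, c(1L, -1L))
})

test_that("identical group sets produce no clusters through the full SPM", {
  set.seed(5)
  A <- fatmapr:::.smooth_curves(10, 101, 12)
  res <- spm_ttest2(A, A)
  expect_equal(nrow(res$clusters), 0)
  expect_s3_class(res, "spm_result")
  expect_gt(res$field$t_star, 0)
})

test_that("a strong localized group effect yields a cluster over the bump", {
  pc <- generate_profile_cohort(effect_amplitude = 12, noise_sd = 4,
                                seed = 77)
  res <- spm_ttest2(pc$patients, pc$controls)
  cl <- res$clusters
  expect_gt(nrow(cl), 0)
  expect_true(any(cl$sign > 0 & cl$start_percent <= 15 &
                  cl$end_percent >= 15))
})

test_that("the scalar unpaired t-test matches its textbook values and oracle", {
  same <- unpaired_ttest(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  tt <- unpaired_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(tt$t), 3.674235, tolerance = 1e-6)
  expect_equal(tt$p, 0.02131164, tolerance = 1e-6)
  set.seed(6)
  for (rep in 1:10) {
    a <- rnorm(7, 50, 9); b <- rnorm(9, 47, 11)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    got <- unpaired_ttest(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(unpaired_ttest(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("null p-values of the unpaired t-test are uniform", {
  set.seed(7)
  p <- replicate(400, unpaired_ttest(rnorm(10), rnorm(10))$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("monte_carlo_null is reproducible and matches the RFT threshold", {
  m1 <- monte_carlo_null(18, 51, 8, 20, seed = 9)
  m2 <- monte_carlo_null(18, 51, 8, 20, seed = 9)
  expect_identical(m1, m2)
  expect_error(monte_carlo_null(7, 51, 8, 5), "even")
})

test_that("with near-infinite smoothness the field maxima follow the scalar t", {
  mx <- monte_carlo_null(38, 101, 101 * 100, 2000, seed = 10)
  expect_lt(abs(quantile(mx, 0.95) - qt(0.95, 38)), 0.15)
})
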