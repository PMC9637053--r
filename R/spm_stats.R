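# One-dimensional statistical parametric mapping: node-wise two-sample
# t-fields, residual smoothness (FWHM) estimation, random-field-theory
# critical thresholds, cluster-level inference, and Monte-Carlo
# validation of the threshold.

.profile_matrix <- function(group) {
  if (is.matrix(group)) {
    storage.mode(group) <- "double"
    return(group)
  }
  if (inherits(group, "normalized_profile")) group <- list(group)
  if (!is.list(group) || !length(group))
    stop("a group must be a numeric matrix (subjects x nodes) or a list of normalized_profile")
  nodes <- group[[1L]]$nodes
  rows <- lapply(group, function(p) {
    stopifnot(inherits(p, "normalized_profile"))
    if (length(p$nodes) != length(nodes) ||
        max(abs(p$nodes - nodes)) > 1e-9)
      stop("profiles do not share a common node grid")
    p$fi
  })
  do.call(rbind, rows)
}

#' Node-wise two-sample t-field
#'
#' At every node of the common 0-100% grid, the standard pooled-variance
#' two-sample t statistic comparing group A with group B (positive where
#' A exceeds B). Residuals are the per-subject deviations from their
#' group's mean curve; they carry the field's smoothness.
#'
#' @param groupA,groupB Matrices (subjects x nodes) or lists of
#'   `normalized_profile` sharing one node grid; at least 2 subjects per
#'   group.
#' @return List: `t` (length Q), `df` (`nA + nB - 2`), `residuals`
#'   (`(nA + nB) x Q`), `nA`, `nB`, `meanA`, `meanB`.
#' @export
t_field <- function(groupA, groupB) {
  A <- .profile_matrix(groupA); B <- .profile_matrix(groupB)
  if (ncol(A) != ncol(B)) stop("groups are on different node grids")
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 2L || nB < 2L) stop("each group needs at least 2 subjects")
  mA <- colMeans(A); mB <- colMeans(B)
  RA <- sweep(A, 2L, mA); RB <- sweep(B, 2L, mB)
  df <- nA + nB - 2L
  sp2 <- (colSums(RA^2) + colSums(RB^2)) / df
  bad <- which(sp2 <= 0)
  if (length(bad))
    stop("zero pooled variance at node ", bad[1L])
  t <- (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
  list(t = t, df = df, residuals = rbind(RA, RB), nA = nA, nB = nB,
       meanA = mA, meanB = mB)
}

# Central-difference gradient along the rows of a matrix (one-sided at
# the ends), the discrete derivative used by the smoothness estimator.
.row_gradient <- function(R) {
  Q <- ncol(R)
  D <- matrix(0, nrow(R), Q)
  if (Q >= 2L) {
    D[, 1L] <- R[, 2L] - R[, 1L]
    D[, Q] <- R[, Q] - R[, Q - 1L]
  }
  if (Q >= 3L)
    D[, 2:(Q - 1L)] <- (R[, 3:Q] - R[, 1:(Q - 2L)]) / 2
  D
}

#' Estimate residual field smoothness (FWHM)
#'
#' Smoothness of the residual field in node units, from the ratio of the
#' spatial-gradient variance to the field variance: at each node,
#' resels-per-node `= sqrt(sum(dR^2) / sum(R^2) / (4 log 2))`; the field
#' FWHM is the reciprocal of the node-wise mean. Scale-invariant by
#' construction. The estimate is clamped to `[1, 10 * Q]`.
#'
#' @param residuals Matrix of residual curves (subjects x nodes), e.g.
#'   from [t_field()].
#' @return Estimated FWHM in nodes.
#' @export
estimate_fwhm <- function(residuals) {
  R <- as.matrix(residuals)
  if (nrow(R) < 2L || ncol(R) < 2L)
    stop("need at least 2 residual curves on at least 2 nodes")
  Q <- ncol(R)
  ssq <- colSums(R^2)
  D <- .row_gradient(R)
  gsq <- colSums(D^2)
  ok <- ssq > 0
  if (!any(ok) || all(gsq[ok] == 0))
    stop(errorCondition("residuals are constant along the field; smoothness is infinite",
                        class = c("fatmapr_infinite_smoothness", "error", "condition")))
  rpn <- sqrt(gsq[ok] / ssq[ok] / (4 * log(2)))
  m <- mean(rpn)
  if (m == 0)
    stop(errorCondition("residuals are constant along the field; smoothness is infinite",
                        class = c("fatmapr_infinite_smoothness", "error", "condition")))
  min(max(1 / m, 1), 10 * Q)
}

# Euler characteristic densities of a 1D t-field.
.ec0_t <- function(u, df) stats::pt(u, df, lower.tail = FALSE)
.ec1_t <- function(u, df)
  sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)

#' Random-field-theory critical threshold for a 1D t-field
#'
#' The smallest `u` solving
#' `alpha = 1 - exp(-(EC0(u) + resels * EC1(u)))` with
#' `resels = (q_nodes - 1) / fwhm`, where `EC0` is the upper tail of the
#' t distribution and `EC1` the 1D Euler-characteristic density. A
#' smooth null t-field then exceeds `u` somewhere along its length with
#' probability `alpha` (one-tailed). As `resels -> 0` the threshold
#' approaches the scalar t critical value.
#'
#' @param df Degrees of freedom (`nA + nB - 2`).
#' @param q_nodes Number of field nodes.
#' @param fwhm Field smoothness in nodes.
#' @param alpha Significance level in (0, 0.5).
#' @return Critical threshold `t_star`.
#' @export
rft_threshold <- function(df, q_nodes, fwhm, alpha = 0.05) {
  if (df < 1) stop("df must be >= 1")
  if (fwhm <= 0) stop("fwhm must be positive")
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must be in (0, 0.5)")
  resels <- (q_nodes - 1) / fwhm
  target <- -log1p(-alpha)
  g <- function(u) .ec0_t(u, df) + resels * .ec1_t(u, df) - target
  lower <- 0
  upper <- 10
  while (g(upper) > 0 && upper < 1e6) upper <- upper * 2
  if (g(upper) > 0) stop("rft_threshold failed to bracket a solution")
  u <- stats::uniroot(g, c(lower, upper), tol = 1e-12,
                      maxiter = 2000L)$root
  if (abs((1 - exp(-(.ec0_t(u, df) + resels * .ec1_t(u, df)))) - alpha) > 1e-8)
    stop("rft_threshold did not converge to the requested alpha")
  u
}

#' Extract supra-threshold clusters from a t-field
#'
#' Maximal runs of contiguous nodes exceeding the critical threshold. In
#' two-sided mode, positive (`t > t_star`) and negative (`t < -t_star`)
#' clusters are found separately and reported with their sign. Cluster
#' spans are given in % radial width with sub-node linear interpolation
#' of the threshold crossings. Cluster-level p-values use the RFT
#' expected-cluster-extent exponential approximation given the field's
#' smoothness and threshold (doubled, capped at 1, in two-sided mode).
#'
#' @param field An `spm_t_field` (see [spm_ttest2()]), or a list with at
#'   least `t`, `t_star`, `df`, `fwhm`, `alpha`, `nodes`, `sided`.
#' @return Data frame of clusters sorted by `start_percent`:
#'   `start_percent`, `end_percent`, `extent` (node count), `p_value`,
#'   `sign`. Zero rows when nothing exceeds the threshold.
#' @export
find_clusters <- function(field) {
  t <- field$t; u <- field$t_star
  nodes <- field$nodes
  if (is.null(nodes)) nodes <- seq(0, 100, length.out = length(t))
  two_sided <- identical(field$sided, "two.sided")
  dn <- nodes[2L] - nodes[1L]
  Q <- length(t)
  resels <- (Q - 1) / field$fwhm

  # expected-extent approximation shared by every cluster at this u
  m <- .ec0_t(u, field$df) + resels * .ec1_t(u, field$df)   # E[#clusters]
  en <- Q * .ec0_t(u, field$df)                              # E[supra nodes]
  n0 <- en / m                                               # E[extent]

  runs_for <- function(x, sgn) {
    above <- x > u
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    out <- lapply(keep, function(j) {
      i1 <- starts[j]; i2 <- ends[j]
      s <- if (i1 == 1L) nodes[1L] else
        nodes[i1 - 1L] + dn * (u - x[i1 - 1L]) / (x[i1] - x[i1 - 1L])
      e <- if (i2 == Q) nodes[Q] else
        nodes[i2] + dn * (x[i2] - u) / (x[i2] - x[i2 + 1L])
      k <- max((e - s) / dn, 1)             # extent in node units
      p <- 1 - exp(-m * exp(-k / n0))
      if (two_sided) p <- min(1, 2 * p)
      data.frame(start_percent = s, end_percent = e,
                 extent = i2 - i1 + 1L, p_value = max(p, .Machine$double.xmin),
                 sign = sgn)
    })
    do.call(rbind, out)
  }

  pos <- runs_for(t, 1L)
  neg <- if (two_sided || identical(field$sided, "less")) runs_for(-t, -1L) else NULL
  if (identical(field$sided, "less")) pos <- NULL
  cl <- rbind(pos, neg)
  if (is.null(cl))
    return(data.frame(start_percent = numeric(0), end_percent = numeric(0),
                      extent = integer(0), p_value = numeric(0),
                      sign = integer(0)))
  cl <- cl[order(cl$start_percent), , drop = FALSE]
  rownames(cl) <- NULL
  cl
}

#' Two-sample SPM t-test over normalized fat-map curves
#'
#' The full 1D SPM procedure: node-wise two-sample t-field, residual
#' smoothness estimation, RFT critical threshold at `alpha`, and
#' supra-threshold cluster extraction. Default inference is two-sided
#' (threshold at `alpha / 2` per tail) with signed cluster reporting.
#'
#' @inheritParams t_field
#' @param alpha Family-wise significance level (default 0.05).
#' @param sided `"two.sided"` (default), `"greater"` (A > B), or
#'   `"less"`.
#' @param comparison Free-text label stored with the result.
#' @return An `spm_result`: `field` (class `spm_t_field`: `t`, `df`,
#'   `fwhm`, `alpha`, `t_star`, `sided`, `nodes`, `resels`), `clusters`
#'   (see [find_clusters()]), `group_sizes`, `comparison`.
#' @export
spm_ttest2 <- function(groupA, groupB, alpha = 0.05,
                       sided = c("two.sided", "greater", "less"),
                       comparison = "") {
  sided <- match.arg(sided)
  tf <- t_field(groupA, groupB)
  Q <- length(tf$t)
  fwhm <- estimate_fwhm(tf$residuals)
  a_tail <- if (sided == "two.sided") alpha / 2 else alpha
  t_star <- rft_threshold(tf$df, Q, fwhm, a_tail)
  field <- structure(
    list(t = tf$t, df = tf$df, fwhm = fwhm, alpha = alpha, t_star = t_star,
         sided = sided, nodes = seq(0, 100, length.out = Q),
         resels = (Q - 1) / fwhm),
    class = "spm_t_field")
  structure(
    list(field = field, clusters = find_clusters(field),
         group_sizes = c(A = tf$nA, B = tf$nB), comparison = comparison,
         meanA = tf$meanA, meanB = tf$meanB),
    class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  f <- x$field
  cat(sprintf("<spm_result> %s (n=%d vs %d), df=%d, FWHM=%.1f nodes, t*=%.3f (%s alpha=%g)\n",
              if (nzchar(x$comparison)) x$comparison else "two-sample SPM{t}",
              x$group_sizes[1L], x$group_sizes[2L], f$df, f$fwhm, f$t_star,
              f$sided, f$alpha))
  if (!nrow(x$clusters)) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: %.1f-%.1f%% (%s), p = %.4g\n", i,
                  x$clusters$start_percent[i], x$clusters$end_percent[i],
                  if (x$clusters$sign[i] > 0) "A > B" else "A < B",
                  x$clusters$p_value[i]))
  }
  invisible(x)
}

#' Scalar pooled-variance unpaired t-test
#'
#' Two-sample t statistic with pooled variance and its two-sided
#' p-value; used for the whole-muscle overall mean FI% comparisons.
#'
#' @param valuesA,valuesB Numeric vectors, at least 2 values each.
#' @return List: `t`, `df`, `p`.
#' @export
unpaired_ttest <- function(valuesA, valuesB) {
  a <- as.numeric(valuesA); b <- as.numeric(valuesB)
  nA <- length(a); nB <- length(b)
  if (nA < 2L || nB < 2L) stop("each sample needs at least 2 values")
  df <- nA + nB - 2L
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / nA + 1 / nB))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Gaussian smoothing weights for Q nodes, each row normalized so the
# smoothed field has exactly unit variance at every node when applied to
# iid N(0,1) noise (edge effects included in the normalization).
.smooth_weights <- function(q_nodes, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  x <- seq_len(q_nodes)
  W <- exp(-outer(x, x, `-`)^2 / (2 * sigma^2))
  W / sqrt(rowSums(W^2))
}

# n smooth unit-variance Gaussian curves (rows) on q_nodes nodes.
.smooth_curves <- function(n, q_nodes, fwhm, W = NULL) {
  if (is.null(W)) W <- .smooth_weights(q_nodes, fwhm)
  matrix(stats::rnorm(n * q_nodes), n, q_nodes) %*% t(W)
}

#' Monte-Carlo null distribution of 1D t-field maxima
#'
#' Simulates smooth unit-variance Gaussian curves (white noise convolved
#' with a Gaussian kernel of the given FWHM, variance-renormalized node
#' by node), forms null two-sample t-fields with `df = nA + nB - 2`
#' (equal groups of `df / 2 + 1`), and returns the field maxima. This is
#' the independent validation oracle for [rft_threshold()]: the
#' empirical `1 - alpha` quantile of the maxima should match the RFT
#' threshold at `alpha`.
#'
#' @param df Degrees of freedom; must be even so two equal groups exist.
#' @param q_nodes Nodes per field.
#' @param fwhm True smoothness of the simulated curves, in nodes.
#' @param n_reps Number of simulated null datasets.
#' @param seed RNG seed (reproducible output).
#' @return Numeric vector of length `n_reps`: the maximum of `t` per
#'   simulated field (one-tailed maxima).
#' @export
monte_carlo_null <- function(df, q_nodes, fwhm, n_reps, seed = 1L) {
  if (df < 2L || df %% 2L != 0L)
    stop("df must be an even number >= 2 (two equal groups)")
  n <- df / 2L + 1L
  if (n_reps < 1L) stop("n_reps must be >= 1")
  set.seed(seed)
  W <- .smooth_weights(q_nodes, fwhm)
  vapply(seq_len(n_reps), function(i) {
    A <- .smooth_curves(n, q_nodes, fwhm, W)
    B <- .smooth_curves(n, q_nodes, fwhm, W)
    max(t_field(A, B)$t)
  }, numeric(1L))
}

#' Simulated family-wise error rate of the full SPM pipeline
#'
#' Generates null cohorts (two groups of smooth unit-variance Gaussian
#' curves with identical distributions), runs the complete SPM
#' procedure — t-field, residual smoothness estimation, RFT threshold,
#' cluster detection — and reports the fraction of repetitions in which
#' any node exceeds the critical threshold. With a calibrated threshold
#' this fraction estimates `alpha`.
#'
#' @param n_reps Number of simulated null cohorts.
#' @param n_per_group Subjects per group (default 20).
#' @param q_nodes Nodes per curve (default 101).
#' @param noise_fwhm True smoothness of the simulated curves, in nodes
#'   (default 10).
#' @param alpha Significance level (default 0.05).
#' @param sided Sidedness passed to [spm_ttest2()].
#' @param seed RNG seed.
#' @return List: `rate` (estimated FWER), `n_reps`, `exceeded` (logical
#'   per repetition).
#' @export
simulate_fwer <- function(n_reps, n_per_group = 20L, q_nodes = 101L,
                          noise_fwhm = 10, alpha = 0.05,
                          sided = "two.sided", seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  set.seed(seed)
  W <- .smooth_weights(q_nodes, noise_fwhm)
  a_tail <- if (identical(sided, "two.sided")) alpha / 2 else alpha
  df <- 2L * n_per_group - 2L
  exceeded <- vapply(seq_len(n_reps), function(i) {
    A <- .smooth_curves(n_per_group, q_nodes, noise_fwhm, W)
    B <- .smooth_curves(n_per_group, q_nodes, noise_fwhm, W)
    tf <- t_field(A, B)
    fwhm <- estimate_fwhm(tf$residuals)
    u <- rft_threshold(df, q_nodes, fwhm, a_tail)
    stat <- if (identical(sided, "two.sided")) max(abs(tf$t))
            else if (identical(sided, "less")) max(-tf$t) else max(tf$t)
    stat > u
  }, logical(1L))
  list(rate = mean(exceeded), n_reps = n_reps, exceeded = exceeded)
}
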