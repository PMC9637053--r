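# Radial fat-maps: annulus means, moving-average smoothing, distance
# normalization, peak summaries.

#' Build a radial fat-infiltration profile for one muscle
#'
#' Concentric annuli of exactly one pixel width radiate outward from the
#' CoR; annulus `k` collects the mask pixels whose centre-to-CoR
#' distance `d` satisfies `k <= d < k + 1`, so every mask pixel belongs
#' to exactly one annulus. The profile stores the arithmetic mean FI%
#' over the non-missing pixels of each annulus, `NA` where an annulus
#' holds no contributing pixel.
#'
#' @param fi A [fat_fraction_slice()].
#' @param mask A [muscle_mask()] on the same grid.
#' @param cor A `cor_point` from [locate_cor()].
#' @return An object of class `radial_profile` with fields `annulus`
#'   (indices `0:kmax`), `mean_fi`, `pixel_count` (non-missing pixels
#'   contributing per annulus), `muscle`, `side`, `subject_id`, `cor`,
#'   `smoothed`.
#' @export
build_radial_profile <- function(fi, mask, cor) {
  stopifnot(inherits(fi, "fat_fraction_slice"), inherits(mask, "muscle_mask"))
  if (!identical(dim(mask$mask), dim(fi$values)))
    stop("mask and image shapes differ")
  if (!any(mask$mask))
    stop(sprintf("empty mask for %s (%s)", mask$muscle, mask$side))
  sel <- mask$mask & !is.na(fi$values)
  if (!any(sel))
    stop(sprintf("all FI values missing under the %s mask", mask$muscle))
  d <- distance_map(dim(fi$values), cor)
  k <- as.integer(floor(d[sel]))
  v <- fi$values[sel]
  kmax <- max(k)
  pixel_count <- tabulate(k + 1L, nbins = kmax + 1L)
  sums <- rep(0, kmax + 1L)
  agg <- rowsum(v, k)                       # ordered by unique k
  sums[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  mean_fi <- ifelse(pixel_count > 0L, sums / pixel_count, NA_real_)
  structure(
    list(annulus = 0:kmax, mean_fi = mean_fi, pixel_count = pixel_count,
         muscle = mask$muscle, side = mask$side, subject_id = fi$subject_id,
         cor = cor, smoothed = FALSE),
    class = "radial_profile")
}

#' Overall mean fat infiltration of a muscle
#'
#' The conventional whole-muscle summary: the unweighted mean FI% over
#' all non-missing mask pixels. Equals the pixel-count-weighted mean of
#' the raw annulus means of [build_radial_profile()].
#'
#' @inheritParams build_radial_profile
#' @return Mean FI% (scalar).
#' @export
overall_mean_fi <- function(fi, mask) {
  stopifnot(inherits(fi, "fat_fraction_slice"), inherits(mask, "muscle_mask"))
  if (!identical(dim(mask$mask), dim(fi$values)))
    stop("mask and image shapes differ")
  if (!any(mask$mask)) stop("empty mask")
  v <- fi$values[mask$mask]
  v <- v[!is.na(v)]
  if (!length(v)) stop("all FI values missing under the mask")
  mean(v)
}

.occupied_span <- function(p) {
  occ <- which(!is.na(p$mean_fi))
  if (!length(occ)) stop("profile has no occupied annulus")
  c(first = occ[1L], last = occ[length(occ)])
}

#' Three-point moving-average smoothing of a radial profile
#'
#' Interior annuli are replaced by the mean of themselves and their two
#' neighbours; the innermost and outermost occupied annuli use the
#' one-sided two-point mean. Empty annuli interior to the occupied span
#' are first filled by linear interpolation between the nearest occupied
#' neighbours (they receive `pixel_count = 0`), giving the gap-free
#' continuum the SPM model requires.
#'
#' @param p A `radial_profile`.
#' @return The smoothed `radial_profile` (`smoothed = TRUE`).
#' @export
smooth_profile <- function(p) {
  stopifnot(inherits(p, "radial_profile"))
  sp <- .occupied_span(p)
  idx <- sp["first"]:sp["last"]
  y <- p$mean_fi[idx]
  gap <- is.na(y)
  if (any(gap))
    y[gap] <- stats::approx(which(!gap), y[!gap], xout = which(gap))$y
  L <- length(y)
  s <- y
  if (L >= 2L) {
    s[1L] <- mean(y[1:2])
    s[L] <- mean(y[(L - 1L):L])
    if (L > 2L) s[2:(L - 1L)] <- (y[1:(L - 2L)] + y[2:(L - 1L)] + y[3:L]) / 3
  }
  p$mean_fi[idx] <- s
  p$smoothed <- TRUE
  p
}

#' Distance-normalize a radial profile to 0-100% radial muscle width
#'
#' Linearly interpolates the profile onto `n_nodes` equally spaced nodes
#' spanning the occupied annulus range, so node 0 is the innermost
#' occupied annulus and node 100 the outermost; endpoint values are
#' preserved exactly. Interior gaps, if still present, are filled by the
#' same linear interpolation.
#'
#' @param p A `radial_profile` (normally already smoothed by
#'   [smooth_profile()]).
#' @param n_nodes Number of nodes on the 0-100% grid (default 101, i.e.
#'   one node per percent).
#' @return An object of class `normalized_profile` with fields `nodes`
#'   (percent radial width), `fi`, `muscle`, `side`, `subject_id`,
#'   `smoothed`.
#' @export
normalize_profile <- function(p, n_nodes = 101L) {
  stopifnot(inherits(p, "radial_profile"))
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2L) stop("`n_nodes` must be at least 2")
  occ <- which(!is.na(p$mean_fi))
  if (length(occ) < 2L)
    stop("normalization needs at least 2 occupied annuli")
  xout <- seq(occ[1L], occ[length(occ)], length.out = n_nodes)
  fi <- stats::approx(occ, p$mean_fi[occ], xout = xout)$y
  structure(
    list(nodes = seq(0, 100, length.out = n_nodes), fi = fi,
         muscle = p$muscle, side = p$side, subject_id = p$subject_id,
         smoothed = isTRUE(p$smoothed)),
    class = "normalized_profile")
}

#' Construct a normalized profile directly from values
#'
#' Convenience constructor used by the phantom generator and by callers
#' holding curves that are already on the common 0-100% grid.
#'
#' @param fi Numeric vector of FI% at equally spaced nodes on 0-100%.
#' @param muscle,side,subject_id Labels; see [muscle_mask()].
#' @param smoothed Whether the curve has been smoothed.
#' @return A `normalized_profile`.
#' @export
normalized_profile <- function(fi, muscle = "multifidus", side = "merged",
                               subject_id = NA_character_, smoothed = TRUE) {
  fi <- as.numeric(fi)
  if (length(fi) < 2L || anyNA(fi) || any(!is.finite(fi)))
    stop("`fi` must be finite at all nodes (>= 2 nodes)")
  structure(
    list(nodes = seq(0, 100, length.out = length(fi)), fi = fi,
         muscle = match.arg(muscle, FATMAP_MUSCLES),
         side = match.arg(side, .fatmap_sides),
         subject_id = as.character(subject_id), smoothed = smoothed),
    class = "normalized_profile")
}

#' Locate the global FI peak of a normalized profile
#'
#' Reports the curve's global maximum, its radial depth, and the region
#' it falls in. Ties are broken toward the smallest depth (the deepest,
#' most CoR-adjacent location). Region boundaries default to equal
#' tertiles: deep < 33.3% radial width, superficial > 66.7%,
#' intermediate between.
#'
#' @param np A `normalized_profile`.
#' @param deep_cut,superficial_cut Region boundaries in % radial width.
#' @return A list (class `peak_summary`): `peak_fi`, `peak_depth`,
#'   `region`, `muscle`, `subject_id`.
#' @export
detect_peak <- function(np, deep_cut = 100 / 3, superficial_cut = 200 / 3) {
  stopifnot(inherits(np, "normalized_profile"))
  i <- which.max(np$fi)                      # first max = smallest depth
  depth <- np$nodes[i]
  region <- if (depth < deep_cut) "deep"
            else if (depth > superficial_cut) "superficial"
            else "intermediate"
  structure(list(peak_fi = np$fi[i], peak_depth = depth, region = region,
                 muscle = np$muscle, subject_id = np$subject_id),
            class = "peak_summary")
}

#' Prevalence of a peak region across subjects
#'
#' Fraction of profiles whose global FI peak falls in the queried region
#' (e.g. the proportion of multifidus muscles peaking in the deep
#' region).
#'
#' @param profiles List of `normalized_profile` objects.
#' @param muscle Optional muscle filter.
#' @param region `"deep"`, `"intermediate"`, or `"superficial"`.
#' @inheritParams detect_peak
#' @return Proportion in \code{[0, 1]}.
#' @export
peak_prevalence <- function(profiles, muscle = NULL, region = "deep",
                            deep_cut = 100 / 3, superficial_cut = 200 / 3) {
  region <- match.arg(region, c("deep", "intermediate", "superficial"))
  if (!is.null(muscle)) {
    muscle <- match.arg(muscle, FATMAP_MUSCLES)
    profiles <- Filter(function(p) p$muscle == muscle, profiles)
  }
  if (!length(profiles)) stop("no profiles to summarise")
  hits <- vapply(profiles, function(p)
    detect_peak(p, deep_cut, superficial_cut)$region == region, logical(1L))
  mean(hits)
}

#' Tabulate peak summaries for a set of profiles
#'
#' @inheritParams peak_prevalence
#' @return A data frame: `subject_id`, `muscle`, `peak_fi`, `peak_depth`,
#'   `region`.
#' @export
peak_table <- function(profiles, deep_cut = 100 / 3,
                       superficial_cut = 200 / 3) {
  rows <- lapply(profiles, function(p) {
    pk <- detect_peak(p, deep_cut, superficial_cut)
    data.frame(subject_id = pk$subject_id, muscle = pk$muscle,
               peak_fi = pk$peak_fi, peak_depth = pk$peak_depth,
               region = pk$region, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.radial_profile <- function(x, ...) {
  occ <- which(!is.na(x$mean_fi))
  cat(sprintf("<radial_profile> %s (%s), annuli %d-%d, %d px%s\n",
              x$muscle, x$side, occ[1L] - 1L, occ[length(occ)] - 1L,
              sum(x$pixel_count), if (x$smoothed) ", smoothed" else ""))
  invisible(x)
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("<normalized_profile> %s (%s), %d nodes, FI %.1f-%.1f%%\n",
              x$muscle, x$side, length(x$nodes), min(x$fi), max(x$fi)))
  invisible(x)
}
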