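# Synthetic phantom cohorts with closed-form radial ground truth.
#
# Muscles are modeled as annular sectors around a fixed CoR. FI is
# painted piecewise-constant within each one-pixel radial shell, at the
# value of the subject's true radial curve evaluated at that shell's
# normalized depth; per-subject noise is generated as a smooth curve in
# the radial-depth domain and painted the same way. The annulus-binning
# step of the pipeline therefore recovers the true curve exactly (up to
# the three-point moving average), making the generator an analytic
# oracle for every downstream stage.

.gauss_bump <- function(x, center, fwhm, amplitude) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  amplitude * exp(-(x - center)^2 / (2 * sigma^2))
}

#' Evaluate a muscle's true baseline radial curve
#'
#' Baseline curves are a superficial plateau plus a Gaussian peak:
#' `plateau + amp * exp(-(d - depth)^2 / (2 * sigma^2))` with `sigma`
#' given through the peak FWHM (`width`).
#'
#' @param params List with `plateau`, `amp`, `depth`, `width` (all in FI
#'   points / % radial width).
#' @param nodes Depths (% radial width) at which to evaluate.
#' @return Numeric vector of FI%.
#' @export
baseline_curve <- function(params, nodes = seq(0, 100, length.out = 101L)) {
  params$plateau + .gauss_bump(nodes, params$depth, params$width, params$amp)
}

#' Configuration of a synthetic phantom cohort
#'
#' Defaults reproduce the study conditions: 40 patients and 21 controls,
#' 1.3 mm in-plane resolution, a deep-peaked multifidus and erector
#' spinae with a flat, low psoas, a patient-only multifidus effect bump
#' at 15% depth (amplitude 8 FI points, FWHM 15%), and smooth
#' within-subject noise (SD 5 FI points, smoothness FWHM 15 nodes).
#'
#' @param n_patients,n_controls Subjects per group (>= 2 each).
#' @param image_shape Image dimensions (pixels).
#' @param pixel_spacing In-plane resolution, mm.
#' @param cor Fixed `(row, col)` centre of rotation shared by all
#'   subjects; disc endpoints are derived so that the 12.5%
#'   interpolation lands exactly on it.
#' @param disc_length AP diameter of the disc in pixels.
#' @param muscles Per-muscle geometry: integer radial span `r_in`/`r_out`
#'   (pixels from the CoR) and angular sector `theta` (degrees in the
#'   image plane); sectors must not overlap.
#' @param baseline Per-muscle true-curve parameters (see
#'   [baseline_curve()]).
#' @param effect Group difference added to patients: `muscle`, `center`
#'   (% depth), `fwhm` (%), `amplitude` (FI points).
#' @param noise `sd` (FI points) and `fwhm` (smoothness of the
#'   within-subject radial noise, in nodes of the 101-node depth grid).
#' @param q_nodes Resolution of the ground-truth depth grid.
#' @param seed RNG seed for the whole cohort.
#' @return A validated `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(
    n_patients = 40L, n_controls = 21L,
    image_shape = c(160L, 160L), pixel_spacing = 1.3,
    cor = c(80, 80), disc_length = 40,
    muscles = list(
      multifidus     = list(r_in = 10L, r_out = 70L, theta = c(-35, 35)),
      erector_spinae = list(r_in = 15L, r_out = 75L, theta = c(45, 110)),
      psoas          = list(r_in = 20L, r_out = 75L, theta = c(120, 180))),
    baseline = list(
      multifidus     = list(plateau = 20, amp = 30, depth = 15, width = 30),
      erector_spinae = list(plateau = 25, amp = 30, depth = 20, width = 35),
      psoas          = list(plateau = 12, amp = 4,  depth = 60, width = 60)),
    effect = list(muscle = "multifidus", center = 15, fwhm = 15,
                  amplitude = 8),
    noise = list(sd = 5, fwhm = 15),
    q_nodes = 101L, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_controls = as.integer(n_controls),
              image_shape = as.integer(image_shape),
              pixel_spacing = pixel_spacing, cor = as.numeric(cor),
              disc_length = disc_length, muscles = muscles,
              baseline = baseline, effect = effect, noise = noise,
              q_nodes = as.integer(q_nodes), seed = as.integer(seed))
  if (cfg$n_patients < 2L || cfg$n_controls < 2L)
    stop("need at least 2 subjects per group")
  if (cfg$effect$amplitude < 0 || cfg$noise$sd < 0)
    stop("effect amplitude and noise sd must be non-negative")
  if (!cfg$effect$muscle %in% names(cfg$muscles))
    stop("effect targets an unknown muscle")
  for (nm in names(cfg$muscles)) {
    g <- cfg$muscles[[nm]]
    if (g$r_in >= g$r_out) stop("r_in must be < r_out for ", nm)
    rmax <- g$r_out
    if (cfg$cor[1] - rmax < 1 || cfg$cor[1] + rmax > cfg$image_shape[1] ||
        cfg$cor[2] - rmax < 1 || cfg$cor[2] + rmax > cfg$image_shape[2])
      stop("muscle geometry for ", nm, " overflows the image bounds")
  }
  ths <- t(vapply(cfg$muscles, function(g) as.numeric(g$theta), numeric(2)))
  o <- order(ths[, 1])
  if (any(ths[o, 1][-1] < ths[o, 2][-nrow(ths)]))
    stop("muscle angular sectors overlap")
  structure(cfg, class = "synthetic_cohort_config")
}

.sector_mask <- function(shape, cor, r_in, r_out, theta) {
  d <- distance_map(shape, cor)
  ang <- atan2(outer(rep(1, shape[1]), seq_len(shape[2])) - cor[2],
               outer(seq_len(shape[1]), rep(1, shape[2])) - cor[1]) * 180 / pi
  d >= r_in & d < r_out & ang >= theta[1] & ang < theta[2]
}

# shell depths (%) for annuli r_in .. r_out-1, matching the pipeline's
# annulus-index normalization exactly
.shell_depths <- function(r_in, r_out)
  (seq.int(r_in, r_out - 1L) - r_in) / (r_out - 1L - r_in) * 100

# Preimage of the pipeline's three-point moving average: returns shell
# values y with MA(y) = target, so the analysis pipeline reproduces the
# target curve exactly at the shell centres.
.ma_preimage <- function(target) {
  K <- length(target)
  if (K < 3L) return(target)
  A <- matrix(0, K, K)
  A[1L, 1:2] <- 0.5
  A[K, (K - 1L):K] <- 0.5
  for (i in 2:(K - 1L)) A[i, (i - 1L):(i + 1L)] <- 1 / 3
  # the operator is singular at some K (an alternating null mode); a
  # smooth target has no component there, so the SVD pseudo-inverse
  # gives an exact preimage for the curves of interest
  s <- svd(A)
  keep <- s$d > max(s$d) * 1e-8
  s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], target)) / s$d[keep])
}

#' Generate a synthetic phantom cohort on disk
#'
#' Writes, per subject, a fat-fraction NIfTI image and one NIfTI mask
#' per muscle; a `cohort.csv` with group, symptom/pathology metadata,
#' disc endpoints and file paths; and a `ground_truth.json` recording
#' the true group curves, effect and geometry. Each subject's true
#' radial curve (baseline, plus the configured effect bump for patients
#' in the target muscle, plus smooth subject noise) is painted
#' piecewise-constant onto the one-pixel radial shells through the
#' moving-average preimage, so that the analysis pipeline's annulus
#' means, after its three-point smoothing, land exactly on the true
#' curve at the shell centres. All painted values are clipped to
#' \code{[0, 100]}.
#'
#' @param config A [synthetic_cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly: `list(dir, cohort, ground_truth)`.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  shape <- config$image_shape
  nodes <- seq(0, 100, length.out = config$q_nodes)

  masks <- lapply(config$muscles, function(g)
    .sector_mask(shape, config$cor, g$r_in, g$r_out, g$theta))
  d <- distance_map(shape, config$cor)
  shell <- floor(d)

  # disc endpoints placed so posterior + 0.125 * (anterior - posterior) = CoR
  L <- config$disc_length
  posterior <- config$cor + c(0.125 * L, 0)
  anterior <- posterior - c(L, 0)

  truth_curves <- list()
  for (nm in names(config$muscles)) {
    base <- baseline_curve(config$baseline[[nm]], nodes)
    eff <- if (nm == config$effect$muscle)
      .gauss_bump(nodes, config$effect$center, config$effect$fwhm,
                  config$effect$amplitude) else rep(0, length(nodes))
    truth_curves[[nm]] <- list(control = base, patient = base + eff)
  }

  n <- config$n_patients + config$n_controls
  group <- c(rep("patient", config$n_patients),
             rep("control", config$n_controls))
  ids <- sprintf("sub-%03d", seq_len(n))

  meta <- data.frame(
    subject_id = ids, group = group,
    vas = ifelse(group == "patient", sample(4:10, n, replace = TRUE),
                 sample(0:1, n, replace = TRUE)),
    odi = ifelse(group == "patient", sample(30:80, n, replace = TRUE),
                 sample(0:8, n, replace = TRUE)),
    cep_damage = stats::runif(n) < ifelse(group == "patient", 0.6, 0.25),
    pfirrmann = ifelse(group == "patient", sample(2:5, n, replace = TRUE),
                       sample(1:3, n, replace = TRUE)),
    modic = stats::runif(n) < ifelse(group == "patient", 0.4, 0.1),
    age = round(stats::rnorm(n, ifelse(group == "patient", 48.8, 43.5),
                             ifelse(group == "patient", 12.2, 12.7)), 1),
    sex = ifelse(stats::runif(n) < ifelse(group == "patient", 0.5, 0.471),
                 "F", "M"),
    bmi = round(stats::rnorm(n, ifelse(group == "patient", 25.6, 23.8),
                             ifelse(group == "patient", 5.1, 4.1)), 1),
    posterior_row = posterior[1], posterior_col = posterior[2],
    anterior_row = anterior[1], anterior_col = anterior[2],
    stringsAsFactors = FALSE)

  img_paths <- character(n)
  mask_paths <- matrix("", n, length(config$muscles),
                       dimnames = list(NULL, names(config$muscles)))
  W <- .smooth_weights(config$q_nodes, config$noise$fwhm)

  for (i in seq_len(n)) {
    sdir <- file.path(out_dir, ids[i])
    dir.create(sdir, showWarnings = FALSE)
    img <- matrix(NA_real_, shape[1], shape[2])
    for (nm in names(config$muscles)) {
      g <- config$muscles[[nm]]
      curve <- truth_curves[[nm]][[group[i]]]
      if (config$noise$sd > 0)
        curve <- curve + config$noise$sd *
          as.numeric(.smooth_curves(1L, config$q_nodes, config$noise$fwhm, W))
      depths <- .shell_depths(g$r_in, g$r_out)
      vals <- stats::approx(nodes, curve, xout = depths, rule = 2)$y
      vals <- pmin(pmax(.ma_preimage(vals), 0), 100)
      m <- masks[[nm]]
      img[m] <- vals[shell[m] - g$r_in + 1L]
    }
    slice <- fat_fraction_slice(img, pixel_spacing = config$pixel_spacing,
                                subject_id = ids[i])
    img_paths[i] <- file.path(ids[i], "fi.nii")
    write_fi_slice(slice, file.path(out_dir, img_paths[i]))
    for (nm in names(config$muscles)) {
      mp <- file.path(ids[i], paste0("mask_", nm, ".nii"))
      mimg <- RNifti::asNifti(masks[[nm]] * 1)
      RNifti::pixdim(mimg) <- rep(config$pixel_spacing, 2L)
      RNifti::writeNifti(mimg, file.path(out_dir, mp), datatype = "uint8")
      mask_paths[i, nm] <- mp
    }
  }

  cohort <- cbind(meta, image = img_paths,
                  as.data.frame(mask_paths, stringsAsFactors = FALSE))
  names(cohort)[names(cohort) %in% names(config$muscles)] <-
    paste0("mask_", names(config$muscles))
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)

  truth <- list(
    nodes = nodes, curves = truth_curves, effect = config$effect,
    noise = config$noise, cor = config$cor,
    muscles = lapply(config$muscles, function(g)
      list(r_in = g$r_in, r_out = g$r_out, theta = g$theta)),
    group = stats::setNames(group, ids), seed = config$seed)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir, cohort = validate_cohort_table(cohort),
                 ground_truth = truth))
}

#' Generate matched null groups of smooth normalized profiles
#'
#' Two groups of identically distributed smooth unit-variance Gaussian
#' curves on a shared node grid, for calibrating the SPM false-positive
#' rate without any imaging step.
#'
#' @param n_per_group Curves per group (>= 2).
#' @param q_nodes Nodes per curve.
#' @param fwhm Curve smoothness in nodes.
#' @param seed RNG seed.
#' @param baseline Optional numeric vector (length `q_nodes`) added to
#'   every curve.
#' @param sd Noise scale multiplying the unit-variance curves.
#' @return `list(groupA, groupB)`: lists of `normalized_profile`.
#' @export
generate_null_profiles <- function(n_per_group, q_nodes = 101L, fwhm = 10,
                                   seed = 1L, baseline = NULL, sd = 1) {
  if (n_per_group < 2L) stop("need at least 2 curves per group")
  set.seed(seed)
  W <- .smooth_weights(q_nodes, fwhm)
  if (is.null(baseline)) baseline <- rep(0, q_nodes)
  wrap <- function(M, tag) lapply(seq_len(nrow(M)), function(i)
    normalized_profile(M[i, ], subject_id = sprintf("%s%03d", tag, i)))
  A <- sweep(sd * .smooth_curves(n_per_group, q_nodes, fwhm, W), 2L,
             baseline, `+`)
  B <- sweep(sd * .smooth_curves(n_per_group, q_nodes, fwhm, W), 2L,
             baseline, `+`)
  list(groupA = wrap(A, "A"), groupB = wrap(B, "B"))
}

#' Generate a profile-level cohort with a known group effect
#'
#' The curve-domain counterpart of [generate_cohort()]: patient and
#' control curves share a baseline and smooth noise model, and patients
#' additionally receive a Gaussian effect bump. Used for parameter
#' recovery at scale without the imaging round trip.
#'
#' @param n_patients,n_controls Curves per group.
#' @param q_nodes Nodes per curve.
#' @param baseline_fi Baseline curve (length `q_nodes`, or scalar).
#' @param effect_center,effect_fwhm,effect_amplitude Gaussian bump added
#'   to patients (% depth, % width, FI points).
#' @param noise_sd,noise_fwhm Smooth-noise scale (FI points) and
#'   smoothness (nodes).
#' @param seed RNG seed.
#' @return `list(patients, controls, nodes, true_effect)` with curve
#'   matrices (subjects x nodes).
#' @export
generate_profile_cohort <- function(n_patients = 20L, n_controls = 20L,
                                    q_nodes = 101L, baseline_fi = 20,
                                    effect_center = 15, effect_fwhm = 15,
                                    effect_amplitude = 8, noise_sd = 5,
                                    noise_fwhm = 15, seed = 1L) {
  set.seed(seed)
  nodes <- seq(0, 100, length.out = q_nodes)
  base <- rep_len(baseline_fi, q_nodes)
  bump <- .gauss_bump(nodes, effect_center, effect_fwhm, effect_amplitude)
  W <- .smooth_weights(q_nodes, noise_fwhm)
  P <- sweep(noise_sd * .smooth_curves(n_patients, q_nodes, noise_fwhm, W),
             2L, base + bump, `+`)
  C <- sweep(noise_sd * .smooth_curves(n_controls, q_nodes, noise_fwhm, W),
             2L, base, `+`)
  list(patients = P, controls = C, nodes = nodes, true_effect = bump)
}
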