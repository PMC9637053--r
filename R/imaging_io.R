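# Imaging and tabular I/O: fat-fraction slices, muscle masks, cohort CSV.

#' Construct a fat-fraction slice
#'
#' A `fat_fraction_slice` holds a 2D grid of per-pixel fat infiltration
#' percentages (FI%, 0-100) for one subject at one spinal level. Pixels
#' outside the body, or without signal, carry `NA` and are excluded from
#' every downstream mean.
#'
#' @param values Numeric matrix of FI% per pixel; `NA` marks missing.
#' @param pixel_spacing In-plane pixel size in mm (isotropic assumed).
#' @param subject_id Subject identifier.
#' @param level Spinal level label; the study design fixes `"L4L5"`.
#' @return An object of class `fat_fraction_slice`.
#' @export
fat_fraction_slice <- function(values, pixel_spacing = 1,
                               subject_id = NA_character_, level = "L4L5") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (any(dim(values) < 2L))
    stop("fat-fraction grid must be at least 2x2")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      is.na(pixel_spacing) || pixel_spacing <= 0)
    stop("`pixel_spacing` must be a single positive number")
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 100))
    stop("non-missing FI values must lie in [0, 100]")
  structure(
    list(values = values, pixel_spacing = pixel_spacing,
         subject_id = as.character(subject_id), level = level),
    class = "fat_fraction_slice")
}

#' @export
print.fat_fraction_slice <- function(x, ...) {
  cat(sprintf("<fat_fraction_slice> subject %s, level %s, %d x %d px @ %.3g mm\n",
              x$subject_id, x$level, nrow(x$values), ncol(x$values),
              x$pixel_spacing))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  FI%% range %.1f-%.1f over %d non-missing pixels\n",
                min(v), max(v), length(v)))
  invisible(x)
}

#' Construct a muscle mask
#'
#' @param mask Logical (or 0/1 numeric) matrix marking the pixels of one
#'   muscle; must match the paired fat-fraction grid in shape.
#' @param muscle One of `r paste0('\x60', FATMAP_MUSCLES, '\x60', collapse = ", ")`.
#' @param side `"left"`, `"right"`, or `"merged"` (both sides in one mask).
#' @return An object of class `muscle_mask`; masks with zero true pixels
#'   are flagged `usable = FALSE` with a warning rather than rejected, so
#'   a cohort read can proceed and drop them later.
#' @export
muscle_mask <- function(mask, muscle, side = "merged") {
  muscle <- match.arg(muscle, FATMAP_MUSCLES)
  side <- match.arg(side, .fatmap_sides)
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  if (is.numeric(mask)) mask <- mask >= 0.5
  if (!is.logical(mask)) stop("`mask` must be logical or numeric")
  mask[is.na(mask)] <- FALSE
  usable <- any(mask)
  if (!usable)
    warning(sprintf("mask for %s (%s) has no true pixels; flagged unusable",
                    muscle, side))
  structure(list(mask = mask, muscle = muscle, side = side, usable = usable),
            class = "muscle_mask")
}

#' Compute a fat-fraction image from water and fat channels
#'
#' Applies the standard water-fat convention FI% = 100 * F / (F + W) per
#' pixel. Pixels where both channels are zero (no signal: air,
#' background) are marked missing.
#'
#' @param water,fat Non-negative numeric matrices of equal shape.
#' @inheritParams fat_fraction_slice
#' @return A [fat_fraction_slice()].
#' @examples
#' compute_fat_fraction(matrix(2, 2, 2), matrix(2, 2, 2))$values  # all 50
#' @export
compute_fat_fraction <- function(water, fat, pixel_spacing = 1,
                                 subject_id = NA_character_, level = "L4L5") {
  if (!is.matrix(water) || !is.matrix(fat))
    stop("`water` and `fat` must be matrices")
  if (!identical(dim(water), dim(fat)))
    stop("`water` and `fat` must have the same shape")
  if (any(water < 0, na.rm = TRUE) || any(fat < 0, na.rm = TRUE))
    stop("negative channel values are not allowed")
  total <- water + fat
  ff <- 100 * fat / total
  ff[!is.na(total) & total == 0] <- NA_real_
  fat_fraction_slice(ff, pixel_spacing = pixel_spacing,
                     subject_id = subject_id, level = level)
}

# --- file readers/writers ---------------------------------------------------

.read_raster <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("nii", "hdr", "img")) {
    img <- RNifti::readNifti(path)
    list(values = as.array(img)[, , drop = TRUE],
         spacing = RNifti::pixdim(img)[1])
  } else if (ext == "png") {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) v <- v[, , 1L]   # collapse grayscale-with-alpha
    list(values = v, spacing = NA_real_)
  } else stop("unsupported image format: ", path)
}

#' Read a fat-fraction image from disk
#'
#' NIfTI images (`.nii`, `.nii.gz`) are read as-is, with pixel spacing
#' taken from the header. PNG images are read as grayscale in \code{[0, 1]}
#' and multiplied by the `scale` recorded in a JSON sidecar
#' (`<path>.json`, default scale 100); PNG storage is quantized, so
#' NIfTI is the lossless interchange format.
#'
#' @param path Image file.
#' @inheritParams fat_fraction_slice
#' @return A [fat_fraction_slice()].
#' @export
read_fi_slice <- function(path, subject_id = NA_character_, level = "L4L5",
                          pixel_spacing = NULL) {
  r <- .read_raster(path)
  vals <- r$values
  if (tolower(tools::file_ext(path)) == "png") {
    scale <- 100
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      if (!is.null(meta$scale)) scale <- as.numeric(meta$scale)
      if (is.null(pixel_spacing) && !is.null(meta$pixel_spacing))
        pixel_spacing <- as.numeric(meta$pixel_spacing)
    }
    vals <- vals * scale
  }
  if (is.null(pixel_spacing))
    pixel_spacing <- if (is.na(r$spacing) || r$spacing <= 0) 1 else r$spacing
  fat_fraction_slice(vals, pixel_spacing = pixel_spacing,
                     subject_id = subject_id, level = level)
}

#' Write a fat-fraction slice as NIfTI
#'
#' Values are stored as doubles so that a write/read round trip is exact;
#' missing pixels are stored as NaN.
#'
#' @param slice A [fat_fraction_slice()].
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_fi_slice <- function(slice, path) {
  stopifnot(inherits(slice, "fat_fraction_slice"))
  img <- RNifti::asNifti(slice$values)
  RNifti::pixdim(img) <- rep(slice$pixel_spacing, 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a muscle mask from disk
#'
#' Grayscale rasters are binarized at 0.5 (NIfTI in native units, PNG in
#' \code{[0, 1]} times 1, i.e. any half-intensity pixel counts as muscle).
#'
#' @param path NIfTI or PNG file.
#' @inheritParams muscle_mask
#' @return A [muscle_mask()].
#' @export
read_muscle_mask <- function(path, muscle, side = "merged") {
  r <- .read_raster(path)
  muscle_mask(r$values >= 0.5, muscle = muscle, side = side)
}

#' Read and validate a cohort metadata table
#'
#' One subject per row. Required columns: `subject_id` (unique), `group`
#' (`"patient"`/`"control"`). Recognized optional columns: `vas` (0-10),
#' `odi` (0-100), `cep_damage`, `modic` (logical/0-1), `pfirrmann`
#' (integer 1-5), `age`, `sex`, `bmi`, disc endpoints
#' (`posterior_row`, `posterior_col`, `anterior_row`, `anterior_col`)
#' and file-path columns (`image`, `mask_<muscle>[_<side>]`).
#'
#' @param path CSV file with a header row.
#' @return A `data.frame` (classed `cohort_table`).
#' @export
read_cohort_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_table(tab)
}

#' @rdname read_cohort_table
#' @param tab A data frame to validate in place.
#' @export
validate_cohort_table <- function(tab) {
  if (!all(c("subject_id", "group") %in% names(tab)))
    stop("cohort table needs `subject_id` and `group` columns")
  if (anyDuplicated(tab$subject_id))
    stop("duplicated subject_id in cohort table")
  if (any(is.na(tab$group)) || !all(tab$group %in% c("patient", "control")))
    stop("`group` must be 'patient' or 'control' for every subject")
  for (col in c("cep_damage", "modic"))
    if (col %in% names(tab)) tab[[col]] <- as.logical(tab[[col]])
  if ("vas" %in% names(tab)) {
    bad <- !is.na(tab$vas) & (tab$vas < 0 | tab$vas > 10)
    if (any(bad)) stop("VAS scores out of range [0, 10]")
  }
  if ("pfirrmann" %in% names(tab)) {
    bad <- !is.na(tab$pfirrmann) & !(tab$pfirrmann %in% 1:5)
    if (any(bad)) stop("Pfirrmann grades must be integers 1-5")
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Read one subject's image and masks as a validated bundle
#'
#' @param image_path Path to the fat-fraction image.
#' @param mask_paths Named character vector of mask files; names are
#'   `<muscle>` or `<muscle>_<side>`, e.g. `"multifidus"` or
#'   `"erector_spinae_left"`.
#' @param metadata_row Optional single-row data frame (e.g. one row of a
#'   [read_cohort_table()] result) supplying `subject_id`.
#' @return `list(slice = fat_fraction_slice, masks = list of muscle_mask)`.
#'   Empty masks are kept but flagged unusable (with a warning).
#' @export
read_slice_bundle <- function(image_path, mask_paths, metadata_row = NULL) {
  subject_id <- if (!is.null(metadata_row) && "subject_id" %in% names(metadata_row))
    metadata_row$subject_id else NA_character_
  slice <- read_fi_slice(image_path, subject_id = subject_id)
  if (is.null(names(mask_paths)) || any(names(mask_paths) == ""))
    stop("`mask_paths` must be a named vector (<muscle>[_<side>])")
  masks <- lapply(seq_along(mask_paths), function(i) {
    nm <- names(mask_paths)[i]
    side <- "merged"
    muscle <- nm
    for (s in c("left", "right")) {
      suf <- paste0("_", s)
      if (endsWith(nm, suf)) {
        side <- s
        muscle <- substr(nm, 1L, nchar(nm) - nchar(suf))
      }
    }
    if (!muscle %in% FATMAP_MUSCLES)
      stop("unknown muscle label in mask name: ", nm)
    m <- read_muscle_mask(mask_paths[[i]], muscle = muscle, side = side)
    if (!identical(dim(m$mask), dim(slice$values)))
      stop(sprintf("mask %s shape (%s) does not match image shape (%s)",
                   nm, paste(dim(m$mask), collapse = "x"),
                   paste(dim(slice$values), collapse = "x")))
    m
  })
  names(masks) <- names(mask_paths)
  list(slice = slice, masks = masks)
}
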