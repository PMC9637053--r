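# Disc geometry: centre of rotation of the L4L5 motion segment and
# pixel-to-CoR distance fields.

#' Disc geometry: endpoints of the mid-sagittal AP diameter
#'
#' Coordinates are continuous `(row, col)` pixel positions, 1-based,
#' origin top-left (see the package coordinate convention).
#'
#' @param posterior,anterior Numeric length-2 `(row, col)` positions of
#'   the posterior and anterior edges of the disc's mid-sagittal
#'   anteroposterior diameter.
#' @return An object of class `disc_geometry`.
#' @export
disc_geometry <- function(posterior, anterior) {
  posterior <- as.numeric(posterior); anterior <- as.numeric(anterior)
  if (length(posterior) != 2L || length(anterior) != 2L ||
      anyNA(posterior) || anyNA(anterior))
    stop("disc endpoints must be numeric (row, col) pairs")
  if (all(posterior == anterior))
    stop("posterior and anterior disc points coincide")
  structure(list(posterior = posterior, anterior = anterior),
            class = "disc_geometry")
}

#' Locate the centre of rotation of the motion segment
#'
#' The CoR is approximated at the centre of the posterior quarter of the
#' disc's mid-sagittal AP diameter, i.e. 12.5% of the way from the
#' posterior to the anterior endpoint. Sub-pixel positions are allowed.
#'
#' @param disc A [disc_geometry()].
#' @return A `cor_point`: numeric `(row, col)` with class attribute.
#' @examples
#' locate_cor(disc_geometry(c(0, 0), c(80, 0)))  # (10, 0)
#' @export
locate_cor <- function(disc) {
  stopifnot(inherits(disc, "disc_geometry"))
  p <- disc$posterior + 0.125 * (disc$anterior - disc$posterior)
  structure(p, class = "cor_point", names = c("row", "col"))
}

#' Euclidean distance from every pixel centre to the CoR
#'
#' @param shape Integer length-2 grid dimensions `(nrow, ncol)`.
#' @param cor A `cor_point` (or numeric `(row, col)`).
#' @return Numeric matrix of distances in pixel units. Pixel centres sit
#'   at integer `(row, col)` coordinates.
#' @export
distance_map <- function(shape, cor) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("`shape` must be two positive integers")
  cor <- as.numeric(cor)
  dr <- (seq_len(shape[1L]) - cor[1L])^2
  dc <- (seq_len(shape[2L]) - cor[2L])^2
  sqrt(outer(dr, dc, `+`))
}
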