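# Base-graphics views of fat-maps and SPM results.

#' @export
plot.normalized_profile <- function(x, ...) {
  graphics::plot(x$nodes, x$fi, type = "l", xlab = "radial width (%)",
                 ylab = "FI (%)",
                 main = sprintf("%s fat-map", x$muscle), ...)
  invisible(x)
}

#' Plot an SPM t-field with its critical threshold and clusters
#'
#' @param x An `spm_result` from [spm_ttest2()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spm_result <- function(x, ...) {
  f <- x$field
  graphics::plot(f$nodes, f$t, type = "l", xlab = "radial width (%)",
                 ylab = "SPM{t}", main = x$comparison, ...)
  graphics::abline(h = c(-1, 1) * f$t_star, lty = 2)
  if (nrow(x$clusters))
    for (i in seq_len(nrow(x$clusters)))
      graphics::rect(x$clusters$start_percent[i], graphics::par("usr")[3],
                     x$clusters$end_percent[i], graphics::par("usr")[4],
                     col = grDevices::adjustcolor("grey", 0.4), border = NA)
  invisible(x)
}
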