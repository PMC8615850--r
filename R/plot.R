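# Base-graphics diagnostics.

#' Plot an angular intensity profile
#'
#' @param x an [angular_profile()].
#' @param candidates optional bearings (degrees) drawn as vertical lines.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.angular_profile <- function(x, candidates = NULL, ...) {
  graphics::plot(x$angles_deg, x$intensities_HU, type = "l",
                 xlab = "bearing from anterior (deg)", ylab = "HU",
                 main = sprintf("angular profile, r = %.1f mm", x$radius_mm),
                 ...)
  if (!is.null(candidates))
    graphics::abline(v = norm_deg360(candidates), lty = 2,
                     col = "firebrick")
  invisible(x)
}

#' Display a resampled CT slice
#'
#' @param x a `ct_slice` from [resample_plane()].
#' @param threshold optional HU level drawn as a contour (e.g. 2000 for the
#'   metal binarization).
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.ct_slice <- function(x, threshold = NULL, ...) {
  graphics::image(x$u_mm, x$v_mm, x$values, asp = 1,
                  col = grDevices::gray.colors(128),
                  xlab = "u (mm)", ylab = "v (mm)", ...)
  if (!is.null(threshold))
    graphics::contour(x$u_mm, x$v_mm, x$values, levels = threshold,
                      add = TRUE, col = "firebrick", drawlabels = FALSE)
  invisible(x)
}
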