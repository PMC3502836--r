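#' Calibrate a two-channel field
#'
#' Estimates the background of each channel as a low quantile of a
#' box-smoothed copy (smoothing suppresses the shot/read-noise tail that
#' would otherwise bias a pixelwise low quantile downward), subtracts it,
#' and scales by a fixed reference level rather than by the image's own
#' maximum — a dim image therefore stays dim, which is what makes the
#' positive/negative intensity cutoff meaningful.
#'
#' @param fitc FITC (antibody) channel, numeric matrix, non-negative.
#' @param counterstain counterstain channel, same shape.
#' @param bg_quantile quantile used for the background estimate.
#' @param ref_level fixed full-scale reference the channels are divided by
#'   after background subtraction (fraction of the dynamic range a strongly
#'   positive nucleus reaches).
#' @param smooth_radius half-width of the box filter used for background
#'   estimation, in px.
#' @return object of class `calibrated_image`: `fitc_norm` and
#'   `counterstain_norm` clipped to \[0,1\], plus per-channel
#'   `background` estimates.
#' @export
calibrate <- function(fitc, counterstain, bg_quantile = 0.05,
                      ref_level = 0.75, smooth_radius = 4) {
  if (!is.matrix(fitc) || !is.matrix(counterstain) ||
      !all(dim(fitc) == dim(counterstain)))
    stopf("channels must be matrices of identical shape")
  if (min(fitc) < 0 || min(counterstain) < 0)
    stopf("channel intensities must be non-negative")
  bg <- function(x) {
    k <- 2 * smooth_radius + 1
    br <- matrix(1 / k^2, k, k)
    stats::quantile(EBImage::filter2(x, br, boundary = "replicate"),
                    bg_quantile, names = FALSE)
  }
  b_f <- bg(fitc)
  b_c <- bg(counterstain)
  structure(
    list(fitc_norm = clip01((fitc - b_f) / ref_level),
         counterstain_norm = clip01((counterstain - b_c) / ref_level),
         background = c(fitc = b_f, counterstain = b_c)),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %dx%d px, background fitc %.4f / counterstain %.4f\n",
              nrow(x$fitc_norm), ncol(x$fitc_norm),
              x$background["fitc"], x$background["counterstain"]))
  invisible(x)
}
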