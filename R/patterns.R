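#' HEp-2 staining pattern taxonomy
#'
#' The seven pattern classes reported in routine HEp-2 ANA screening:
#' six positive morphologies plus `negative`. Order is fixed and is the
#' tie-break order used by the k-NN classifier.
#'
#' @return character vector of the seven class labels.
#' @export
#' @examples
#' pattern_classes()
pattern_classes <- function() {
  c("homogeneous", "speckled", "nucleolar", "centromeres",
    "nuclear_dots", "cytoplasmic", "negative")
}

#' Positive pattern classes
#'
#' The six classes a positive sample can display; `negative` is decided by
#' image intensity, never by the pattern classifier.
#'
#' @return character vector of six labels.
#' @export
positive_classes <- function() setdiff(pattern_classes(), "negative")

assert_patterns <- function(labels) {
  bad <- setdiff(labels, pattern_classes())
  if (length(bad) > 0)
    stopf("unknown pattern class(es): %s", paste(bad, collapse = ", "))
  if ("negative" %in% labels && length(labels) > 1)
    stopf("'negative' may not co-occur with other patterns")
  invisible(labels)
}

#' Default acquisition-noise model
#'
#' Parameters of the simulated camera: constant background level, a weak
#' linear illumination gradient (the LED illumination of slide scanners is
#' nearly flat), Poisson photon noise at a fixed conversion gain and Gaussian
#' read noise. All levels are fractions of the 16-bit full scale.
#'
#' @param background mean background level.
#' @param gradient peak-to-centre amplitude of the illumination plane.
#' @param read_sd read-noise standard deviation.
#' @param photon logical; apply Poisson photon noise.
#' @param photons photons corresponding to full scale (shot-noise strength).
#' @return named list of noise parameters.
#' @export
noise_model <- function(background = 0.05, gradient = 0.002,
                        read_sd = 0.005, photon = TRUE, photons = 800) {
  stopifnot(background >= 0, gradient >= 0, read_sd >= 0, photons > 0)
  list(background = background, gradient = gradient,
       read_sd = read_sd, photon = isTRUE(photon), photons = photons)
}

#' Specify a synthetic HEp-2 field
#'
#' Bundles everything needed to render one two-channel field: the pattern
#' mixture with relative strengths, the sample's true endpoint titer, the
#' dilution the field is imaged at, cell counts and geometry, and the noise
#' model. The mean antibody amplitude of the rendered FITC signal follows
#' [dilution_amplitude()], so the last dilution at which a field still
#' reads positive recovers the titer (endpoint reading).
#'
#' @param patterns named numeric vector mapping pattern class to relative
#'   strength in (0, 1]; e.g. `c(speckled = 1)` or
#'   `c(homogeneous = 1, nucleolar = 0.5)`. Use `c(negative = 1)` with
#'   `titer = 0` for a negative sample.
#' @param titer reciprocal endpoint titer (1000 means 1:1000); 0 for negative.
#' @param dilution reciprocal serum dilution the field is imaged at.
#' @param n_cells number of cells to place.
#' @param mitotic_fraction fraction of cells rendered as mitotic figures,
#'   in \[0, 0.2\].
#' @param image_shape integer vector (rows, cols) in pixels.
#' @param noise a [noise_model()].
#' @param seed integer seed; identical specs render bit-identical fields.
#' @return object of class `field_spec`.
#' @export
#' @examples
#' field_spec(c(speckled = 1), titer = 1000, dilution = 100,
#'            n_cells = 20, image_shape = c(256, 256), seed = 1)
field_spec <- function(patterns, titer, dilution = 100, n_cells = 60,
                       mitotic_fraction = 0.08,
                       image_shape = c(1024, 1024),
                       noise = noise_model(), seed = 1) {
  if (is.null(names(patterns)) || any(names(patterns) == ""))
    stopf("'patterns' must be a named numeric vector")
  assert_patterns(names(patterns))
  if (any(patterns <= 0 | patterns > 1))
    stopf("pattern strengths must lie in (0, 1]")
  if (!is_count(n_cells)) stopf("n_cells must be a non-negative count")
  if (!is.numeric(dilution) || dilution < 1) stopf("dilution must be >= 1")
  if (!is.numeric(titer) || titer < 0) stopf("titer must be >= 0")
  if ("negative" %in% names(patterns) && titer != 0)
    stopf("a negative pattern requires titer = 0")
  if (mitotic_fraction < 0 || mitotic_fraction > 0.2)
    stopf("mitotic_fraction must lie in [0, 0.2]")
  if (length(image_shape) != 2 || any(image_shape < 32))
    stopf("image_shape must be (rows, cols), each >= 32 px")
  structure(
    list(patterns = patterns, titer = titer, dilution = dilution,
         n_cells = as.integer(n_cells),
         mitotic_fraction = mitotic_fraction,
         image_shape = as.integer(image_shape),
         noise = noise, seed = as.integer(seed)),
    class = "field_spec")
}

#' @export
print.field_spec <- function(x, ...) {
  cat("<field_spec> ", paste(sprintf("%s(%.2g)", names(x$patterns), x$patterns),
                             collapse = " + "),
      sprintf("\n  titer 1:%g imaged at 1:%g | %d cells (%.0f%% mitotic) | %dx%d px | seed %d\n",
              x$titer, x$dilution, x$n_cells, 100 * x$mitotic_fraction,
              x$image_shape[1], x$image_shape[2], x$seed))
  invisible(x)
}
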