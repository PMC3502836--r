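# End-to-end convenience wrappers: field -> well result, series -> report.

#' Evaluate one field through the full pipeline
#'
#' Calibration, counterstain segmentation, normalized-intensity
#' positive/negative call, per-cell k-NN pattern classification (positives
#' only), and rule-based aggregation into one per-dilution result.
#'
#' @param field a `labeled_field` (or any list with `fitc` and
#'   `counterstain` matrices).
#' @param db a `reference_db`.
#' @param cutoff positive/negative intensity cutoff.
#' @param k neighbour count.
#' @param min_fraction mixed-pattern reporting threshold.
#' @param dilution reciprocal dilution of the field; defaults to the
#'   field's own spec when present.
#' @return a `well_result`.
#' @export
#' @examples
#' \donttest{
#' db <- build_reference_db(40, seed = 11, n_cells_per_field = 12,
#'                          image_shape = c(384, 384))
#' f <- render_field(field_spec(c(speckled = 1), titer = 1000, dilution = 100,
#'                              n_cells = 12, image_shape = c(384, 384),
#'                              seed = 99))
#' evaluate_field(f, db)
#' }
evaluate_field <- function(field, db, cutoff = 0.15, k = db$k_default,
                           min_fraction = 0.25,
                           dilution = if (!is.null(field$spec)) field$spec$dilution else 100) {
  cal <- calibrate(field$fitc, field$counterstain)
  regions <- segment_field(cal)
  intensity <- normalized_image_intensity(cal, regions)
  positive <- classify_pos_neg(intensity, cutoff)
  cells <- if (positive && nrow(regions) > 0) {
    feats <- extract_features_all(cal, regions)
    classify_cells(feats, db, k)
  } else {
    tibble::tibble(cell = integer(), label = character(),
                   confidence = double())
  }
  aggregate_cell_results(cells, positive, intensity,
                         dilution = dilution, min_fraction = min_fraction)
}

#' Evaluate a dilution series into a patient report
#'
#' @param fields list of fields ordered by increasing dilution (e.g. from
#'   [render_dilution_series()]).
#' @param db a `reference_db`.
#' @param screening_dilution reciprocal screening dilution.
#' @param sample sample identifier.
#' @inheritParams evaluate_field
#' @return a `patient_report`.
#' @export
evaluate_series <- function(fields, db, screening_dilution = 100,
                            sample = "sample", cutoff = 0.15,
                            k = db$k_default, min_fraction = 0.25) {
  wells <- purrr::map(fields, evaluate_field, db = db, cutoff = cutoff,
                      k = k, min_fraction = min_fraction)
  merge_patient(wells, screening_dilution, sample = sample)
}
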