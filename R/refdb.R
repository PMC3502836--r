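#' Build a labelled reference database from synthetic fields
#'
#' Renders single-pattern fields for each of the six positive classes at the
#' screening dilution and full amplitude, segments them, extracts per-cell
#' features, and stores `n_per_pattern` labelled records per class together
#' with per-feature normalization statistics. Reference cells are interphase
#' only (mitoses carry no pattern vote). Deterministic for a given seed.
#'
#' @param n_per_pattern records per positive class.
#' @param seed integer seed; choose seeds disjoint from any evaluation
#'   fields.
#' @param image_shape,n_cells_per_field geometry of the rendered donor
#'   fields.
#' @param noise a [noise_model()].
#' @param k_default default neighbour count stored with the database.
#' @return a `reference_db`.
#' @export
build_reference_db <- function(n_per_pattern, seed = 1,
                               image_shape = c(512, 512),
                               n_cells_per_field = 24,
                               noise = noise_model(), k_default = 9) {
  if (!is_count(n_per_pattern) || n_per_pattern < 1)
    stopf("n_per_pattern must be a positive count")
  feats <- list()
  labels <- character()
  for (cls in positive_classes()) {
    got <- 0L
    fidx <- 0L
    cls_feats <- list()
    while (got < n_per_pattern) {
      fidx <- fidx + 1L
      if (fidx > ceiling(4 * n_per_pattern / n_cells_per_field) + 4)
        stopf("segmentation yielded too few cells for class '%s'", cls)
      spec <- field_spec(stats::setNames(1, cls), titer = 1000, dilution = 100,
                         n_cells = n_cells_per_field, mitotic_fraction = 0,
                         image_shape = image_shape, noise = noise,
                         seed = child_seed(seed, "refdb", cls, fidx) %% 2000000000L)
      fld <- render_field(spec)
      cal <- calibrate(fld$fitc, fld$counterstain)
      regions <- segment_field(cal)
      if (nrow(regions) == 0 && fidx > 2)
        stopf("segmentation yielded zero cells for class '%s'", cls)
      if (nrow(regions) == 0) next
      ft <- extract_features_all(cal, regions)
      ft <- ft[!ft$mitotic, , drop = FALSE]
      cls_feats[[length(cls_feats) + 1]] <- ft
      got <- got + nrow(ft)
    }
    all <- dplyr::bind_rows(cls_feats)[seq_len(n_per_pattern), ]
    feats[[cls]] <- as.matrix(all[, feature_names()])
    labels <- c(labels, rep(cls, n_per_pattern))
  }
  new_reference_db(do.call(rbind, feats), labels, k_default = k_default)
}

#' Write a reference database to plain-text files
#'
#' One CSV row per cell (`label` + features) plus a JSON header carrying the
#' feature list, normalization statistics, default k and the feature-set
#' version, so a database/query feature mismatch is detectable.
#'
#' @param db a `reference_db`.
#' @param csv_path,header_path output paths; `header_path` defaults to the
#'   CSV path with extension `.json`.
#' @return `csv_path`, invisibly.
#' @export
write_reference_db <- function(db, csv_path,
                               header_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(db, "reference_db"))
  df <- data.frame(label = db$labels, db$features, check.names = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE)
  header <- list(feature_version = db$feature_version,
                 features = feature_names(),
                 centre = as.list(db$centre), scale = as.list(db$scale),
                 k_default = db$k_default)
  jsonlite::write_json(header, header_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Read a reference database written by [write_reference_db()]
#'
#' @inheritParams write_reference_db
#' @return a `reference_db`.
#' @export
read_reference_db <- function(csv_path,
                              header_path = sub("\\.csv$", ".json", csv_path)) {
  header <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  if (!identical(header$feature_version, FEATURE_SET_VERSION))
    stopf("database feature set '%s' does not match this package ('%s')",
          header$feature_version, FEATURE_SET_VERSION)
  df <- utils::read.csv(csv_path, check.names = FALSE)
  db <- new_reference_db(as.matrix(df[, header$features]), df$label,
                         k_default = header$k_default)
  db$centre <- unlist(header$centre)
  db$scale <- unlist(header$scale)
  db
}
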