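#' Normalized image fluorescence intensity
#'
#' One scalar per field: the median over non-mitotic cells of the mean
#' calibrated FITC intensity over each cell's nucleus-plus-cytoplasm region.
#' This is the quantity the positive/negative cutoff is applied to and the
#' sort key of the negative worklist. Returns 0 when no (non-mitotic) cells
#' are present.
#'
#' @param cal a [calibrate()]d image.
#' @param regions region tibble from [segment_field()].
#' @return scalar in \[0, 1\].
#' @export
normalized_image_intensity <- function(cal, regions) {
  stopifnot(inherits(cal, "calibrated_image"))
  use <- regions[!regions$mitotic, , drop = FALSE]
  if (nrow(use) == 0) return(0)
  per_cell <- purrr::map_dbl(seq_len(nrow(use)), function(i) {
    px <- c(use$nucleus[[i]], use$cytoplasm[[i]])
    mean(cal$fitc_norm[px])
  })
  stats::median(per_cell)
}

#' Positive/negative call from normalized intensity
#'
#' A field is positive when its normalized intensity reaches the configured
#' cutoff (inclusive boundary). The cutoff is a laboratory configuration
#' parameter; 0.15 is the recommended basic setup used throughout the
#' package.
#'
#' @param intensity scalar from [normalized_image_intensity()].
#' @param cutoff positive/negative intensity cutoff, strictly inside (0, 1).
#' @return logical.
#' @export
classify_pos_neg <- function(intensity, cutoff = 0.15) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 ||
      cutoff <= 0 || cutoff >= 1)
    stopf("cutoff must lie strictly inside (0, 1)")
  intensity >= cutoff
}

new_reference_db <- function(features, labels, k_default = 9) {
  stopifnot(nrow(features) == length(labels))
  if ("negative" %in% labels)
    stopf("the reference database may not contain negative-class records")
  centre <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale < 1e-12] <- 1  # constant features carry no distance
  structure(
    list(features = features, labels = labels,
         centre = centre, scale = scale,
         k_default = as.integer(k_default),
         feature_version = FEATURE_SET_VERSION),
    class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d cells x %d features (%s), k default %d\n",
              nrow(x$features), ncol(x$features), x$feature_version,
              x$k_default))
  print(table(x$labels))
  invisible(x)
}

#' Classify one cell by k-nearest neighbours
#'
#' Features are z-scored by the database's normalization statistics,
#' neighbours found by Euclidean distance, and the label decided by
#' plurality vote among the k nearest. Ties are broken by the smaller total
#' distance of each tied class's voters, then by the fixed class order of
#' [pattern_classes()]. Confidence is winning votes / k.
#'
#' @param fv named feature vector from [extract_features()].
#' @param db a `reference_db`.
#' @param k neighbour count, 1 <= k <= records.
#' @return list of class `cell_classification`: `label`, `confidence`,
#'   `votes` (named integer vector over the voted classes).
#' @export
knn_classify_cell <- function(fv, db, k = db$k_default) {
  stopifnot(inherits(db, "reference_db"))
  if (length(fv) != ncol(db$features))
    stopf("feature length %d does not match database (%d features, %s)",
          length(fv), ncol(db$features), db$feature_version)
  if (k < 1 || k > nrow(db$features))
    stopf("k must lie in [1, %d]", nrow(db$features))
  z <- (as.numeric(fv) - db$centre) / db$scale
  zdb <- sweep(sweep(db$features, 2, db$centre), 2, db$scale, "/")
  d <- sqrt(rowSums(sweep(zdb, 2, z)^2))
  ord <- order(d)[seq_len(k)]
  lab <- db$labels[ord]
  votes <- table(lab)
  top <- max(votes)
  tied <- names(votes)[votes == top]
  if (length(tied) > 1) {
    tot <- vapply(tied, function(cl) sum(d[ord][lab == cl]), numeric(1))
    tied <- tied[tot == min(tot)]
    if (length(tied) > 1)
      tied <- tied[order(match(tied, pattern_classes()))]
  }
  structure(list(label = tied[1], confidence = as.numeric(top) / k,
                 votes = stats::setNames(as.integer(votes), names(votes))),
            class = "cell_classification")
}

#' Classify every non-mitotic cell of a field
#'
#' Mitotic cells are excluded from pattern voting; their homogeneous-type
#' chromatin staining status is recorded separately for the report.
#'
#' @param feats feature tibble from [extract_features_all()].
#' @param db a `reference_db`.
#' @param k neighbour count.
#' @return tibble: `cell`, `label`, `confidence`.
#' @export
classify_cells <- function(feats, db, k = db$k_default) {
  use <- feats[!feats$mitotic, , drop = FALSE]
  if (nrow(use) == 0)
    return(tibble::tibble(cell = integer(), label = character(),
                          confidence = double()))
  fmat <- as.matrix(use[, feature_names()])
  purrr::map_dfr(seq_len(nrow(use)), function(i) {
    cc <- knn_classify_cell(fmat[i, ], db, k)
    tibble::tibble(cell = use$cell[i], label = cc$label,
                   confidence = cc$confidence)
  })
}
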