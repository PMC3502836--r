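# Shared fixtures, built once per test run. All synthetic; seeds used for
# evaluation fields are disjoint from the reference-database seed stream.

.fixtures <- new.env(parent = emptyenv())

# reference database: 60 interphase cells per positive class
fixture_db <- function() {
  if (is.null(.fixtures$db))
    .fixtures$db <- build_reference_db(60, seed = 1,
                                       image_shape = c(512, 512),
                                       n_cells_per_field = 24)
  .fixtures$db
}

single_field <- function(cls, seed, n_cells = 16, titer = 1000,
                         dilution = 100, shape = c(512, 512), ...) {
  render_field(field_spec(stats::setNames(1, cls), titer = titer,
                          dilution = dilution, n_cells = n_cells,
                          image_shape = shape, seed = seed, ...))
}

# greedy IoU matching of predicted masks against truth masks
match_masks <- function(pred, truth, iou_min = 0.5) {
  if (length(pred) == 0 || length(truth) == 0) return(0L)
  iou <- matrix(0, length(pred), length(truth))
  for (i in seq_along(pred)) for (j in seq_along(truth)) {
    inter <- length(intersect(pred[[i]], truth[[j]]))
    if (inter > 0)
      iou[i, j] <- inter / (length(pred[[i]]) + length(truth[[j]]) - inter)
  }
  matched <- 0L
  while (TRUE) {
    m <- which.max(iou)
    if (iou[m] < iou_min) break
    matched <- matched + 1L
    i <- (m - 1) %% nrow(iou) + 1
    j <- (m - 1) %/% nrow(iou) + 1
    iou[i, ] <- -1
    iou[, j] <- -1
  }
  matched
}

# a synthetic calibrated image with one disc-shaped cell, for closed-form
# feature checks
disc_region_fixture <- function(value = 0.5, radius = 12, shape = c(64, 64),
                                cyto_value = 0) {
  img <- matrix(0, shape[1], shape[2])
  centre <- shape / 2
  d2 <- outer((seq_len(shape[1]) - centre[1])^2,
              (seq_len(shape[2]) - centre[2])^2, "+")
  nuc <- which(d2 <= radius^2)
  ring <- which(d2 > radius^2 & d2 <= (radius + 5)^2)
  img[nuc] <- value
  img[ring] <- cyto_value
  cal <- structure(list(fitc_norm = img,
                        counterstain_norm = img,
                        background = c(fitc = 0, counterstain = 0)),
                   class = "calibrated_image")
  list(cal = cal,
       region = tibble::tibble(cell = 1L, centroid_row = centre[1] - 1,
                               centroid_col = centre[2] - 1,
                               area = length(nuc), mitotic = FALSE,
                               nucleus = list(nuc), cytoplasm = list(ring)))
}

cli_script <- function() {
  p <- system.file("cli", "ana.R", package = "anapattern")
  stopifnot(nzchar(p))
  p
}

run_cli <- function(...) {
  out <- system2(file.path(R.home("bin"), "Rscript"), c(cli_script(), ...),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("CLI failed: ", paste(out, collapse = "\n"))
  invisible(out)
}
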