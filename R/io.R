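# Plain-file interfaces: two-page 16-bit TIFF per field (page 1 FITC,
# page 2 counterstain) plus a JSON sidecar carrying the generating spec and
# per-cell truth; masks as run-length encodings over the column-major linear
# pixel index, 0-based, half-open [start, start + length).

rle_encode <- function(idx) {
  if (length(idx) == 0)
    return(list(starts = integer(), lengths = integer()))
  idx <- sort(as.integer(idx)) - 1L  # 0-based
  breaks <- which(diff(idx) != 1L)
  starts <- idx[c(1L, breaks + 1L)]
  ends <- idx[c(breaks, length(idx))]
  list(starts = starts, lengths = ends - starts + 1L)
}

rle_decode <- function(starts, lengths) {
  if (length(starts) == 0) return(integer())
  as.integer(unlist(purrr::map2(starts, lengths, ~ seq.int(.x, .x + .y - 1L)))) + 1L
}

#' Write a labelled field to disk
#'
#' Writes `<stem>.tiff` (two-page 16-bit: FITC then counterstain) and
#' `<stem>.json` (field spec and per-cell truth with run-length-encoded
#' masks). Byte-stable for identical fields.
#'
#' @param field a `labeled_field`.
#' @param stem output path without extension.
#' @return the TIFF path, invisibly.
#' @export
write_field <- function(field, stem) {
  stopifnot(inherits(field, "labeled_field"))
  tiff_path <- paste0(stem, ".tiff")
  tiff::writeTIFF(list(field$fitc, field$counterstain), tiff_path,
                  bits.per.sample = 16, compression = "none")
  truth <- purrr::map(seq_len(nrow(field$truth)), function(i) {
    r <- field$truth[i, ]
    enc <- rle_encode(r$pixels[[1]])
    list(cell = r$cell, centroid_row = r$centroid_row,
         centroid_col = r$centroid_col, area = r$area, label = r$label,
         mitotic = r$mitotic, mask_rle = enc)
  })
  spec <- field$spec
  sidecar <- list(
    spec = list(patterns = as.list(spec$patterns), titer = spec$titer,
                dilution = spec$dilution, n_cells = spec$n_cells,
                mitotic_fraction = spec$mitotic_fraction,
                image_shape = spec$image_shape, noise = spec$noise,
                seed = spec$seed),
    index_convention = "column-major linear index, 0-based, runs half-open",
    truth = truth)
  jsonlite::write_json(sidecar, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' Read a labelled field written by [write_field()]
#'
#' @param stem path stem used when writing.
#' @return a `labeled_field`.
#' @export
read_field <- function(stem) {
  pages <- tiff::readTIFF(paste0(stem, ".tiff"), all = TRUE)
  sc <- jsonlite::read_json(paste0(stem, ".json"))
  sp <- sc$spec
  spec <- field_spec(unlist(sp$patterns), titer = sp$titer,
                     dilution = sp$dilution, n_cells = sp$n_cells,
                     mitotic_fraction = sp$mitotic_fraction,
                     image_shape = unlist(sp$image_shape),
                     noise = do.call(noise_model, sp$noise[setdiff(names(sp$noise), character())]),
                     seed = sp$seed)
  truth <- purrr::map_dfr(sc$truth, function(r)
    tibble::tibble(cell = r$cell, centroid_row = r$centroid_row,
                   centroid_col = r$centroid_col, area = r$area,
                   label = r$label, mitotic = r$mitotic,
                   pixels = list(rle_decode(unlist(r$mask_rle$starts),
                                            unlist(r$mask_rle$lengths)))))
  if (length(sc$truth) == 0)
    truth <- tibble::tibble(cell = integer(), centroid_row = double(),
                            centroid_col = double(), area = integer(),
                            label = character(), mitotic = logical(),
                            pixels = list())
  structure(list(fitc = quantize16(pages[[1]]),
                 counterstain = quantize16(pages[[2]]),
                 truth = truth, spec = spec),
            class = "labeled_field")
}

#' Write segmentation output
#'
#' Writes a 16-bit label image (`0` background, `i` for cell `i`) and a
#' per-cell CSV (`id`, `centroid_row`, `centroid_col`, `area`, `mitotic`).
#'
#' @param regions region tibble from [segment_field()].
#' @param shape image shape (rows, cols).
#' @param stem output path stem.
#' @return the CSV path, invisibly.
#' @export
write_segmentation <- function(regions, shape, stem) {
  lab <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(nrow(regions))) lab[regions$nucleus[[i]]] <- regions$cell[i]
  tiff::writeTIFF(lab / 65535, paste0(stem, "_labels.tiff"),
                  bits.per.sample = 16, compression = "none")
  df <- data.frame(id = regions$cell, centroid_row = regions$centroid_row,
                   centroid_col = regions$centroid_col, area = regions$area,
                   mitotic = regions$mitotic)
  csv <- paste0(stem, "_cells.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  invisible(csv)
}

#' Serialize a result to JSON
#'
#' Deterministic JSON writers for `well_result` and `patient_report`
#' objects (identical inputs give byte-identical files).
#'
#' @param x a `well_result` or `patient_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(result_to_list(x), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

result_to_list <- function(x) {
  if (inherits(x, "well_result")) {
    list(dilution = x$dilution, positive = x$positive,
         intensity = x$intensity, n_cells = x$n_cells, status = x$status,
         patterns = purrr::map(seq_len(nrow(x$patterns)), function(i)
           list(label = x$patterns$label[i],
                confidence = x$patterns$confidence[i],
                support = x$patterns$support[i])))
  } else if (inherits(x, "patient_report")) {
    list(sample = x$sample, overall_positive = x$overall_positive,
         main_pattern = if (is.na(x$main_pattern)) NULL else x$main_pattern,
         confidence = if (is.na(x$confidence)) NULL else x$confidence,
         status = x$status,
         patterns = purrr::map(seq_len(nrow(x$patterns)), function(i)
           list(label = x$patterns$label[i],
                titer = if (x$patterns$titer_censored[i])
                  paste0(">=", x$patterns$titer[i]) else x$patterns$titer[i],
                confidence = x$patterns$confidence[i])),
         wells = purrr::map(x$wells, result_to_list))
  } else stopf("cannot serialize a %s", class(x)[1])
}

#' Read a well result written by [write_result_json()]
#'
#' @param path JSON path.
#' @return a `well_result`.
#' @export
read_well_json <- function(path) {
  j <- jsonlite::read_json(path)
  pats <- purrr::map_dfr(j$patterns, tibble::as_tibble)
  if (length(j$patterns) == 0)
    pats <- tibble::tibble(label = character(), confidence = double(),
                           support = double())
  structure(list(dilution = j$dilution, positive = j$positive,
                 intensity = j$intensity, n_cells = j$n_cells,
                 status = j$status, patterns = pats),
            class = "well_result")
}
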