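# Counterstain-driven segmentation: every nucleus is counterstained whether
# or not the serum reacts, so cell finding never depends on the antibody
# channel — a weak or failed FITC signal cannot silently lose cells.

#' Segment nuclei from the calibrated counterstain channel
#'
#' Global Otsu threshold, hole filling, watershed split of touching nuclei
#' seeded from distance-transform maxima, then an area filter. Deterministic.
#'
#' @param counterstain_norm calibrated counterstain matrix in \[0,1\].
#' @param min_area,max_area retained object area bounds, px.
#' @param tolerance watershed minimum object depth on the distance map, px.
#' @return list of nucleus masks, each an integer vector of linear pixel
#'   indices; empty list when nothing is found.
#' @export
segment_nuclei <- function(counterstain_norm, min_area = 200,
                           max_area = 8000, tolerance = 3) {
  stopifnot(is.matrix(counterstain_norm))
  rng <- range(counterstain_norm)
  if (diff(rng) < 1e-6) return(list())
  thr <- EBImage::otsu(EBImage::Image(counterstain_norm), range = c(0, 1))
  bin <- EBImage::fillHull(counterstain_norm > thr)
  if (sum(bin) == 0) return(list())
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  lab <- EBImage::imageData(lab)
  n <- max(lab)
  if (n == 0) return(list())
  idx <- split(seq_along(lab), factor(lab[seq_along(lab)], levels = 1:n))
  idx <- idx[lengths(idx) >= min_area & lengths(idx) <= max_area]
  unname(lapply(idx, as.integer))
}

mask_centroid <- function(idx, nr) {
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  c(mean(rows), mean(cols))
}

#' Derive per-cell measurement regions
#'
#' The cytoplasmic compartment is approximated as a perinuclear annulus:
#' morphological dilation of each nucleus by `dilate_radius`, minus the
#' pixels of every nucleus. Needed because the cytoplasmic pattern stains
#' outside the nucleus. Regions are ordered by centroid (row, col).
#'
#' @param nucleus_masks list of linear-index masks from [segment_nuclei()].
#' @param counterstain_norm the channel the masks came from (shape source).
#' @param dilate_radius annulus width, px.
#' @return tibble with one row per cell: `cell`, 0-based
#'   `centroid_row`/`centroid_col`, `area`, `mitotic` (all `FALSE` here; see
#'   [identify_mitoses()]) and list-columns `nucleus`, `cytoplasm` of linear
#'   pixel indices.
#' @export
define_cell_regions <- function(nucleus_masks, counterstain_norm,
                                dilate_radius = 6) {
  shape <- dim(counterstain_norm)
  empty <- tibble::tibble(cell = integer(), centroid_row = double(),
                          centroid_col = double(), area = integer(),
                          mitotic = logical(), nucleus = list(),
                          cytoplasm = list())
  if (length(nucleus_masks) == 0) return(empty)

  all_nuc <- matrix(FALSE, shape[1], shape[2])
  for (m in nucleus_masks) all_nuc[m] <- TRUE
  brush <- EBImage::makeBrush(2 * dilate_radius + 1, "disc")

  rows <- purrr::imap(nucleus_masks, function(m, i) {
    # dilate within the padded bounding box only
    mr <- (m - 1L) %% shape[1] + 1L
    mc <- (m - 1L) %/% shape[1] + 1L
    r0 <- max(1L, min(mr) - dilate_radius); r1 <- min(shape[1], max(mr) + dilate_radius)
    c0 <- max(1L, min(mc) - dilate_radius); c1 <- min(shape[2], max(mc) + dilate_radius)
    nucm <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    nucm[cbind(mr - r0 + 1L, mc - c0 + 1L)] <- TRUE
    dil <- EBImage::dilate(nucm, brush) > 0
    loc <- which(dil)
    lr <- (loc - 1L) %% nrow(nucm) + r0
    lc <- (loc - 1L) %/% nrow(nucm) + c0
    glob <- (lc - 1L) * shape[1] + lr
    cyto <- glob[!all_nuc[glob]]
    cen <- mask_centroid(m, shape[1])
    tibble::tibble(cell = i, centroid_row = cen[1] - 1,
                   centroid_col = cen[2] - 1, area = length(m),
                   mitotic = FALSE,
                   nucleus = list(sort(as.integer(m))),
                   cytoplasm = list(sort(as.integer(cyto))))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$centroid_row, .data$centroid_col)
  out$cell <- seq_len(nrow(out))
  out
}

#' Flag mitotic figures
#'
#' A region is called mitotic when its mean in-nucleus counterstain is at
#' least `brightness_factor` times the median over all nuclei (condensed
#' chromatin binds more DNA dye) and its area is at most `area_factor` times
#' the median area. With fewer than 3 regions the statistics are meaningless
#' and nothing is flagged.
#'
#' @param regions tibble from [define_cell_regions()].
#' @param counterstain_norm calibrated counterstain matrix.
#' @param brightness_factor,area_factor rule thresholds.
#' @return `regions` with the `mitotic` column set; order preserved.
#' @export
identify_mitoses <- function(regions, counterstain_norm,
                             brightness_factor = 1.5, area_factor = 0.8) {
  if (nrow(regions) < 3) {
    regions$mitotic <- rep(FALSE, nrow(regions))
    return(regions)
  }
  bright <- purrr::map_dbl(regions$nucleus,
                           ~ mean(counterstain_norm[.x]))
  med_b <- stats::median(bright)
  med_a <- stats::median(regions$area)
  regions$mitotic <- bright >= brightness_factor * med_b &
    regions$area <= area_factor * med_a
  regions
}

#' Segment a field end to end
#'
#' Convenience wrapper: [segment_nuclei()], [define_cell_regions()],
#' [identify_mitoses()] on a calibrated image.
#'
#' @param cal a [calibrate()]d image.
#' @param ... passed to [segment_nuclei()] and [define_cell_regions()].
#' @inheritParams segment_nuclei
#' @inheritParams define_cell_regions
#' @return region tibble (see [define_cell_regions()]).
#' @export
segment_field <- function(cal, min_area = 200, max_area = 8000,
                          dilate_radius = 6) {
  stopifnot(inherits(cal, "calibrated_image"))
  masks <- segment_nuclei(cal$counterstain_norm,
                          min_area = min_area, max_area = max_area)
  regions <- define_cell_regions(masks, cal$counterstain_norm,
                                 dilate_radius = dilate_radius)
  identify_mitoses(regions, cal$counterstain_norm)
}
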