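# Per-cell feature extraction for pattern recognition.
#
# 62 features per cell, in a fixed documented order shared by the reference
# database and every query. Intensity statistics are computed on the
# calibrated scale and deliberately carry the antibody amplitude; texture
# features (GLCM, LBP, granulometry, edges, bright-area fraction) are
# computed on a per-cell min-max normalized nucleus crop so pattern identity
# is insensitive to titer/dilution scaling. Blob detection alone stays on
# the unstretched (contrast-preserving) crop: a near-uniform fill must not
# grow blobs just because normalization amplified its residual relief.

FEATURE_SET_VERSION <- "anapattern-fv1"

#' Feature names of the per-cell feature vector
#'
#' Fixed order: 7 nuclear intensity statistics (mean, sd, skewness, kurtosis,
#' quantiles 10/50/90), the same 7 for the perinuclear cytoplasm annulus, the
#' nucleus/cytoplasm mean ratio, 16 grey-level co-occurrence features
#' (contrast, correlation, energy, homogeneity at offsets E, S, SE, SW),
#' 20 uniform local-binary-pattern histogram bins (radius 1 and 2), a
#' 6-scale granulometry spectrum, 3 Laplacian-of-Gaussian blob statistics
#' (count, mean scale, mean prominence), edge density, and the fraction of
#' nuclear area above 50% of the nuclear maximum.
#'
#' @return character vector of length 62.
#' @export
feature_names <- function() {
  stats7 <- c("mean", "sd", "skew", "kurt", "q10", "q50", "q90")
  c(paste0("nuc_", stats7),
    paste0("cyto_", stats7),
    "nc_ratio",
    paste0("glcm_", rep(c("contrast", "correlation", "energy", "homogeneity"),
                        each = 4), "_o", rep(1:4, times = 4)),
    paste0("lbp_r1_b", 0:9),
    paste0("lbp_r2_b", 0:9),
    paste0("granulo_s", 1:6),
    "blob_count", "blob_mean_scale", "blob_mean_prominence",
    "edge_density", "frac_above_half")
}

intensity_stats <- function(v) {
  if (length(v) == 0) return(rep(0, 7))
  s <- stats::sd(v)
  c(mean(v),
    if (is.na(s)) 0 else s,
    if (is.na(s) || s < 1e-12) 0 else e1071::skewness(v),
    if (is.na(s) || s < 1e-12) 0 else e1071::kurtosis(v),
    stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE))
}

# grey-level co-occurrence features on a masked crop, `levels` grey levels,
# symmetric accumulation at the 4 standard offsets
glcm_features <- function(crop, mask, levels = 16) {
  q <- matrix(NA_integer_, nrow(crop), ncol(crop))
  q[mask] <- pmin(levels, floor(crop[mask] * levels) + 1L)
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  out <- matrix(0, 4, 4)  # rows: contrast, correlation, energy, homogeneity
  ij <- (0:(levels - 1))
  for (o in seq_along(offsets)) {
    dr <- offsets[[o]][1]; dc <- offsets[[o]][2]
    nr <- nrow(q); nc <- ncol(q)
    r_a <- max(1, 1 - dr):min(nr, nr - dr)
    c_a <- max(1, 1 - dc):min(nc, nc - dc)
    a <- q[r_a, c_a, drop = FALSE]
    b <- q[r_a + dr, c_a + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) next
    cm <- matrix(0, levels, levels)
    tab <- table(factor(a[ok], levels = 1:levels),
                 factor(b[ok], levels = 1:levels))
    cm <- cm + tab + t(tab)          # symmetric GLCM
    p <- cm / sum(cm)
    pi_ <- rowSums(p)
    mu <- sum(ij * pi_)
    s2 <- sum((ij - mu)^2 * pi_)
    dmat <- outer(ij, ij, "-")
    out[1, o] <- sum(dmat^2 * p)                           # contrast
    out[2, o] <- if (s2 < 1e-12) 0 else
      sum(outer(ij - mu, ij - mu) * p) / s2                # correlation
    out[3, o] <- sum(p^2)                                  # energy
    out[4, o] <- sum(p / (1 + abs(dmat)))                  # homogeneity
  }
  as.numeric(t(out))  # feature-major: contrast o1..o4, correlation o1..o4, ...
}

# uniform LBP (8 neighbours) histogram: 9 uniform-pattern bins (0..8 ones)
# + 1 non-uniform bin, normalized
lbp_hist <- function(crop, mask, radius) {
  ang <- 2 * pi * (0:7) / 8
  drc <- cbind(round(-radius * sin(ang)), round(radius * cos(ang)))
  nr <- nrow(crop); nc <- ncol(crop)
  cand <- which(mask, arr.ind = TRUE)
  keep <- cand[, 1] > radius & cand[, 1] <= nr - radius &
    cand[, 2] > radius & cand[, 2] <= nc - radius
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(rep(0, 10))
  centre <- crop[cand]
  bits <- matrix(0L, nrow(cand), 8)
  for (k in 1:8)
    bits[, k] <- (crop[cbind(cand[, 1] + drc[k, 1], cand[, 2] + drc[k, 2])] >=
                    centre) * 1L
  trans <- rowSums(abs(bits - bits[, c(2:8, 1)]))
  ones <- rowSums(bits)
  bin <- ifelse(trans <= 2, ones, 9L)  # uniform patterns keyed by #ones
  h <- tabulate(bin + 1L, nbins = 10)
  h / sum(h)
}

# granulometry: loss of in-mask mass under morphological opening with discs
# of increasing radius, normalized by total mass
granulometry <- function(crop, mask, radii = 1:6) {
  img <- crop
  img[!mask] <- 0
  tot <- sum(img)
  if (tot < 1e-9) return(rep(0, length(radii)))
  prev <- img
  out <- numeric(length(radii))
  for (i in seq_along(radii)) {
    op <- EBImage::opening(img, EBImage::makeBrush(2 * radii[i] + 1, "disc"))
    op <- pmin(op, prev)
    out[i] <- (sum(prev) - sum(op)) / tot
    prev <- op
  }
  out
}

log_kernel <- function(sigma) {
  h <- ceiling(3 * sigma)
  g <- outer(-h:h, -h:h, function(r, c) exp(-(r^2 + c^2) / (2 * sigma^2)))
  g <- g / sum(g)
  rc2 <- outer((-h:h)^2, (-h:h)^2, "+")
  k <- g * (rc2 - 2 * sigma^2) / sigma^4
  k - mean(k)
}

# scale-normalized LoG blob detection within the mask; expects the crop on
# the calibrated (contrast-preserving) scale so smooth low-relief fills do
# not register as blobs
blob_stats <- function(crop, mask, sigmas = c(1.5, 2.5, 4, 6),
                       threshold = 0.08) {
  img <- crop
  img[!mask] <- 0
  # pad so the largest kernel always fits
  h <- ceiling(3 * max(sigmas)) + 1
  padded <- matrix(0, nrow(img) + 2 * h, ncol(img) + 2 * h)
  padded[h + seq_len(nrow(img)), h + seq_len(ncol(img))] <- img
  pmask <- matrix(FALSE, nrow(padded), ncol(padded))
  pmask[h + seq_len(nrow(img)), h + seq_len(ncol(img))] <- mask
  img <- padded; mask <- pmask
  responses <- lapply(sigmas, function(s)
    -s^2 * EBImage::filter2(img, log_kernel(s), boundary = 0))
  blobs <- list()
  for (si in seq_along(sigmas)) {
    r <- responses[[si]]
    nr <- nrow(r); nc <- ncol(r)
    if (nr < 3 || nc < 3) next
    inner <- r[2:(nr - 1), 2:(nc - 1)]
    ismax <- inner >= threshold & mask[2:(nr - 1), 2:(nc - 1)]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      ismax <- ismax & inner >= r[2:(nr - 1) + dr, 2:(nc - 1) + dc]
    }
    # dominant over neighbouring scales
    for (sj in c(si - 1, si + 1)) {
      if (sj < 1 || sj > length(sigmas)) next
      ismax <- ismax & inner >= responses[[sj]][2:(nr - 1), 2:(nc - 1)]
    }
    w <- which(ismax)
    if (length(w) > 0)
      blobs[[length(blobs) + 1]] <-
        cbind(scale = sigmas[si], prominence = inner[w])
  }
  if (length(blobs) == 0) return(c(0, 0, 0))
  all <- do.call(rbind, blobs)
  c(nrow(all), mean(all[, "scale"]), mean(all[, "prominence"]))
}

#' Extract the per-cell feature vector
#'
#' Computes the 62 features of [feature_names()] for one cell of a
#' calibrated field. Deterministic; all values finite.
#'
#' @param cal a [calibrate()]d image.
#' @param region one-row slice of the region tibble from
#'   [define_cell_regions()] (or a list with `nucleus` and `cytoplasm`
#'   index vectors).
#' @return named numeric vector, order matching [feature_names()].
#' @export
extract_features <- function(cal, region) {
  stopifnot(inherits(cal, "calibrated_image"))
  nuc <- if (is.list(region$nucleus)) region$nucleus[[1]] else region$nucleus
  cyto <- if (is.list(region$cytoplasm)) region$cytoplasm[[1]] else region$cytoplasm
  if (length(nuc) < 25)
    stopf("cell %s: nucleus area %d px is below the feature window",
          if (!is.null(region$cell)) region$cell[[1]] else "?", length(nuc))
  img <- cal$fitc_norm
  nr <- nrow(img)

  v_nuc <- img[nuc]
  v_cyto <- img[cyto]

  # nucleus crop, min-max normalized for the texture features
  rows <- (nuc - 1L) %% nr + 1L
  cols <- (nuc - 1L) %/% nr + 1L
  r0 <- min(rows); c0 <- min(cols)
  crop <- matrix(0, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
  mask <- matrix(FALSE, nrow(crop), ncol(crop))
  loc <- cbind(rows - r0 + 1L, cols - c0 + 1L)
  mask[loc] <- TRUE
  rngv <- range(v_nuc)
  z <- if (diff(rngv) < 1e-9) rep(0, length(v_nuc)) else
    (v_nuc - rngv[1]) / diff(rngv)
  crop[loc] <- z
  # contrast-preserving crop (background-anchored, not stretched) for blobs
  raw_crop <- matrix(0, nrow(crop), ncol(crop))
  raw_crop[loc] <- v_nuc - rngv[1]

  sob <- EBImage::filter2(crop, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 4,
                          boundary = "replicate")
  sob_t <- EBImage::filter2(crop, t(matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)) / 4,
                            boundary = "replicate")
  grad <- sqrt(sob^2 + sob_t^2)

  out <- c(
    intensity_stats(v_nuc),
    intensity_stats(v_cyto),
    mean(v_nuc) / (mean(v_cyto) + 1e-6),
    glcm_features(crop, mask),
    lbp_hist(crop, mask, 1),
    lbp_hist(crop, mask, 2),
    granulometry(crop, mask),
    blob_stats(raw_crop, mask),
    mean(grad[mask] > 0.25),
    mean(z > 0.5)
  )
  out[!is.finite(out)] <- 0
  stats::setNames(out, feature_names())
}

#' Extract features for every non-degenerate cell of a field
#'
#' @param cal a [calibrate()]d image.
#' @param regions region tibble from [segment_field()].
#' @return tibble: `cell`, `mitotic`, then one column per feature.
#' @export
extract_features_all <- function(cal, regions) {
  if (nrow(regions) == 0)
    return(tibble::as_tibble(c(list(cell = integer(), mitotic = logical()),
                               stats::setNames(rep(list(double()), 62),
                                               feature_names()))))
  fv <- purrr::map(seq_len(nrow(regions)),
                   ~ extract_features(cal, regions[.x, ]))
  dplyr::bind_cols(
    tibble::tibble(cell = regions$cell, mitotic = regions$mitotic),
    tibble::as_tibble(do.call(rbind, fv)))
}
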