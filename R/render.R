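# Synthetic two-channel HEp-2 field rendering.
#
# Geometry (cell layout, per-cell pattern detail) is drawn from a sub-seed
# that depends only on the field seed, while acquisition noise is drawn from
# a sub-seed that also includes the dilution. A dilution series therefore
# shows the same cells under the amplitude law s = min(1, titer/dilution)
# with fresh camera noise per acquisition.

#' Antibody amplitude at a given dilution
#'
#' Mean FITC amplitude of a sample with endpoint titer `titer` imaged at
#' `dilution`: `min(1, titer/dilution) / (1 + dilution/(20 * titer))`.
#' The saturating first factor makes the endpoint (last positive dilution)
#' recover the titer; the soft mass-action shoulder makes the signal
#' strictly decreasing in dilution even below the endpoint, as serial IIF
#' dilutions visibly fade well before they extinguish.
#'
#' @param titer reciprocal endpoint titer (0 for a negative sample).
#' @param dilution reciprocal dilution, >= 1.
#' @return amplitude scalar in \[0, 1\], strictly decreasing in `dilution`
#'   for `titer > 0`.
#' @export
dilution_amplitude <- function(titer, dilution) {
  if (titer <= 0) return(0)
  min(1, titer / dilution) / (1 + dilution / (20 * titer))
}

NUCLEUS_RADIUS_RANGE <- c(14, 20)   # semi-major axis, px
NUCLEUS_AXIS_RATIO   <- c(0.70, 1.00)
MITOTIC_SCALE        <- 0.75        # mitotic figures are smaller ...
MITOTIC_GAIN         <- 2.0         # ... and brighter in the counterstain
COUNTERSTAIN_BASE    <- 0.45
CYTO_SCALE           <- 1.35        # cytoplasm ellipse relative to nucleus

# pixels of an ellipse centred at (cr, cc); returns linear indices plus the
# local elliptic radius u in [0,1] for profile shading
ellipse_pixels <- function(cr, cc, a, b, theta, shape) {
  r0 <- max(1L, floor(cr - a)); r1 <- min(shape[1], ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(shape[2], ceiling(cc + a))
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - cr, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cc)
  x <- dr * cos(theta) + dc * sin(theta)
  y <- -dr * sin(theta) + dc * cos(theta)
  u2 <- (x / a)^2 + (y / b)^2
  keep <- which(u2 <= 1)
  idx <- as.integer(outer(rows, (cols - 1L) * shape[1], "+"))[keep]
  list(idx = idx, u = sqrt(u2[keep]),
       rows = rep(rows, times = length(cols))[keep],
       cols = rep(cols, each = length(rows))[keep])
}

# smooth multiplicative texture over a pixel set, via blurred uniform noise
# on the bounding box
smooth_texture <- function(px, sigma = 2) {
  r0 <- min(px$rows); c0 <- min(px$cols)
  nr <- max(px$rows) - r0 + 1L; nc <- max(px$cols) - c0 + 1L
  k <- 2 * ceiling(2 * sigma) + 1
  raw <- matrix(stats::runif(max(nr, k) * max(nc, k)), max(nr, k), max(nc, k))
  br <- EBImage::makeBrush(k, "gaussian", sigma = sigma)
  sm <- EBImage::filter2(raw, br)
  v <- sm[cbind(px$rows - r0 + 1L, px$cols - c0 + 1L)]
  rng <- range(v)
  if (diff(rng) < 1e-12) rep(0.5, length(v)) else (v - rng[1]) / diff(rng)
}

# draw n points uniformly inside the ellipse, shrunk by `inner`
ellipse_points <- function(n, cr, cc, a, b, theta, inner = 0.75) {
  u <- sqrt(stats::runif(n)) * inner
  ang <- stats::runif(n, 0, 2 * pi)
  x <- u * a * cos(ang); y <- u * b * sin(ang)
  cbind(row = cr + x * cos(theta) - y * sin(theta),
        col = cc + x * sin(theta) + y * cos(theta))
}

# add Gaussian-profile dots into the field matrix
paint_dots <- function(fitc, centers, radii, amp, shape) {
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    ext <- ceiling(2.2 * r)
    r0 <- max(1L, floor(centers[i, 1] - ext)); r1 <- min(shape[1], ceiling(centers[i, 1] + ext))
    c0 <- max(1L, floor(centers[i, 2] - ext)); c1 <- min(shape[2], ceiling(centers[i, 2] + ext))
    rows <- r0:r1; cols <- c0:c1
    d2 <- outer((rows - centers[i, 1])^2, (cols - centers[i, 2])^2, "+")
    prof <- amp * exp(-d2 / (2 * (r / 1.6)^2))
    idx <- as.integer(outer(rows, (cols - 1L) * shape[1], "+"))
    fitc[idx] <- pmax(fitc[idx], prof)
  }
  fitc
}

place_cells <- function(spec) {
  n <- spec$n_cells
  shape <- spec$image_shape
  a <- stats::runif(n, NUCLEUS_RADIUS_RANGE[1], NUCLEUS_RADIUS_RANGE[2])
  ratio <- stats::runif(n, NUCLEUS_AXIS_RATIO[1], NUCLEUS_AXIS_RATIO[2])
  theta <- stats::runif(n, 0, pi)
  mitotic <- rep(FALSE, n)
  if (n > 0 && spec$mitotic_fraction > 0) {
    n_mit <- round(spec$mitotic_fraction * n)
    if (n_mit > 0) mitotic[sample.int(n, n_mit)] <- TRUE
  }
  a[mitotic] <- a[mitotic] * MITOTIC_SCALE
  b <- a * ratio

  # per-cell dominant pattern ~ Multinomial(relative strengths)
  pats <- names(spec$patterns)
  if (identical(pats, "negative") || spec$titer == 0) {
    label <- rep("negative", n)
  } else if (length(pats) == 1) {
    label <- rep(pats, n)
  } else {
    label <- sample(pats, n, replace = TRUE, prob = spec$patterns)
  }

  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  max_tries <- 400L * max(n, 1L)
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stopf("could not place %d non-overlapping cells of radius ~%d px in a %dx%d image",
            n, round(mean(NUCLEUS_RADIUS_RANGE)), shape[1], shape[2])
    i <- placed + 1L
    m <- a[i] * CYTO_SCALE + 2
    cand <- c(stats::runif(1, m, shape[1] - m), stats::runif(1, m, shape[2] - m))
    ok <- TRUE
    if (placed > 0) {
      d <- sqrt((centers[1:placed, 1] - cand[1])^2 + (centers[1:placed, 2] - cand[2])^2)
      ok <- all(d >= a[1:placed] + a[i] + 6)
    }
    if (ok) {
      centers[i, ] <- cand
      placed <- i
    }
  }
  list(centers = centers, a = a, b = b, theta = theta,
       mitotic = mitotic, label = label)
}

# paint one cell's FITC pattern; amp already includes dilution scaling and
# the pattern's relative strength
render_cell_fitc <- function(fitc, px, cyto_px, cell, amp, shape) {
  if (amp <= 0 || cell$label == "negative") return(fitc)
  lab <- cell$label
  mit <- cell$mitotic
  if (lab == "homogeneous") {
    tex <- smooth_texture(px, sigma = 4)
    gain <- if (mit) 1.15 else 1
    fitc[px$idx] <- pmax(fitc[px$idx], amp * gain * (0.82 + 0.08 * tex))
  } else if (lab == "speckled") {
    if (mit) return(fitc)  # speckled antigens spare condensed chromatin
    tex <- smooth_texture(px, sigma = 1.2)
    val <- amp * (0.12 + 0.88 * tex^1.3)
    fitc[px$idx] <- pmax(fitc[px$idx], val)
    # nucleoli spared: 2 dark holes
    holes <- ellipse_points(2, cell$cr, cell$cc, cell$a, cell$b, cell$theta, 0.55)
    for (h in seq_len(nrow(holes))) {
      d <- sqrt((px$rows - holes[h, 1])^2 + (px$cols - holes[h, 2])^2)
      dark <- d < 3.5
      fitc[px$idx[dark]] <- amp * 0.10
    }
  } else if (lab == "nucleolar") {
    if (mit) return(fitc)
    fitc[px$idx] <- pmax(fitc[px$idx], amp * 0.25)
    nb <- sample(2:5, 1)
    ctr <- ellipse_points(nb, cell$cr, cell$cc, cell$a, cell$b, cell$theta, 0.55)
    fitc <- paint_dots(fitc, ctr, stats::runif(nb, 4.5, 6.5), amp, shape)
  } else if (lab == "centromeres") {
    # centromere antigens also decorate the mitotic plate
    fitc[px$idx] <- pmax(fitc[px$idx], amp * 0.25)
    nd <- sample(30:50, 1)
    ctr <- ellipse_points(nd, cell$cr, cell$cc, cell$a, cell$b, cell$theta, 0.85)
    fitc <- paint_dots(fitc, ctr, stats::runif(nd, 1.2, 1.8), amp, shape)
  } else if (lab == "nuclear_dots") {
    if (mit) return(fitc)
    fitc[px$idx] <- pmax(fitc[px$idx], amp * 0.25)
    nd <- sample(4:10, 1)
    ctr <- ellipse_points(nd, cell$cr, cell$cc, cell$a, cell$b, cell$theta, 0.7)
    fitc <- paint_dots(fitc, ctr, stats::runif(nd, 2.5, 3.5), amp, shape)
  } else if (lab == "cytoplasmic") {
    tex <- smooth_texture(cyto_px, sigma = 2)
    fitc[cyto_px$idx] <- pmax(fitc[cyto_px$idx], amp * 0.7 * (0.75 + 0.25 * tex))
    fitc[px$idx] <- amp * 0.05  # nucleus reads dark
  }
  fitc
}

apply_acquisition_noise <- function(signal, noise, shape) {
  # illumination plane: weak linear gradient with random orientation
  ang <- stats::runif(1, 0, 2 * pi)
  rr <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / shape[1]
  cc <- (seq_len(shape[2]) - (shape[2] + 1) / 2) / shape[2]
  plane <- noise$gradient * 2 * (outer(rr, rep(1, shape[2])) * cos(ang) +
                                 outer(rep(1, shape[1]), cc) * sin(ang))
  x <- clip01(signal + noise$background + plane)
  if (noise$photon)
    x <- stats::rpois(length(x), x * noise$photons) / noise$photons
  if (noise$read_sd > 0)
    x <- x + stats::rnorm(length(x), 0, noise$read_sd)
  matrix(quantize16(x), shape[1], shape[2])
}

#' Render a synthetic two-channel HEp-2 field
#'
#' Places non-overlapping elliptical nuclei by rejection sampling, paints the
#' counterstain channel (all nuclei; mitotic figures smaller and about twice
#' as bright, emulating condensed chromatin), and paints the FITC antibody
#' channel according to each cell's pattern at amplitude
#' `dilution_amplitude(titer, dilution) * strength`. Identical specs render
#' bit-identical images.
#'
#' @param spec a [field_spec()].
#' @return object of class `labeled_field`: list with numeric matrices
#'   `fitc` and `counterstain` (values in \[0,1\] on a 16-bit grid), a `truth`
#'   tibble (one row per cell: `cell`, 0-based `centroid_row`/`centroid_col`,
#'   `area`, `label`, `mitotic`, and a `pixels` list-column of linear pixel
#'   indices), and the generating `spec`.
#' @export
#' @examples
#' f <- render_field(field_spec(c(nucleolar = 1), titer = 1000, dilution = 100,
#'                              n_cells = 8, image_shape = c(256, 256), seed = 3))
#' f$truth
render_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  shape <- spec$image_shape

  layout <- withr::with_seed(child_seed(spec$seed, "geom"), place_cells(spec))

  s <- dilution_amplitude(spec$titer, spec$dilution)

  fitc_sig <- matrix(0, shape[1], shape[2])
  counter_sig <- matrix(0, shape[1], shape[2])
  truth <- vector("list", spec$n_cells)

  withr::with_seed(child_seed(spec$seed, "paint"), {
    for (i in seq_len(spec$n_cells)) {
      cell <- list(cr = layout$centers[i, 1], cc = layout$centers[i, 2],
                   a = layout$a[i], b = layout$b[i], theta = layout$theta[i],
                   mitotic = layout$mitotic[i], label = layout$label[i])
      px <- ellipse_pixels(cell$cr, cell$cc, cell$a, cell$b, cell$theta, shape)
      cyto_all <- ellipse_pixels(cell$cr, cell$cc, cell$a * CYTO_SCALE,
                                 cell$b * CYTO_SCALE, cell$theta, shape)
      keep <- !(cyto_all$idx %in% px$idx)
      cyto_px <- list(idx = cyto_all$idx[keep], u = cyto_all$u[keep],
                      rows = cyto_all$rows[keep], cols = cyto_all$cols[keep])

      base <- COUNTERSTAIN_BASE * stats::rnorm(1, 1, 0.06)
      gain <- if (cell$mitotic) MITOTIC_GAIN else 1
      ctex <- smooth_texture(px, sigma = 2.5)
      counter_sig[px$idx] <- pmax(counter_sig[px$idx],
                                  base * gain * (0.88 + 0.24 * ctex))

      amp <- s * unname(spec$patterns[cell$label])
      if (cell$label == "negative") amp <- 0
      fitc_sig <- render_cell_fitc(fitc_sig, px, cyto_px, cell, amp, shape)

      truth[[i]] <- tibble::tibble(
        cell = i,
        centroid_row = layout$centers[i, 1] - 1,
        centroid_col = layout$centers[i, 2] - 1,
        area = length(px$idx),
        label = layout$label[i], mitotic = layout$mitotic[i],
        pixels = list(sort(px$idx)))
    }
  })

  withr::with_seed(child_seed(spec$seed, "noise", spec$dilution), {
    fitc <- apply_acquisition_noise(fitc_sig, spec$noise, shape)
    counterstain <- apply_acquisition_noise(counter_sig, spec$noise, shape)
  })

  truth <- if (spec$n_cells > 0) dplyr::bind_rows(truth) else
    tibble::tibble(cell = integer(), centroid_row = double(),
                   centroid_col = double(), area = integer(),
                   label = character(), mitotic = logical(), pixels = list())

  structure(list(fitc = fitc, counterstain = counterstain,
                 truth = truth, spec = spec),
            class = "labeled_field")
}

#' @export
print.labeled_field <- function(x, ...) {
  cat(sprintf("<labeled_field> %dx%d px, %d cells (%d mitotic), patterns: %s\n",
              nrow(x$fitc), ncol(x$fitc), nrow(x$truth), sum(x$truth$mitotic),
              paste(unique(x$truth$label), collapse = ", ")))
  invisible(x)
}

#' Render a dilution series of one sample
#'
#' Renders one field per requested dilution with the cell layout and pattern
#' detail held fixed (same geometry sub-seed) and fresh acquisition noise per
#' dilution. Mean antibody amplitude follows [dilution_amplitude()], so the
#' series fades strictly with dilution and the endpoint titer is
#' recoverable.
#'
#' @param spec a [field_spec()]; its `dilution` field is overridden.
#' @param dilutions strictly increasing reciprocal dilutions, each >= 1.
#' @return list of `labeled_field`, in the order of `dilutions`.
#' @export
render_dilution_series <- function(spec, dilutions) {
  stopifnot(inherits(spec, "field_spec"))
  if (length(dilutions) == 0) stopf("at least one dilution is required")
  if (any(dilutions < 1)) stopf("dilutions must be >= 1")
  if (length(dilutions) > 1 && any(diff(dilutions) <= 0))
    stopf("dilutions must be strictly increasing")
  purrr::map(dilutions, function(d) {
    s <- spec
    s$dilution <- d
    render_field(s)
  })
}
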