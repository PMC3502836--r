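test_that("calibration handles zero input and removes constant offsets", {
  z <- matrix(0, 64, 64)
  cal <- calibrate(z, z)
  expect_equal(cal$fitc_norm, z)
  expect_equal(unname(cal$background), c(0, 0))

  f <- single_field("speckled", seed = 21, n_cells = 6, shape = c(256, 256))
  cal1 <- calibrate(f$fitc, f$counterstain)
  cal2 <- calibrate(f$fitc + 0.1, f$counterstain + 0.1)
  expect_equal(cal2$fitc_norm, cal1$fitc_norm, tolerance = 1e-12)

  expect_error(calibrate(matrix(0, 4, 4), matrix(0, 5, 5)), "shape")
  expect_error(calibrate(matrix(-1, 4, 4), matrix(0, 4, 4)), "non-negative")
})

test_that("calibration recovers the configured background within 10%", {
  for (seed in c(31, 32)) {
    f <- single_field("homogeneous", seed = seed, n_cells = 12,
                      shape = c(384, 384))
    cal <- calibrate(f$fitc, f$counterstain)
    b <- f$spec$noise$background
    expect_lt(abs(cal$background["fitc"] - b) / b, 0.10)
    expect_lt(abs(cal$background["counterstain"] - b) / b, 0.10)
  }
})

test_that("nucleus segmentation finds nothing on a blank image and one disc", {
  expect_identical(segment_nuclei(matrix(0, 128, 128)), list())

  img <- matrix(0, 128, 128)
  d2 <- outer((1:128 - 60.3)^2, (1:128 - 70.7)^2, "+")
  img[d2 <= 20^2] <- 0.8
  masks <- segment_nuclei(img)
  expect_length(masks, 1)
  cen <- colMeans(cbind((masks[[1]] - 1) %% 128 + 1,
                        (masks[[1]] - 1) %/% 128 + 1))
  expect_lt(max(abs(cen - c(60.3, 70.7))), 2)
})

test_that("segmentation recovers the generated nuclei with high IoU", {
  f <- single_field("homogeneous", seed = 41, n_cells = 20,
                    shape = c(512, 512))
  cal <- calibrate(f$fitc, f$counterstain)
  masks <- segment_nuclei(cal$counterstain_norm)
  matched <- match_masks(masks, f$truth$pixels, iou_min = 0.5)
  expect_gte(matched, 19)
})

test_that("cell regions have disjoint annuli ordered by centroid", {
  expect_equal(nrow(define_cell_regions(list(), matrix(0, 32, 32))), 0)

  # two adjacent discs: each annulus must exclude both nuclei entirely
  img <- matrix(0, 96, 96)
  d2a <- outer((1:96 - 40)^2, (1:96 - 40)^2, "+")
  d2b <- outer((1:96 - 40)^2, (1:96 - 68)^2, "+")
  masks <- list(which(d2a <= 12^2), which(d2b <= 12^2))
  regions <- define_cell_regions(masks, img, dilate_radius = 6)
  expect_equal(nrow(regions), 2)
  all_nuc <- unlist(regions$nucleus)
  for (i in 1:2) {
    expect_gt(length(regions$cytoplasm[[i]]), 0)
    expect_length(intersect(regions$cytoplasm[[i]], all_nuc), 0)
  }
  expect_true(!is.unsorted(regions$centroid_row +
                             regions$centroid_col * 1e-6))

  # property on a rendered field: disjointness and area bounds
  f <- single_field("speckled", seed = 43, n_cells = 12, shape = c(384, 384))
  cal <- calibrate(f$fitc, f$counterstain)
  reg <- segment_field(cal)
  nucs <- unlist(reg$nucleus)
  expect_false(anyDuplicated(nucs) > 0)
  for (i in seq_len(nrow(reg)))
    expect_length(intersect(reg$cytoplasm[[i]], nucs), 0)
  expect_true(all(reg$area >= 200 & reg$area <= 8000))
})

test_that("mitosis flags follow the brightness-and-size rule", {
  f0 <- single_field("homogeneous", seed = 51, n_cells = 15,
                     mitotic_fraction = 0, shape = c(384, 384))
  cal0 <- calibrate(f0$fitc, f0$counterstain)
  reg0 <- segment_field(cal0)
  expect_equal(sum(reg0$mitotic), 0)

  # 10% mitoses: flagged set matches truth with F1 >= 0.8
  f1 <- single_field("speckled", seed = 52, n_cells = 30,
                     mitotic_fraction = 0.1, shape = c(512, 512))
  cal1 <- calibrate(f1$fitc, f1$counterstain)
  reg1 <- segment_field(cal1)
  truth_mit <- f1$truth$pixels[f1$truth$mitotic]
  pred_mit <- reg1$nucleus[reg1$mitotic]
  tp <- match_masks(pred_mit, truth_mit, iou_min = 0.5)
  prec <- if (length(pred_mit) == 0) 0 else tp / length(pred_mit)
  rec <- if (length(truth_mit) == 0) 1 else tp / length(truth_mit)
  f1_score <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  expect_gte(f1_score, 0.8)

  # guard clause: fewer than 3 regions -> nothing flagged
  two <- reg1[1:2, ]
  out <- identify_mitoses(two, cal1$counterstain_norm)
  expect_equal(sum(out$mitotic), 0)
})

test_that("segmentation is translation-equivariant", {
  f <- single_field("homogeneous", seed = 61, n_cells = 5,
                    shape = c(256, 256))
  cal <- calibrate(f$fitc, f$counterstain)
  base <- segment_field(cal)

  dr <- 7L; dc <- 11L
  pad_val <- stats::quantile(cal$counterstain_norm, 0.05, names = FALSE)
  shifted <- matrix(pad_val, 256, 256)
  shifted[(dr + 1):256, (dc + 1):256] <-
    cal$counterstain_norm[1:(256 - dr), 1:(256 - dc)]
  masks <- segment_nuclei(shifted)
  moved <- define_cell_regions(masks, shifted)
  # match cells that stayed fully in frame
  keep <- base$centroid_row + dr < 250 & base$centroid_col + dc < 250
  base <- base[keep, ]
  expect_equal(nrow(moved), nrow(base))
  for (i in seq_len(nrow(base))) {
    d <- sqrt((moved$centroid_row - base$centroid_row[i] - dr)^2 +
                (moved$centroid_col - base$centroid_col[i] - dc)^2)
    expect_lt(min(d), 1)
  }
})

test_that("segmentation depends on the counterstain channel only", {
  f <- single_field("nucleolar", seed = 71, n_cells = 8, shape = c(256, 256))
  cal1 <- calibrate(f$fitc, f$counterstain)
  cal2 <- calibrate(matrix(0, 256, 256), f$counterstain)
  set.seed(99)
  cal3 <- calibrate(matrix(stats::runif(256^2), 256, 256), f$counterstain)
  r1 <- segment_field(cal1)
  r2 <- segment_field(cal2)
  r3 <- segment_field(cal3)
  expect_identical(r1$nucleus, r2$nucleus)
  expect_identical(r1$nucleus, r3$nucleus)
  expect_identical(r1$mitotic, r3$mitotic)
})
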