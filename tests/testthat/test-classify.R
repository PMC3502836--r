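test_that("normalized image intensity is the median over non-mitotic cells", {
  fix <- disc_region_fixture(value = 0.6, cyto_value = 0.6)
  # constant 0.6 over every in-cell pixel -> exactly 0.6
  expect_equal(normalized_image_intensity(fix$cal, fix$region), 0.6)

  # zero FITC -> 0; no regions -> 0
  zero <- fix$cal
  zero$fitc_norm <- matrix(0, 64, 64)
  expect_equal(normalized_image_intensity(zero, fix$region), 0)
  expect_equal(normalized_image_intensity(fix$cal, fix$region[0, ]), 0)

  # mitotic cells are excluded
  mit <- fix$region
  mit$mitotic <- TRUE
  expect_equal(normalized_image_intensity(fix$cal, mit), 0)
})

test_that("the positive/negative cutoff is inclusive, validated, monotone", {
  expect_false(classify_pos_neg(0, 0.15))
  expect_true(classify_pos_neg(0.15, 0.15))   # boundary inclusive
  expect_error(classify_pos_neg(0.5, 0), "cutoff")
  expect_error(classify_pos_neg(0.5, 1), "cutoff")

  intensities <- c(0.02, 0.07, 0.12, 0.15, 0.31, 0.55, 0.80)
  counts <- vapply(seq(0.01, 0.99, by = 0.01), function(ct)
    sum(vapply(intensities, classify_pos_neg, logical(1), cutoff = ct)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("features on a constant disc match closed forms", {
  fix <- disc_region_fixture(value = 0.5)
  fv <- extract_features(fix$cal, fix$region)
  expect_equal(unname(fv["nuc_mean"]), 0.5)
  expect_equal(unname(fv["nuc_sd"]), 0)
  expect_equal(unname(fv[paste0("glcm_contrast_o", 1:4)]), rep(0, 4))
  expect_equal(unname(fv["cyto_mean"]), 0)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_names())

  tiny <- fix$region
  tiny$nucleus <- list(fix$region$nucleus[[1]][1:10])
  expect_error(extract_features(fix$cal, tiny), "below the feature window")
})

test_that("features are invariant to a pre-calibration constant offset", {
  f <- single_field("speckled", seed = 81, n_cells = 6, shape = c(256, 256))
  cal1 <- calibrate(f$fitc, f$counterstain)
  cal2 <- calibrate(f$fitc + 0.08, f$counterstain)
  reg <- segment_field(cal1)
  fv1 <- extract_features(cal1, reg[1, ])
  fv2 <- extract_features(cal2, reg[1, ])
  expect_equal(fv1, fv2, tolerance = 1e-12)
})

test_that("nucleolar cells show more LoG blobs than homogeneous cells", {
  blobs <- function(cls, seed) {
    f <- single_field(cls, seed = seed, n_cells = 14, shape = c(512, 512))
    cal <- calibrate(f$fitc, f$counterstain)
    reg <- segment_field(cal)
    feats <- extract_features_all(cal, reg)
    stats::median(feats$blob_count)
  }
  expect_gt(blobs("nucleolar", 91), blobs("homogeneous", 92))
})

test_that("k-NN matches a brute-force oracle on a printed 2-D toy set", {
  pts <- matrix(c(0.0, 0.0,   0.2, 0.1,   0.1, 0.9,   0.2, 1.1,
                  1.0, 0.0,   1.1, 0.2,   1.0, 1.0,   0.9, 1.1),
                ncol = 2, byrow = TRUE)
  labs <- c("homogeneous", "homogeneous", "speckled", "speckled",
            "nucleolar", "nucleolar", "centromeres", "centromeres")
  db <- anapattern:::new_reference_db(pts, labs, k_default = 3)
  queries <- rbind(c(0.1, 0.05), c(0.15, 1.0), c(1.05, 0.1),
                   c(0.95, 1.05), c(0.5, 0.5))
  for (q in seq_len(nrow(queries))) {
    got <- knn_classify_cell(queries[q, ], db, k = 3)
    # independent oracle: z-score, full distance sort, majority count
    z <- sweep(sweep(pts, 2, db$centre), 2, db$scale, "/")
    zq <- (queries[q, ] - db$centre) / db$scale
    d <- sqrt(rowSums(sweep(z, 2, zq)^2))
    nn <- labs[order(d)[1:3]]
    tab <- sort(table(nn), decreasing = TRUE)
    if (tab[1] > ifelse(length(tab) > 1, tab[2], 0)) {
      expect_equal(got$label, names(tab)[1])
    }
    expect_equal(sum(got$votes), 3)
    expect_equal(got$confidence, max(tab) / 3)
  }
})

test_that("k-NN breaks vote ties by total distance, then class order", {
  pts <- matrix(c(0, 0,  0, 1,  2, 0,  2, 1), ncol = 2, byrow = TRUE)
  labs <- c("speckled", "speckled", "homogeneous", "homogeneous")
  db <- anapattern:::new_reference_db(pts, labs)
  # query nearer the speckled pair: 2-2 vote, speckled wins on distance
  got <- knn_classify_cell(c(0.9, 0.5), db, k = 4)
  expect_equal(got$label, "speckled")
  # exact centre: distance also tied -> fixed class order (homogeneous first)
  got <- knn_classify_cell(c(1, 0.5), db, k = 4)
  expect_equal(got$label, "homogeneous")
})

test_that("k-NN validates inputs", {
  db <- anapattern:::new_reference_db(diag(3) * 1.0,
                                      c("speckled", "nucleolar", "speckled"))
  expect_error(knn_classify_cell(c(1, 2), db, k = 1), "feature length")
  expect_error(knn_classify_cell(c(1, 2, 3), db, k = 9), "k must lie")
  expect_error(anapattern:::new_reference_db(diag(2), c("negative", "speckled")),
               "negative-class")
})

test_that("leave-one-in 1-NN training accuracy is 100%", {
  db <- fixture_db()
  idx <- seq(1, nrow(db$features), by = 24)
  for (i in idx) {
    got <- knn_classify_cell(db$features[i, ], db, k = 1)
    expect_equal(got$label, db$labels[i])
    expect_equal(got$confidence, 1)
  }
})

test_that("nearest-neighbour search agrees with an independent library", {
  skip_if_not_installed("class")
  db <- fixture_db()
  f <- single_field("nuclear_dots", seed = 97, n_cells = 10,
                    shape = c(384, 384))
  cal <- calibrate(f$fitc, f$counterstain)
  feats <- extract_features_all(cal, segment_field(cal))
  fmat <- as.matrix(feats[!feats$mitotic, feature_names()])
  ours <- apply(fmat, 1, function(v) knn_classify_cell(v, db, k = 1)$label)
  ztrain <- sweep(sweep(db$features, 2, db$centre), 2, db$scale, "/")
  zquery <- sweep(sweep(fmat, 2, db$centre), 2, db$scale, "/")
  theirs <- as.character(class::knn(ztrain, zquery,
                                    factor(db$labels), k = 1))
  expect_equal(ours, unname(theirs))
})

test_that("classification is invariant to record order and feature scale", {
  db <- fixture_db()
  f <- single_field("centromeres", seed = 95, n_cells = 8,
                    shape = c(384, 384))
  cal <- calibrate(f$fitc, f$counterstain)
  feats <- extract_features_all(cal, segment_field(cal))
  base <- classify_cells(feats, db)

  perm <- withr::with_seed(1, sample(nrow(db$features)))
  db_perm <- anapattern:::new_reference_db(db$features[perm, ],
                                           db$labels[perm],
                                           k_default = db$k_default)
  expect_equal(classify_cells(feats, db_perm)$label, base$label)

  db_scaled <- db
  db_scaled$features[, 3] <- db$features[, 3] * 10
  db_scaled <- anapattern:::new_reference_db(db_scaled$features, db$labels,
                                             k_default = db$k_default)
  feats_scaled <- feats
  feats_scaled[[feature_names()[3]]] <- feats[[feature_names()[3]]] * 10
  expect_equal(classify_cells(feats_scaled, db_scaled)$label, base$label)
})
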