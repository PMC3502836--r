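cells_tbl <- function(labels, confidence = 0.9) {
  tibble::tibble(cell = seq_along(labels), label = labels,
                 confidence = rep_len(confidence, length(labels)))
}

test_that("cell results aggregate by the min-fraction rule", {
  # unanimity
  w <- aggregate_cell_results(cells_tbl(rep("speckled", 10)), TRUE, 0.4)
  expect_equal(w$patterns$label, "speckled")
  expect_equal(w$n_cells, 10)

  # 60/40 split -> mixed pattern
  w <- aggregate_cell_results(
    cells_tbl(c(rep("speckled", 6), rep("nucleolar", 4))), TRUE, 0.4)
  expect_setequal(w$patterns$label, c("speckled", "nucleolar"))

  # 90/10 split -> minor pattern below min_fraction is dropped
  w <- aggregate_cell_results(
    cells_tbl(c(rep("homogeneous", 9), "nucleolar")), TRUE, 0.4)
  expect_equal(w$patterns$label, "homogeneous")

  # plurality is always reported even below min_fraction
  labs <- c(rep("homogeneous", 2), rep("speckled", 2), rep("nucleolar", 2),
            rep("centromeres", 2), "nuclear_dots")
  w <- aggregate_cell_results(cells_tbl(labs), TRUE, 0.4, min_fraction = 0.3)
  expect_gte(nrow(w$patterns), 1)

  expect_error(aggregate_cell_results(cells_tbl("speckled"), TRUE, 0.4,
                                      min_fraction = 0.7), "min_fraction")
})

test_that("per-pattern confidence is the mean over supporting cells", {
  cells <- tibble::tibble(cell = 1:4,
                          label = c("speckled", "speckled", "nucleolar",
                                    "nucleolar"),
                          confidence = c(0.8, 0.6, 1.0, 0.5))
  w <- aggregate_cell_results(cells, TRUE, 0.4)
  expect_equal(w$patterns$confidence[w$patterns$label == "speckled"], 0.7)
  expect_equal(w$patterns$confidence[w$patterns$label == "nucleolar"], 0.75)
  # sorted by descending confidence
  expect_true(!is.unsorted(rev(w$patterns$confidence)))
})

test_that("negative and empty-positive wells are handled distinctly", {
  w <- aggregate_cell_results(cells_tbl(rep("speckled", 5)), FALSE, 0.05)
  expect_equal(nrow(w$patterns), 0)
  expect_equal(w$status, "ok")

  w <- aggregate_cell_results(cells_tbl(character()), TRUE, 0.4)
  expect_equal(w$status, "manual_review")
  expect_equal(nrow(w$patterns), 0)
})

well <- function(dilution, labels, positive = length(labels) > 0,
                 intensity = if (positive) 0.4 else 0.05) {
  aggregate_cell_results(cells_tbl(labels), positive, intensity,
                         dilution = dilution)
}

test_that("patient merging reads the endpoint titer", {
  wells <- list(well(100, rep("speckled", 8)),
                well(1000, rep("speckled", 8)),
                well(10000, character(), positive = FALSE))
  rep <- merge_patient(wells, 100, sample = "s1")
  expect_true(rep$overall_positive)
  expect_equal(rep$main_pattern, "speckled")
  expect_equal(rep$patterns$titer, 1000)
  expect_false(rep$patterns$titer_censored)
  expect_true(all(rep$patterns$titer >= 100))

  # still positive at the maximal tested dilution -> right-censored
  wells <- list(well(100, rep("nucleolar", 8)),
                well(1000, rep("nucleolar", 8)))
  rep <- merge_patient(wells, 100)
  expect_true(rep$patterns$titer_censored)
  expect_equal(rep$patterns$titer, 1000)
})

test_that("an all-negative series yields an empty negative report", {
  wells <- list(well(100, character(), positive = FALSE),
                well(1000, character(), positive = FALSE))
  rep <- merge_patient(wells, 100)
  expect_false(rep$overall_positive)
  expect_equal(nrow(rep$patterns), 0)
  expect_true(is.na(rep$main_pattern))
})

test_that("patient merging validates its well list", {
  w1 <- well(100, rep("speckled", 4))
  expect_error(merge_patient(list(w1, w1), 100), "duplicate")
  expect_error(merge_patient(list(well(1000, "speckled"), w1), 100),
               "sorted")
  expect_error(merge_patient(list(w1), 200), "screening")
})

test_that("the negative worklist sorts ascending with id tie-breaks", {
  tbl <- tibble::tibble(
    sample = c("a", "b", "c", "d", "e"),
    positive = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    intensity = c(0.12, 0.50, 0.01, 0.07, 0.07))
  wl <- negative_worklist(tbl)
  expect_equal(wl$sample, c("c", "d", "e", "a"))
  expect_false("b" %in% wl$sample)
  expect_equal(nrow(negative_worklist(tbl[tbl$positive, ])), 0)
})

test_that("serialized reports are byte-identical across reruns", {
  wells <- list(well(100, rep("speckled", 8)),
                well(1000, rep("speckled", 8)),
                well(10000, character(), positive = FALSE))
  rep <- merge_patient(wells, 100, sample = "s9")
  tmp <- withr::local_tempdir()
  p1 <- file.path(tmp, "r1.json"); p2 <- file.path(tmp, "r2.json")
  write_result_json(rep, p1)
  write_result_json(merge_patient(wells, 100, sample = "s9"), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  # well JSON round trip
  p3 <- file.path(tmp, "w.json")
  write_result_json(wells[[1]], p3)
  back <- read_well_json(p3)
  expect_equal(back$dilution, wells[[1]]$dilution)
  expect_equal(back$patterns$label, wells[[1]]$patterns$label)
})

test_that("tidy and glance views expose the report fields", {
  wells <- list(well(100, c(rep("speckled", 6), rep("nucleolar", 3))),
                well(1000, rep("speckled", 8)),
                well(10000, character(), positive = FALSE))
  rep <- merge_patient(wells, 100, sample = "s2")
  td <- tidy(rep)
  expect_setequal(td$label, c("speckled", "nucleolar"))
  expect_equal(td$titer[td$label == "speckled"], 1000)
  expect_equal(td$titer[td$label == "nucleolar"], 100)
  gl <- glance(rep)
  expect_equal(gl$n_wells, 3)
  expect_equal(gl$main_pattern, "speckled")
  tw <- tidy(wells[[1]])
  expect_equal(nrow(tw), 2)
  expect_equal(unique(tw$dilution), 100)
})
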