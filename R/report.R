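# Rule-based synthesis of per-cell calls into per-dilution results, and
# merging of a dilution series into one patient report with endpoint titer.

#' Aggregate per-cell classifications into one result per dilution
#'
#' On a positive field, a pattern is reported when at least `min_fraction`
#' of the voting cells carry it as their label (mixed patterns), and the
#' plurality pattern is always reported even below that fraction. Per-pattern
#' confidence is the mean cell confidence among its supporters. A positive
#' field with no classifiable cells is flagged for manual review rather than
#' silently reported negative.
#'
#' @param cells tibble from [classify_cells()] (non-mitotic cells).
#' @param positive logical from [classify_pos_neg()].
#' @param intensity scalar from [normalized_image_intensity()].
#' @param dilution reciprocal dilution of the field.
#' @param min_fraction minimum supporting cell fraction for a pattern to be
#'   reported, in (0, 0.5].
#' @return object of class `well_result`: `dilution`, `positive`,
#'   `intensity`, `n_cells`, `status` (`"ok"` or `"manual_review"`), and
#'   `patterns` — a tibble (`label`, `confidence`, `support`) sorted by
#'   descending confidence.
#' @export
aggregate_cell_results <- function(cells, positive, intensity,
                                   dilution = 100, min_fraction = 0.25) {
  if (min_fraction <= 0 || min_fraction > 0.5)
    stopf("min_fraction must lie in (0, 0.5]")
  empty_pat <- tibble::tibble(label = character(), confidence = double(),
                              support = double())
  status <- "ok"
  if (!positive) {
    pats <- empty_pat
  } else if (nrow(cells) == 0) {
    pats <- empty_pat
    status <- "manual_review"
  } else {
    tallies <- cells |>
      dplyr::count(.data$label, name = "n") |>
      dplyr::mutate(support = .data$n / sum(.data$n))
    keep <- tallies$support >= min_fraction
    keep[which.max(tallies$support)] <- TRUE  # plurality always reported
    tallies <- tallies[keep, , drop = FALSE]
    conf <- cells |>
      dplyr::filter(.data$label %in% tallies$label) |>
      dplyr::summarise(confidence = mean(.data$confidence),
                       .by = "label")
    pats <- tallies |>
      dplyr::left_join(conf, by = "label") |>
      dplyr::arrange(dplyr::desc(.data$confidence),
                     dplyr::desc(.data$support), .data$label) |>
      dplyr::select("label", "confidence", "support")
  }
  structure(list(dilution = dilution, positive = positive,
                 intensity = intensity, n_cells = nrow(cells),
                 status = status, patterns = pats),
            class = "well_result")
}

#' @export
print.well_result <- function(x, ...) {
  cat(sprintf("<well_result> 1:%g %s (intensity %.3f, %d cells%s)\n",
              x$dilution, if (x$positive) "POSITIVE" else "negative",
              x$intensity, x$n_cells,
              if (x$status != "ok") paste0(", ", x$status) else ""))
  if (nrow(x$patterns) > 0) print(x$patterns)
  invisible(x)
}

#' Merge a dilution series into one patient report
#'
#' Overall positivity is the call at the screening dilution. Each pattern's
#' estimated titer is the highest dilution at which the pattern is still
#' reported (endpoint reading, no interpolation); a pattern still present at
#' the highest tested dilution is right-censored (`titer_censored = TRUE`,
#' read as ">= max dilution"). The main pattern and the report confidence
#' come from the screening-dilution well.
#'
#' @param wells list of [aggregate_cell_results()] results, sorted by
#'   increasing dilution, screening dilution included, no duplicates.
#' @param screening_dilution reciprocal screening dilution (positivity is
#'   decided here).
#' @param sample sample identifier carried into the report.
#' @return object of class `patient_report`: `sample`, `overall_positive`,
#'   `main_pattern`, `confidence`, `status`, `patterns` (tibble `label`,
#'   `titer`, `titer_censored`, `confidence`) and the input `wells`.
#' @export
merge_patient <- function(wells, screening_dilution = 100, sample = "sample") {
  stopifnot(length(wells) > 0,
            all(purrr::map_lgl(wells, inherits, "well_result")))
  dil <- purrr::map_dbl(wells, "dilution")
  if (anyDuplicated(dil)) stopf("duplicate dilutions in the series")
  if (is.unsorted(dil, strictly = TRUE))
    stopf("wells must be sorted by increasing dilution")
  i_s <- match(screening_dilution, dil)
  if (is.na(i_s)) stopf("screening dilution 1:%g not among the wells",
                        screening_dilution)
  screen <- wells[[i_s]]
  empty_pat <- tibble::tibble(label = character(), titer = double(),
                              titer_censored = logical(),
                              confidence = double())
  status <- if (any(purrr::map_chr(wells, "status") != "ok"))
    "manual_review" else "ok"
  if (!screen$positive) {
    return(structure(list(sample = sample, overall_positive = FALSE,
                          main_pattern = NA_character_,
                          confidence = NA_real_, status = status,
                          patterns = empty_pat, wells = wells),
                     class = "patient_report"))
  }
  max_dil <- max(dil)
  pats <- purrr::map_dfr(wells, function(w)
    dplyr::mutate(w$patterns, dilution = w$dilution)) |>
    dplyr::summarise(titer = max(.data$dilution),
                     .by = "label") |>
    dplyr::mutate(titer_censored = .data$titer == max_dil)
  conf <- screen$patterns |> dplyr::select("label", "confidence")
  pats <- pats |>
    dplyr::left_join(conf, by = "label") |>
    dplyr::arrange(dplyr::desc(.data$titer), .data$label)
  main <- if (nrow(screen$patterns) > 0) screen$patterns$label[1] else
    NA_character_
  main_conf <- if (nrow(screen$patterns) > 0) screen$patterns$confidence[1] else
    NA_real_
  structure(list(sample = sample, overall_positive = TRUE,
                 main_pattern = main, confidence = main_conf,
                 status = status, patterns = pats, wells = wells),
            class = "patient_report")
}

#' @export
print.patient_report <- function(x, ...) {
  cat(sprintf("<patient_report> %s: %s%s\n", x$sample,
              if (x$overall_positive) "POSITIVE" else "negative",
              if (x$status != "ok") paste0(" [", x$status, "]") else ""))
  if (x$overall_positive) {
    cat(sprintf("  main pattern: %s (confidence %.2f)\n",
                x$main_pattern, x$confidence))
    for (i in seq_len(nrow(x$patterns)))
      cat(sprintf("  %-12s titer %s1:%g\n", x$patterns$label[i],
                  if (x$patterns$titer_censored[i]) ">= " else "",
                  x$patterns$titer[i]))
  }
  invisible(x)
}

#' Negative worklist
#'
#' All negative fields, ordered by ascending normalized fluorescence
#' intensity (ties broken by sample id) — the batch-validation list a
#' reviewer confirms in one step.
#'
#' @param wells tibble with columns `sample`, `positive`, `intensity` (one
#'   row per screened field), or a named list of `well_result` objects.
#' @return tibble of the negative rows, sorted.
#' @export
negative_worklist <- function(wells) {
  if (!is.data.frame(wells)) {
    wells <- purrr::imap_dfr(wells, function(w, nm)
      tibble::tibble(sample = nm, positive = w$positive,
                     intensity = w$intensity))
  }
  wells |>
    dplyr::filter(!.data$positive) |>
    dplyr::arrange(.data$intensity, .data$sample)
}
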