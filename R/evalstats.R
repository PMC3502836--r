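# Agreement statistics between visual and automated reading: concordance,
# unweighted Cohen's kappa with the Altman interpretation bands, and the
# diagnostic rates of a 2x2 table. Percentages are rounded half-up to one
# decimal and kappa to three decimals, the precision of published
# validation tables.

#' A 2x2 visual-vs-automated confusion table
#'
#' @param a auto-positive / visual-positive count.
#' @param b auto-positive / visual-negative count.
#' @param c auto-negative / visual-positive count.
#' @param d auto-negative / visual-negative count.
#' @return object of class `confusion_2x2`.
#' @export
#' @examples
#' confusion_2x2(a = 272, b = 2, c = 0, d = 77)
confusion_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("counts must be non-negative integers")
  if (sum(counts) == 0) stopf("the table must contain at least one pair")
  structure(as.list(counts), class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(auto = c("positive", "negative"),
                              visual = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Build a 2x2 table from paired visual/automated calls
#'
#' @param pairs data frame (or tibble) with logical columns `visual` and
#'   `auto`, one row per sample.
#' @return a [confusion_2x2()].
#' @export
confusion_from_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("visual", "auto") %in% names(pairs)))
  if (nrow(pairs) == 0) stopf("at least one pair is required")
  v <- as.logical(pairs$visual); a <- as.logical(pairs$auto)
  confusion_2x2(a = sum(a & v), b = sum(a & !v),
                c = sum(!a & v), d = sum(!a & !v))
}

#' Altman interpretation band for a kappa value
#'
#' poor (<= 0.20), fair (0.21-0.40), moderate (0.41-0.60), good (0.61-0.80),
#' very good (0.81-1.00).
#'
#' @param kappa numeric kappa value(s).
#' @return character vector of band names.
#' @export
altman_band <- function(kappa) {
  cut(kappa, breaks = c(-Inf, 0.20, 0.40, 0.60, 0.80, 1),
      labels = c("poor", "fair", "moderate", "good", "very good")) |>
    as.character()
}

#' Agreement statistics from a 2x2 table
#'
#' Concordance `100*(a+d)/n`; unweighted Cohen's kappa
#' `(p_o - p_e)/(1 - p_e)` with `p_o = (a+d)/n` and
#' `p_e = ((a+b)(a+c) + (c+d)(b+d))/n^2`; analytical sensitivity
#' `100*a/(a+c)`, specificity `100*d/(b+d)`, PPV `100*a/(a+b)`,
#' NPV `100*d/(c+d)`. Rates with an empty denominator are `NA` (undefined,
#' not zero). On a constant table (expected agreement 1), kappa is reported
#' as 1 when observed agreement is also 1 and is an error otherwise.
#'
#' @param t a [confusion_2x2()].
#' @return object of class `agreement_stats` with fields `concordance`,
#'   `kappa`, `kappa_band`, `sensitivity`, `specificity`, `ppv`, `npv`
#'   (rounded as printed), `kappa_unrounded` (full precision) and `n`.
#' @export
#' @examples
#' agreement_stats(confusion_2x2(272, 2, 0, 77))
agreement_stats <- function(t) {
  stopifnot(inherits(t, "confusion_2x2"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  kappa <- if (abs(1 - p_e) < 1e-12) {
    if (abs(1 - p_o) < 1e-12) 1 else
      stopf("kappa undefined: expected agreement 1 with observed %.3f", p_o)
  } else (p_o - p_e) / (1 - p_e)
  rate <- function(num, den) if (den == 0) NA_real_ else
    round_half_up(100 * num / den, 1)
  kappa_r <- round_half_up(kappa, 3)
  structure(list(concordance = round_half_up(100 * p_o, 1),
                 kappa = kappa_r,
                 kappa_unrounded = kappa,
                 kappa_band = altman_band(kappa_r),
                 sensitivity = rate(a, a + c),
                 specificity = rate(d, b + d),
                 ppv = rate(a, a + b),
                 npv = rate(d, c + d),
                 n = n),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(paste0("<agreement_stats> n = %d\n",
                     "  concordance %.1f%%, kappa %.3f (%s)\n",
                     "  sensitivity %s, specificity %s, PPV %s, NPV %s\n"),
              x$n, x$concordance, x$kappa, x$kappa_band,
              fmt_pct(x$sensitivity), fmt_pct(x$specificity),
              fmt_pct(x$ppv), fmt_pct(x$npv)))
  invisible(x)
}

fmt_pct <- function(x) if (is.na(x)) "undefined" else sprintf("%.1f%%", x)

#' Per-pattern recognition table
#'
#' Recognition rate per pattern plus a total row summed over patterns, with
#' the same half-up one-decimal rounding as the agreement statistics.
#'
#' @param rows data frame with columns `pattern`, `n_samples`,
#'   `n_recognized`.
#' @return tibble with columns `pattern`, `n_samples`, `n_recognized`,
#'   `rate` (percent), ending in a `"total"` row.
#' @export
#' @examples
#' pattern_table(data.frame(pattern = c("homogeneous", "speckled"),
#'                          n_samples = c(33, 130),
#'                          n_recognized = c(27, 123)))
pattern_table <- function(rows) {
  stopifnot(is.data.frame(rows),
            all(c("pattern", "n_samples", "n_recognized") %in% names(rows)))
  bad <- rows$n_samples == 0
  if (any(bad))
    stopf("row '%s' has zero samples", rows$pattern[which(bad)[1]])
  if (any(rows$n_recognized > rows$n_samples | rows$n_recognized < 0))
    stopf("n_recognized must lie in [0, n_samples]")
  out <- tibble::as_tibble(rows[, c("pattern", "n_samples", "n_recognized")])
  out <- dplyr::bind_rows(
    out,
    tibble::tibble(pattern = "total",
                   n_samples = sum(rows$n_samples),
                   n_recognized = sum(rows$n_recognized)))
  dplyr::mutate(out,
                rate = round_half_up(100 * .data$n_recognized / .data$n_samples, 1))
}
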