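# broom-style accessors

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an agreement_stats object
#'
#' @param x an `agreement_stats`.
#' @param ... unused.
#' @return long tibble with `metric`, `value`, `unit`.
#' @method tidy agreement_stats
#' @export
tidy.agreement_stats <- function(x, ...) {
  tibble::tibble(
    metric = c("concordance", "kappa", "sensitivity", "specificity",
               "ppv", "npv"),
    value = c(x$concordance, x$kappa, x$sensitivity, x$specificity,
              x$ppv, x$npv),
    unit = c("percent", "kappa", rep("percent", 4)))
}

#' Glance at an agreement_stats object
#'
#' @param x an `agreement_stats`.
#' @param ... unused.
#' @return one-row tibble.
#' @method glance agreement_stats
#' @export
glance.agreement_stats <- function(x, ...) {
  tibble::tibble(n = x$n, concordance = x$concordance, kappa = x$kappa,
                 kappa_band = x$kappa_band, sensitivity = x$sensitivity,
                 specificity = x$specificity, ppv = x$ppv, npv = x$npv)
}

#' Tidy a well_result object
#'
#' @param x a `well_result`.
#' @param ... unused.
#' @return tibble with one row per reported pattern (zero rows when
#'   negative), carrying the well-level fields.
#' @method tidy well_result
#' @export
tidy.well_result <- function(x, ...) {
  base <- tibble::tibble(dilution = x$dilution, positive = x$positive,
                         intensity = x$intensity, n_cells = x$n_cells,
                         status = x$status)
  if (nrow(x$patterns) == 0) return(dplyr::bind_cols(
    base[0, ], tibble::tibble(label = character(), confidence = double(),
                              support = double())))
  dplyr::bind_cols(base[rep(1, nrow(x$patterns)), ], x$patterns)
}

#' Tidy a patient_report object
#'
#' @param x a `patient_report`.
#' @param ... unused.
#' @return tibble with one row per reported pattern and its endpoint titer.
#' @method tidy patient_report
#' @export
tidy.patient_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sample = x$sample,
                   overall_positive = x$overall_positive,
                   status = x$status)[rep(1, max(1, nrow(x$patterns))), ],
    if (nrow(x$patterns) > 0) x$patterns else
      tibble::tibble(label = NA_character_, titer = NA_real_,
                     titer_censored = NA, confidence = NA_real_))
}

#' Glance at a patient_report object
#'
#' @param x a `patient_report`.
#' @param ... unused.
#' @return one-row tibble with the headline result.
#' @method glance patient_report
#' @export
glance.patient_report <- function(x, ...) {
  tibble::tibble(sample = x$sample, overall_positive = x$overall_positive,
                 main_pattern = x$main_pattern, confidence = x$confidence,
                 n_patterns = nrow(x$patterns),
                 n_wells = length(x$wells), status = x$status)
}
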