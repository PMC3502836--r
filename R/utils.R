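# internal helpers shared across modules

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going up (0.05 -> 0.1), the
#' convention used by clinical agreement tables, unlike [round()]'s
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(81.25, 1)  # 81.3, where round() gives 81.2
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# deterministic child seed; keeps results < 2^31 and distinct per stream
child_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483563
  as.integer(h + 1L)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# quantize to a 16-bit grid so equality of rendered images is exact
quantize16 <- function(x) round(clip01(x) * 65535) / 65535

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)
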