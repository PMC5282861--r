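#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero (the
#' convention used for the printed agreement percentages), unlike base
#' [round()] which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percent renderings
#'
#' `percent_round()` renders a proportion as a percentage rounded half-up to
#' `digits` decimals (the rendering used throughout the agreement table);
#' `percent_trunc()` truncates to the integer percent (the rendering used by
#' the worked example, where 10/15 prints as 66%).
#'
#' @param p Proportion(s) in \[0, 1\].
#' @param digits Decimal places for `percent_round()`.
#' @return Numeric vector on the percent scale.
#' @export
percent_round <- function(p, digits = 2) round_half_up(100 * p, digits)

#' @rdname percent_round
#' @export
percent_trunc <- function(p) floor(100 * p + 1e-9)

# internal: stop with a classed condition so callers/tests can be precise
epokb_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "epokb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# internal: deterministic sort of a character vector (C locale, stable)
sort_c <- function(x) {
  if (length(x) == 0) return(character(0))
  x[order(x, method = "radix")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
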