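# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding used for all reported percentages and ratios: ties are
#' rounded away from zero (0.125 -> 0.13 at 2 digits), unlike [round()]'s
#' round-half-even. Exposed because percentage tables are defined in terms of
#' this convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_away(c(2.5, -2.5), 0)
#' round_half_away(14.705, 2)
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by machine eps to protect values like 67.365 stored as 67.36499...
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

stop_spaccess <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "spaccess_error"),
                      call = sys.call(-1)))
}

assert_finite_num <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop_spaccess("%s must be finite numeric values", what,
                  class = "spaccess_validation_error")
  invisible(x)
}

# deterministic per-component stream seed: same (seed, name) always maps to
# the same substream, and adding a new named draw site does not shift others
seed_stream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 99991L
  as.integer((as.numeric(seed) %% 20000003 + 104729 * h) %% 2147483647)
}
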