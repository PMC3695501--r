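# internal helpers shared across modules

#' Round half away from zero
#'
#' Rounding convention used for all printed percentages: halves round away
#' from zero (so 76.5 -> 77 and -76.5 -> -77), unlike base [round()] which
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_out(c(0.5, 1.5, 2.5))   # 1 2 3
round_half_out <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# seconds -> minutes; the single time-unit boundary of the package.
# All public time grids are in seconds, all rate constants in min^-1;
# this conversion is applied exactly once on entry to the integrator /
# fitters and nowhere else.
.sec_to_min <- function(t_sec) t_sec / 60

.assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("'%s' must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

# draw reproducibly without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
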