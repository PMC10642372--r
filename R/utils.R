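# shared small helpers

#' Round half away from zero
#'
#' Rounding used for all reported percentages: half-values round away from
#' zero (so 10.25 -> 10.3), matching conventional clinical-table rounding
#' rather than IEC 60559 banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as a percentage to one decimal
#'
#' @param x proportion in [0, 1] (or NaN for empty denominators).
#' @param digits decimal places, default 1.
#' @return numeric percentage rounded half away from zero.
#' @export
pct <- function(x, digits = 1) {
  round_half_up(100 * x, digits)
}

.assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

.assert_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# deterministic per-stage seed derived from one root seed; stays < 2^31
.stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 11L, profiles = 23L, match = 37L, fit = 53L,
               survival = 71L, design = 89L, power = 97L)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}
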