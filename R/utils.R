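# Shared constants and small helpers.

DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 30.4375          # DAYS_PER_YEAR / 12
PHASE_BOUNDARY_DAYS <- 183         # 6 months (182.625 d) rounded up

PERIOD_LEVELS <- c("P0_6", "P6_12", "P12_18", "P18_24", "P24PLUS")
MODEL_PERIOD_LEVELS <- c("P6_12", "P12_18", "P18_24", "P24PLUS")
STAGE_LEVELS <- c("REF", "TB_ADI", "NONTB_ADI")

#' Convert days since cART initiation to an analysis period
#'
#' Periods are half-open on the left on the month scale
#' (months = days / 30.4375): (6, 12], (12, 18], (18, 24], (24, Inf).
#' Times at or below 6 months are labelled \code{"P0_6"}; these never enter
#' the regression model, which is restricted to endpoints beyond 183 days.
#'
#' @param days numeric vector of days since cART initiation.
#' @return factor with levels \code{P0_6, P6_12, P12_18, P18_24, P24PLUS}.
#' @export
period_of_days <- function(days) {
  months <- days / DAYS_PER_MONTH
  cut(months,
      breaks = c(-Inf, 6, 12, 18, 24, Inf),
      labels = PERIOD_LEVELS,
      right = TRUE)
}

#' Round half away from zero
#'
#' Deterministic decimal rounding used for display grids (base
#' \code{round()} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Derive a per-stage seed from a root seed, staying below 2^31.
derive_seed <- function(root, stage) {
  (as.double(root) + 1000003 * stage) %% 2147483647
}

set_seed_strict <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(stage, msg, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(msg, ...)), call. = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
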