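# Slope calculator: predicted CD4 slope from patient covariates and model
# coefficients; prediction grids over viral-load levels; viral-load
# thresholds compatible with a target slope.

#' Default viral-load grid (copies/mL)
#' @export
DEFAULT_VL_GRID <- c(500, 1000, 2000, 3000, 4000, 5000, 10000, 20000,
                     30000, 40000, 50000, 100000, 150000)

#' Patient covariate profile for slope prediction
#'
#' @param female 0/1.
#' @param age_years current age in years (> 0).
#' @param stage \code{"REF"} (CDC category A), \code{"TB_ADI"} or
#'   \code{"NONTB_ADI"}.
#' @param haemoglobin g/dL (enters with its model coefficient, 0.0 in the
#'   published model).
#' @param cd4 concurrent CD4 count, cells/uL (>= 0).
#' @param hepatitis 0/1 hepatitis B or C co-infection.
#' @param period analysis period: \code{"P6_12"}, \code{"P12_18"},
#'   \code{"P18_24"} or \code{"P24PLUS"}.
#' @param nnrti,boosted_pi,abacavir 0/1 initial-regimen indicators.
#' @return an object of class \code{cd4_patient_profile}.
#' @export
patient_profile <- function(female = 0, age_years = 30, stage = "REF",
                            haemoglobin = 14, cd4 = 200, hepatitis = 0,
                            period = "P6_12", nnrti = 0, boosted_pi = 0,
                            abacavir = 0) {
  if (!is_scalar_number(age_years) || age_years <= 0)
    stop("patient_profile: age_years must be positive", call. = FALSE)
  if (!is_scalar_number(cd4) || cd4 < 0)
    stop("patient_profile: cd4 must be non-negative", call. = FALSE)
  if (!stage %in% STAGE_LEVELS)
    stop("patient_profile: unknown stage '", stage, "'", call. = FALSE)
  if (!period %in% MODEL_PERIOD_LEVELS)
    stop("patient_profile: unknown period '", period, "'", call. = FALSE)
  structure(list(female = female, age_years = age_years, stage = stage,
                 haemoglobin = haemoglobin, cd4 = cd4, hepatitis = hepatitis,
                 period = period, nnrti = nnrti, boosted_pi = boosted_pi,
                 abacavir = abacavir),
            class = "cd4_patient_profile")
}

#' Published final-model coefficients
#'
#' The published multivariate coefficients for the CD4 slope model and its
#' constant, with standard errors back-computed from the printed 95\%
#' confidence intervals (half-width / 1.96).  P-values below the printed
#' precision are stored as 0.0005.
#'
#' @return a \code{cd4_model_fit} with \code{source = "published"}.
#' @export
published_coefficients <- function() {
  est <- c("(Intercept)" = 205.5, female = 7.8, age_decades = -4.8,
           stageTB_ADI = 26.3, stageNONTB_ADI = 12.0, haemoglobin = 0.0,
           cd4_per100 = 1.9, log10_vl = -40.5, hepatitis = -17.7,
           periodP12_18 = -21.5, periodP18_24 = -25.8,
           periodP24PLUS = -59.1, nnrti = -1.3, boosted_pi = -3.4,
           abacavir = -5.6)
  ci_low <- c(174.4, -1.5, -8.6, 15.6, 2.5, 0.0, 0.2, -48.4, -29.7,
              -37.8, -42.0, -71.7, -9.2, -13.2, -18.5)
  ci_high <- c(236.6, 17.2, -1.0, 37.0, 21.4, 0.1, 3.7, -32.6, -5.7,
               -5.2, -9.7, -46.5, 6.6, 6.3, 7.3)
  p <- c(NA, 0.099, 0.013, 0.0005, 0.013, 0.689, 0.033, 0.0005, 0.004,
         0.010, 0.002, 0.0005, 0.749, 0.493, 0.397)
  names(ci_low) <- names(ci_high) <- names(p) <- names(est)
  se <- (ci_high - ci_low) / (2 * 1.96)
  structure(list(coefficients = est, se = se, ci_low = ci_low,
                 ci_high = ci_high, wald_z = est / se, wald_p = p,
                 sigma_b2 = NA_real_, sigma_e2 = NA_real_,
                 lambda = NA_real_, loglik = NA_real_, criterion = "REML",
                 n_obs = 10899L, n_patients = 1676L,
                 constant = 205.5, vcov = NULL, flags = character(0),
                 source = "published"),
            class = "cd4_model_fit")
}

profile_design <- function(profile) {
  c("(Intercept)" = 1,
    female = profile$female,
    age_decades = profile$age_years / 10,
    stageTB_ADI = as.numeric(profile$stage == "TB_ADI"),
    stageNONTB_ADI = as.numeric(profile$stage == "NONTB_ADI"),
    haemoglobin = profile$haemoglobin,
    cd4_per100 = profile$cd4 / 100,
    hepatitis = profile$hepatitis,
    periodP12_18 = as.numeric(profile$period == "P12_18"),
    periodP18_24 = as.numeric(profile$period == "P18_24"),
    periodP24PLUS = as.numeric(profile$period == "P24PLUS"),
    nnrti = profile$nnrti,
    boosted_pi = profile$boosted_pi,
    abacavir = profile$abacavir)
}

# Linear predictor excluding the viral-load term; coefficients absent from
# the fit (e.g. terms dropped during selection) contribute zero.
lp_excluding_vl <- function(profile, model) {
  x <- profile_design(profile)
  b <- model$coefficients
  common <- intersect(names(x), names(b))
  sum(x[common] * b[common])
}

#' Predict the CD4 slope for a patient profile
#'
#' Evaluates the model linear predictor: constant + coefficient-weighted
#' covariates, with the viral load entering as log10(copies/mL).
#'
#' @param profile a \code{\link{patient_profile}} (its \code{period} is
#'   used unless overridden via \code{period}).
#' @param model a \code{cd4_model_fit}; defaults to the published
#'   coefficients.
#' @param vl concurrent viral load, copies/mL (> 0); vectorised.
#' @param period optional period overriding the profile's.
#' @return predicted slope(s), cells/uL per year (unrounded).
#' @export
predict_slope <- function(profile, model = published_coefficients(), vl,
                          period = NULL) {
  if (any(!is.finite(vl)) || any(vl <= 0))
    stop("predict_slope: vl must be positive (copies/mL)", call. = FALSE)
  if (!is.null(period)) {
    profile$period <- period
    profile <- do.call(patient_profile, unclass(profile))
  }
  b <- model$coefficients
  beta_vl <- if ("log10_vl" %in% names(b)) b[["log10_vl"]] else 0
  lp_excluding_vl(profile, model) + beta_vl * log10(vl)
}

#' Prediction grid over periods and viral-load levels
#'
#' Builds the period-by-VL matrix of predicted slopes, rounded half away
#' from zero to 1 decimal place for display (raw values are retained), with
#' borderline flags where the slope lies in [-20, +20] cells/uL/year
#' (endpoints included).
#'
#' @param profile a \code{\link{patient_profile}}.
#' @param model a \code{cd4_model_fit}.
#' @param vl_grid ascending viral-load levels, copies/mL.
#' @param periods periods for the grid rows.
#' @param borderline_band slopes within this band (inclusive) are flagged.
#' @return object of class \code{cd4_prediction_grid}: list with
#'   \code{raw}, \code{rounded} and \code{borderline} matrices.
#' @export
build_grid <- function(profile, model = published_coefficients(),
                       vl_grid = DEFAULT_VL_GRID,
                       periods = MODEL_PERIOD_LEVELS,
                       borderline_band = c(-20, 20)) {
  if (!length(vl_grid) || is.unsorted(vl_grid, strictly = TRUE))
    stop("build_grid: vl_grid must be non-empty and strictly ascending",
         call. = FALSE)
  raw <- t(vapply(periods, function(per) {
    predict_slope(profile, model, vl_grid, period = per)
  }, numeric(length(vl_grid))))
  dimnames(raw) <- list(periods, format(vl_grid, scientific = FALSE,
                                        trim = TRUE))
  structure(list(raw = raw,
                 rounded = round_half_away(raw, 1),
                 borderline = raw >= borderline_band[1] &
                   raw <= borderline_band[2],
                 vl_grid = vl_grid, periods = periods),
            class = "cd4_prediction_grid")
}

#' @export
print.cd4_prediction_grid <- function(x, ...) {
  cat("Estimated CD4 slope (cells/uL/year) by period and HIV VL",
      "(borderline values ** flagged **)\n")
  disp <- matrix(sprintf("%.1f", x$rounded), nrow = nrow(x$rounded),
                 dimnames = dimnames(x$rounded))
  disp[x$borderline] <- paste0("**", disp[x$borderline], "**")
  print(as.data.frame(disp), right = TRUE)
  invisible(x)
}

#' Viral-load threshold maintaining a target CD4 slope
#'
#' For each period, the viral load at which the predicted slope equals the
#' target.  \code{"GRID"} mode returns the largest grid level whose
#' predicted slope is at or above the target (status
#' \code{"below_minimum"} if even the smallest grid level fails,
#' \code{"at_maximum"} if every level succeeds); \code{"CONTINUOUS"} mode
#' returns the closed form 10^((lp_excluding_vl - target) / (-beta_vl)).
#'
#' @param profile a \code{\link{patient_profile}}.
#' @param model a \code{cd4_model_fit}; its VL coefficient must be
#'   negative.
#' @param target_slope target slope, cells/uL/year (default 20).
#' @param mode \code{"GRID"} or \code{"CONTINUOUS"}.
#' @param vl_grid grid levels for \code{"GRID"} mode.
#' @param periods periods to solve for.
#' @return data.frame with period, vl (copies/mL) and status.
#' @export
solve_vl_threshold <- function(profile, model = published_coefficients(),
                               target_slope = 20,
                               mode = c("GRID", "CONTINUOUS"),
                               vl_grid = DEFAULT_VL_GRID,
                               periods = MODEL_PERIOD_LEVELS) {
  mode <- match.arg(mode)
  b <- model$coefficients
  beta_vl <- if ("log10_vl" %in% names(b)) b[["log10_vl"]] else NULL
  if (is.null(beta_vl) || beta_vl >= 0)
    stop("solve_vl_threshold: VL coefficient must be negative",
         call. = FALSE)
  rows <- lapply(periods, function(per) {
    prof <- profile; prof$period <- per
    prof <- do.call(patient_profile, unclass(prof))
    if (mode == "CONTINUOUS") {
      vl <- 10^((lp_excluding_vl(prof, model) - target_slope) / (-beta_vl))
      return(data.frame(period = per, vl = vl, status = "ok",
                        stringsAsFactors = FALSE))
    }
    pred <- predict_slope(prof, model, vl_grid)
    ok <- which(pred >= target_slope)
    if (!length(ok))
      data.frame(period = per, vl = NA_real_, status = "below_minimum",
                 stringsAsFactors = FALSE)
    else
      data.frame(period = per, vl = vl_grid[max(ok)],
                 status = if (length(ok) == length(vl_grid)) "at_maximum"
                          else "ok",
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
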