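#' Coefficients of the data-generating ("true") slope model
#'
#' The linear predictor for the phase-2 CD4 slope (cells/uL/year), evaluated
#' at time-updated covariates.  Defaults are the published final multivariate
#' model for this endpoint: each coefficient is the change in annual CD4
#' slope per unit of the covariate (age per decade, CD4 per 100 cells/uL,
#' viral load per log10 copies/mL, indicator contrasts otherwise).
#'
#' @param constant intercept, cells/uL/year.
#' @param beta_female,beta_age_per10,beta_tb,beta_nontb_adi,beta_haemoglobin,beta_cd4_per100,beta_log10vl,beta_hepatitis,beta_period_12_18,beta_period_18_24,beta_period_24plus,beta_nnrti,beta_boosted_pi,beta_abacavir
#'   slope differences, cells/uL/year per covariate unit.
#' @return an object of class \code{cd4_true_model} (named list).
#' @export
true_model <- function(constant = 205.5,
                       beta_female = 7.8,
                       beta_age_per10 = -4.8,
                       beta_tb = 26.3,
                       beta_nontb_adi = 12.0,
                       beta_haemoglobin = 0.0,
                       beta_cd4_per100 = 1.9,
                       beta_log10vl = -40.5,
                       beta_hepatitis = -17.7,
                       beta_period_12_18 = -21.5,
                       beta_period_18_24 = -25.8,
                       beta_period_24plus = -59.1,
                       beta_nnrti = -1.3,
                       beta_boosted_pi = -3.4,
                       beta_abacavir = -5.6) {
  tm <- list(constant = constant,
             beta_female = beta_female,
             beta_age_per10 = beta_age_per10,
             beta_tb = beta_tb,
             beta_nontb_adi = beta_nontb_adi,
             beta_haemoglobin = beta_haemoglobin,
             beta_cd4_per100 = beta_cd4_per100,
             beta_log10vl = beta_log10vl,
             beta_hepatitis = beta_hepatitis,
             beta_period_12_18 = beta_period_12_18,
             beta_period_18_24 = beta_period_18_24,
             beta_period_24plus = beta_period_24plus,
             beta_nnrti = beta_nnrti,
             beta_boosted_pi = beta_boosted_pi,
             beta_abacavir = beta_abacavir)
  bad <- names(tm)[!vapply(tm, is_scalar_number, logical(1))]
  if (length(bad))
    stop("true_model: non-finite or non-scalar coefficients: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(tm, class = "cd4_true_model")
}

# Evaluate the true-model linear predictor (vectorised over rows).
true_model_lp <- function(tm, female, age_decades, stage, haemoglobin,
                          cd4_per100, log10_vl, hepatitis, period,
                          nnrti, boosted_pi, abacavir) {
  tm$constant +
    tm$beta_female * female +
    tm$beta_age_per10 * age_decades +
    tm$beta_tb * (stage == "TB_ADI") +
    tm$beta_nontb_adi * (stage == "NONTB_ADI") +
    tm$beta_haemoglobin * haemoglobin +
    tm$beta_cd4_per100 * cd4_per100 +
    tm$beta_log10vl * log10_vl +
    tm$beta_hepatitis * hepatitis +
    tm$beta_period_12_18 * (period == "P12_18") +
    tm$beta_period_18_24 * (period == "P18_24") +
    tm$beta_period_24plus * (period == "P24PLUS") +
    tm$beta_nnrti * nnrti +
    tm$beta_boosted_pi * boosted_pi +
    tm$beta_abacavir * abacavir
}

#' Synthetic-cohort generator configuration
#'
#' Defaults emulate a treatment-naive adult cART cohort: 74\% male, median
#' age 36 (IQR 30-42), 12\% hepatitis B/C co-infection, median baseline CD4
#' 140 cells/uL, median baseline viral load 4.93 log10 copies/mL, routine
#' testing at a median 165-day spacing (IQR 106-223) after an initial
#' denser monitoring phase, median follow-up 4.2 years, 83\% virological
#' suppression (< 400 copies/mL) at 6 months and 82\% at 12 months, and a
#' two-phase CD4 response (rapid first-6-month rise, then the slope model
#' in \code{true_model}).
#'
#' Continuous baselines use log-normal (age: truncated normal)
#' distributions parameterised to reproduce the target medians/IQRs.
#' Viral loads below \code{detection_limit} are stored as
#' \code{detection_limit / 2} so the log10 transform is defined.
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical cohorts.
#' @param prop_male fraction male.
#' @param age_location,age_scale mean and SD (years) of the truncated-normal
#'   age-at-initiation distribution (truncated to \code{[18, 75]}).
#' @param prop_hepatitis fraction hepatitis B or C co-infected.
#' @param stage_probs probabilities at initiation for (CDC category A/B,
#'   TB with or without other ADI, non-TB ADI); any remainder is added to
#'   the reference category.
#' @param regimen_probs probabilities for an (NNRTI-based, non-boosted PI,
#'   boosted PI) initial regimen; the remainder is "other" (all flags 0).
#' @param prop_abacavir fraction whose initial regimen contains abacavir.
#' @param baseline_cd4_log_location,baseline_cd4_log_scale log-normal
#'   parameters of baseline CD4 (cells/uL), truncated to \code{[1, 1200]}.
#' @param baseline_log10vl_location,baseline_log10vl_scale normal parameters
#'   of baseline log10 viral load, truncated to \code{[2.7, 7]}.
#' @param visit_interval_log_location,visit_interval_log_scale log-normal
#'   parameters of the routine inter-visit gap in days.
#' @param early_visit_log_locations,early_visit_log_scale log-normal
#'   location(s) for the first monitoring gaps after initiation (defaults:
#'   medians 30, 50, 60 and 60 days), reflecting denser monitoring during
#'   the first six months of treatment.
#' @param followup_log_location,followup_log_scale log-normal parameters of
#'   follow-up duration in years.
#' @param p_suppress_6m fraction suppressed (< detection limit) from 6
#'   months.
#' @param p_still_suppressed_12m target marginal suppressed fraction at 12
#'   months; the per-visit rebound probability is solved from this.
#' @param detection_limit assay detection limit, copies/mL.
#' @param suppression_day day by which suppressing patients reach the
#'   detection limit.
#' @param fail_log10vl_location,fail_log10vl_scale per-patient set point
#'   (log10 copies/mL) of unsuppressed viral load.
#' @param fail_log10vl_jitter per-visit SD around the set point.
#' @param phase1_slope_mean,phase1_slope_sd per-patient CD4 slope
#'   (cells/uL/year) during the first 183 days.
#' @param true_model a \code{\link{true_model}} object driving the phase-2
#'   slope.
#' @param sigma_b between-patient SD of the slope-level random effect,
#'   cells/uL/year.
#' @param sigma_m additive CD4 measurement noise SD, cells/uL.
#' @param tb_incidence,adi_incidence incident TB / non-TB ADI rates, events
#'   per person-year.
#' @param haemoglobin_location,haemoglobin_scale patient-mean haemoglobin
#'   distribution, g/dL.
#' @param haemoglobin_visit_sd within-patient per-visit haemoglobin SD.
#' @param class_change_rate annual rate of a drug-class change.
#' @param gap_prob probability that a regimen change involves an
#'   off-treatment gap longer than 30 days.
#' @param pretreatment_window_days labs/events may precede cART start by at
#'   most this many days.
#' @return an object of class \code{cd4_generator_config} (named list).
#' @export
generator_config <- function(n_patients = 1676,
                             seed = 1,
                             prop_male = 0.74,
                             age_location = 36,
                             age_scale = 8.9,
                             prop_hepatitis = 0.12,
                             stage_probs = c(0.64, 0.144, 0.216),
                             regimen_probs = c(0.63, 0.15, 0.20),
                             prop_abacavir = 0.05,
                             baseline_cd4_log_location = log(140),
                             baseline_cd4_log_scale = 1.26,
                             baseline_log10vl_location = 4.93,
                             baseline_log10vl_scale = 0.96,
                             visit_interval_log_location = log(165),
                             visit_interval_log_scale = 0.551,
                             early_visit_log_locations = log(c(30, 50, 60, 60)),
                             early_visit_log_scale = 0.22,
                             followup_log_location = log(4.2),
                             followup_log_scale = 0.624,
                             p_suppress_6m = 0.83,
                             p_still_suppressed_12m = 0.82,
                             detection_limit = 400,
                             suppression_day = 90,
                             fail_log10vl_location = 5.1,
                             fail_log10vl_scale = 0.6,
                             fail_log10vl_jitter = 0.1,
                             phase1_slope_mean = 179,
                             phase1_slope_sd = 40,
                             true_model = cd4slope::true_model(),
                             sigma_b = 25,
                             sigma_m = 50,
                             tb_incidence = 0.015,
                             adi_incidence = 0.02,
                             haemoglobin_location = 14.0,
                             haemoglobin_scale = 1.9,
                             haemoglobin_visit_sd = 0.5,
                             class_change_rate = 0.2,
                             gap_prob = 0.2,
                             pretreatment_window_days = 30) {
  cfg <- as.list(environment())
  validate_generator_config(cfg)
  structure(cfg, class = "cd4_generator_config")
}

validate_generator_config <- function(cfg) {
  num_fields <- setdiff(names(cfg), "true_model")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("generator_config: field '", f, "' must be finite numeric",
           call. = FALSE)
  }
  if (!inherits(cfg$true_model, "cd4_true_model"))
    stop("generator_config: 'true_model' must be a true_model() object",
         call. = FALSE)
  if (cfg$n_patients < 0 || cfg$n_patients != round(cfg$n_patients))
    stop("generator_config: n_patients must be a non-negative integer",
         call. = FALSE)
  fracs <- c("prop_male", "prop_hepatitis", "prop_abacavir",
             "p_suppress_6m", "p_still_suppressed_12m", "gap_prob")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("generator_config: fraction '", f, "' outside [0, 1]",
           call. = FALSE)
  for (f in c("stage_probs", "regimen_probs")) {
    p <- cfg[[f]]
    if (any(p < 0) || sum(p) > 1 + 1e-12)
      stop("generator_config: '", f,
           "' must be non-negative and sum to at most 1", call. = FALSE)
  }
  if (length(cfg$stage_probs) != 3L)
    stop("generator_config: stage_probs needs 3 entries (A/B, TB, non-TB)",
         call. = FALSE)
  if (length(cfg$regimen_probs) != 3L)
    stop("generator_config: regimen_probs needs 3 entries",
         call. = FALSE)
  if (cfg$detection_limit <= 0)
    stop("generator_config: detection_limit must be positive", call. = FALSE)
  invisible(cfg)
}

#' Read a generator configuration from YAML
#'
#' Unknown top-level keys are rejected.  A \code{true_model} mapping, if
#' present, overrides individual coefficients of the default model.
#'
#' @param path path to a YAML file.
#' @return a \code{\link{generator_config}} object.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("read_generator_config: unknown fields: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(raw$true_model))
    raw$true_model <- do.call(true_model, raw$true_model)
  do.call(generator_config, raw)
}

#' @export
print.cd4_generator_config <- function(x, ...) {
  cat("cd4slope generator config: ", x$n_patients, " patients, seed ",
      x$seed, "\n", sep = "")
  cat("  baseline CD4 median ", round(exp(x$baseline_cd4_log_location)),
      " cells/uL; baseline VL median ", x$baseline_log10vl_location,
      " log10 copies/mL\n", sep = "")
  cat("  suppression: ", x$p_suppress_6m * 100, "% at 6 months, ",
      x$p_still_suppressed_12m * 100, "% at 12 months (< ",
      x$detection_limit, " copies/mL)\n", sep = "")
  invisible(x)
}
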