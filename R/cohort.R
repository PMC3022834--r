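#' Container for a long-format cohort
#'
#' Bundles the four long-format tables (patients, labs, events, treatments)
#' and validates referential integrity, date ordering and value ranges.
#'
#' @param patients data.frame: patient_id, sex ("M"/"F"), birth_date,
#'   cart_start (Date), regimen_nnrti, regimen_boosted_pi,
#'   regimen_nonboosted_pi, abacavir, hepatitis_bc (0/1).
#' @param labs data.frame: patient_id, date (Date), analyte
#'   ("CD4"/"VL"/"HB"), value.
#' @param events data.frame: patient_id, date (Date), event
#'   ("TB_ADI"/"NONTB_ADI").
#' @param treatments data.frame: patient_id, start, stop (Date), classes
#'   (comma-separated drug classes, one entry per drug).
#' @param pretreatment_window_days how far labs/events may precede cART
#'   start.
#' @return an object of class \code{cd4_cohort}.
#' @export
cohort_tables <- function(patients, labs, events, treatments,
                          pretreatment_window_days = 30) {
  obj <- structure(list(patients = patients, labs = labs, events = events,
                        treatments = treatments),
                   pretreatment_window_days = pretreatment_window_days,
                   class = "cd4_cohort")
  validate_cohort(obj)
  obj
}

validate_cohort <- function(x) {
  stopifnot(inherits(x, "cd4_cohort"))
  ids <- x$patients$patient_id
  if (anyDuplicated(ids))
    stop("cohort: duplicated patient_id in patients table", call. = FALSE)
  for (tab in c("labs", "events", "treatments")) {
    extra <- setdiff(x[[tab]]$patient_id, ids)
    if (length(extra))
      stop("cohort: ", tab, " reference unknown patient_id: ",
           paste(utils::head(extra, 3), collapse = ", "), call. = FALSE)
  }
  win <- attr(x, "pretreatment_window_days") %||% 30
  if (nrow(x$labs)) {
    start <- x$patients$cart_start[match(x$labs$patient_id, ids)]
    if (any(as.numeric(x$labs$date - start) < -win))
      stop("cohort: lab dated more than ", win,
           " days before cART start", call. = FALSE)
    cd4 <- x$labs$value[x$labs$analyte == "CD4"]
    if (any(cd4 < 0)) stop("cohort: negative CD4 value", call. = FALSE)
    vl <- x$labs$value[x$labs$analyte == "VL"]
    if (any(vl < 1)) stop("cohort: VL below 1 copies/mL", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.cd4_cohort <- function(x, ...) {
  cat("cd4slope cohort: ", nrow(x$patients), " patients, ",
      nrow(x$labs), " lab results, ", nrow(x$events), " clinical events, ",
      nrow(x$treatments), " treatment episodes\n", sep = "")
  invisible(x)
}

# Per-visit rebound probability after suppression, solved so that the
# marginal suppressed fraction at 12 months matches p_still_suppressed_12m
# given p_suppress_6m and the expected number of visits between 6 and 12
# months under the routine-interval distribution.
solve_rebound_prob <- function(cfg) {
  if (cfg$p_still_suppressed_12m >= cfg$p_suppress_6m) return(0)
  mean_gap <- exp(cfg$visit_interval_log_location +
                  cfg$visit_interval_log_scale^2 / 2)
  n_visits <- (DAYS_PER_YEAR - DAYS_PER_YEAR / 2) / mean_gap
  f <- function(r) {
    cfg$p_suppress_6m * (1 - r)^n_visits - cfg$p_still_suppressed_12m
  }
  stats::uniroot(f, c(0, 0.999), tol = 1e-12)$root
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a seeded synthetic cohort
#'
#' Simulates patients, dated laboratory results (CD4, viral load,
#' haemoglobin), clinical events and treatment episodes with the
#' longitudinal structure described in \code{\link{generator_config}}:
#' visit dates by cumulative log-normal gaps (denser in the first months);
#' a viral-load trajectory that declines to the detection limit by
#' \code{suppression_day} for suppressing patients, with a calibrated
#' constant per-visit rebound probability thereafter, and a persistent
#' per-patient set point for unsuppressed patients; and a latent CD4
#' trajectory advanced between visits at the phase-1 slope up to day 183
#' and afterwards at the true-model linear predictor evaluated at the
#' covariates of the earlier visit plus a patient-level random effect,
#' observed with additive Gaussian noise and floored at zero.
#'
#' @param config a \code{\link{generator_config}}.
#' @return a \code{\link{cohort_tables}} object.
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  cfg <- config
  set_seed_strict(cfg$seed)
  n <- cfg$n_patients

  if (n == 0) {
    empty_date <- as.Date(character())
    return(cohort_tables(
      patients = data.frame(patient_id = character(), sex = character(),
                            birth_date = empty_date, cart_start = empty_date,
                            regimen_nnrti = integer(),
                            regimen_boosted_pi = integer(),
                            regimen_nonboosted_pi = integer(),
                            abacavir = integer(), hepatitis_bc = integer(),
                            stringsAsFactors = FALSE),
      labs = data.frame(patient_id = character(), date = empty_date,
                        analyte = character(), value = numeric(),
                        stringsAsFactors = FALSE),
      events = data.frame(patient_id = character(), date = empty_date,
                          event = character(), stringsAsFactors = FALSE),
      treatments = data.frame(patient_id = character(), start = empty_date,
                              stop = empty_date, classes = character(),
                              stringsAsFactors = FALSE),
      pretreatment_window_days = cfg$pretreatment_window_days))
  }

  tm <- cfg$true_model
  rebound_p <- solve_rebound_prob(cfg)
  log10_lod <- log10(cfg$detection_limit)
  censored_value <- cfg$detection_limit / 2

  ## ---- patient-level draws (vectorised) ----
  pid <- sprintf("P%05d", seq_len(n))
  female <- as.integer(stats::runif(n) >= cfg$prop_male)
  age0 <- rnorm_trunc(n, cfg$age_location, cfg$age_scale, 18, 75)
  hepatitis <- as.integer(stats::runif(n) < cfg$prop_hepatitis)
  p_stage <- cfg$stage_probs
  stage0 <- sample(STAGE_LEVELS, n, replace = TRUE,
                   prob = c(p_stage[1] + (1 - sum(p_stage)),
                            p_stage[2], p_stage[3]))
  p_reg <- cfg$regimen_probs
  regimen <- sample(c("NNRTI", "NONBOOSTED_PI", "BOOSTED_PI", "OTHER"), n,
                    replace = TRUE, prob = c(p_reg, 1 - sum(p_reg)))
  abacavir <- as.integer(stats::runif(n) < cfg$prop_abacavir)
  cd4_0 <- exp(rnorm_trunc(n, cfg$baseline_cd4_log_location,
                           cfg$baseline_cd4_log_scale, log(1), log(1200)))
  log10vl_0 <- rnorm_trunc(n, cfg$baseline_log10vl_location,
                           cfg$baseline_log10vl_scale, 2.7, 7)
  followup_days <- pmax(30, round(exp(stats::rnorm(
    n, cfg$followup_log_location, cfg$followup_log_scale)) * DAYS_PER_YEAR))
  suppressor <- stats::runif(n) < cfg$p_suppress_6m
  fail_level <- pmax(log10_lod + 0.05,
                     stats::rnorm(n, cfg$fail_log10vl_location,
                                  cfg$fail_log10vl_scale))
  phase1_slope <- stats::rnorm(n, cfg$phase1_slope_mean, cfg$phase1_slope_sd)
  b_i <- stats::rnorm(n, 0, cfg$sigma_b)
  hb_mean <- rnorm_trunc(n, cfg$haemoglobin_location, cfg$haemoglobin_scale,
                         6, 20)
  cart_start <- as.Date("2003-01-01") + sample.int(2191L, n, replace = TRUE) - 1L
  birth_date <- cart_start - round(age0 * DAYS_PER_YEAR)
  tb_day <- stats::rexp(n, rate = pmax(cfg$tb_incidence, 1e-12)) * DAYS_PER_YEAR
  adi_day <- stats::rexp(n, rate = pmax(cfg$adi_incidence, 1e-12)) * DAYS_PER_YEAR
  change_day <- stats::rexp(n, rate = pmax(cfg$class_change_rate, 1e-12)) *
    DAYS_PER_YEAR
  has_gap <- stats::runif(n) < cfg$gap_prob
  gap_len <- ifelse(has_gap, stats::runif(n, 31, 120), stats::runif(n, 0, 14))

  ## ---- per-patient trajectories ----
  acc_pid <- vector("list", n); acc_day <- vector("list", n)
  acc_analyte <- vector("list", n); acc_value <- vector("list", n)
  ev_pid <- vector("list", n); ev_day <- vector("list", n)
  ev_type <- vector("list", n)
  tr_pid <- vector("list", n); tr_start <- vector("list", n)
  tr_stop <- vector("list", n); tr_classes <- vector("list", n)

  n_early <- length(cfg$early_visit_log_locations)
  third_class <- c(NNRTI = "NNRTI", NONBOOSTED_PI = "PI",
                   BOOSTED_PI = "BPI", OTHER = "NRTI")

  # per-patient fixed part of the true-model linear predictor
  lp_base <- tm$constant +
    tm$beta_female * female +
    tm$beta_haemoglobin * hb_mean +
    tm$beta_hepatitis * hepatitis +
    tm$beta_nnrti * (regimen == "NNRTI") +
    tm$beta_boosted_pi * (regimen == "BOOSTED_PI") +
    tm$beta_abacavir * abacavir +
    b_i
  beta_period <- c(P6_12 = 0, P12_18 = tm$beta_period_12_18,
                   P18_24 = tm$beta_period_18_24,
                   P24PLUS = tm$beta_period_24plus)

  for (i in seq_len(n)) {
    fu <- followup_days[i]
    gaps_early <- exp(stats::rnorm(n_early, cfg$early_visit_log_locations,
                                   cfg$early_visit_log_scale))
    n_routine <- ceiling(fu / exp(cfg$visit_interval_log_location -
                                  cfg$visit_interval_log_scale)) + 3L
    gaps <- c(gaps_early,
              exp(stats::rnorm(n_routine, cfg$visit_interval_log_location,
                               cfg$visit_interval_log_scale)))
    days <- cumsum(pmax(1, round(gaps)))
    while (days[length(days)] < fu) {
      g <- max(1, round(exp(stats::rnorm(1, cfg$visit_interval_log_location,
                                         cfg$visit_interval_log_scale))))
      days <- c(days, days[length(days)] + g)
    }
    days <- c(0, days[days <= fu])
    K <- length(days)

    ## viral load (true log10 scale, then censor at the detection limit)
    lvl <- numeric(K)
    if (suppressor[i]) {
      pre <- days < cfg$suppression_day
      lvl[pre] <- log10vl_0[i] -
        (log10vl_0[i] - (log10_lod - 0.5)) * days[pre] / cfg$suppression_day
      post_idx <- which(!pre)
      np <- length(post_idx)
      if (np) {
        lvl[post_idx] <- log10_lod - 1        # suppressed
        if (np > 1 && rebound_p > 0) {
          u <- stats::runif(np - 1)
          hit <- which(u < rebound_p)
          if (length(hit)) {
            kk <- post_idx[hit[1] + 1]:K
            lvl[kk] <- pmax(log10_lod + 0.05,
                            fail_level[i] +
                              stats::rnorm(length(kk), 0,
                                           cfg$fail_log10vl_jitter))
          }
        }
      }
    } else {
      lvl[1] <- log10vl_0[i]
      if (K > 1)
        lvl[-1] <- pmax(log10_lod + 0.05,
                        fail_level[i] +
                          stats::rnorm(K - 1, 0, cfg$fail_log10vl_jitter))
    }
    vl_obs <- ifelse(lvl < log10_lod, censored_value, 10^lvl)
    log10_vl_stored <- log10(vl_obs)

    ## covariate paths at each visit (vectorised)
    stage_tb <- stage0[i] == "TB_ADI" | tb_day[i] <= days
    stage_nontb <- !stage_tb & (stage0[i] == "NONTB_ADI" | adi_day[i] <= days)
    per_idx <- findInterval(pmax(days, PHASE_BOUNDARY_DAYS + 1) /
                              DAYS_PER_MONTH, c(6, 12, 18, 24))
    lp_fixed <- lp_base[i] +
      tm$beta_age_per10 * (age0[i] + days / DAYS_PER_YEAR) / 10 +
      tm$beta_tb * stage_tb + tm$beta_nontb_adi * stage_nontb +
      tm$beta_log10vl * log10_vl_stored +
      beta_period[per_idx]

    ## latent CD4 advanced visit-to-visit
    latent <- numeric(K)
    latent[1] <- cd4_0[i]
    if (K > 1) {
      b_cd4 <- tm$beta_cd4_per100 / 100
      p1 <- phase1_slope[i]
      for (k in seq_len(K - 1)) {
        d0 <- days[k]; d1 <- days[k + 1]
        adv <- 0
        if (d0 < PHASE_BOUNDARY_DAYS)
          adv <- p1 * (min(d1, PHASE_BOUNDARY_DAYS) - d0) / DAYS_PER_YEAR
        if (d1 > PHASE_BOUNDARY_DAYS)
          adv <- adv + (lp_fixed[k] + b_cd4 * latent[k]) *
            (d1 - max(d0, PHASE_BOUNDARY_DAYS)) / DAYS_PER_YEAR
        latent[k + 1] <- max(0, latent[k] + adv)
      }
    }
    cd4_obs <- pmax(0, latent + stats::rnorm(K, 0, cfg$sigma_m))
    hb_obs <- hb_mean[i] + stats::rnorm(K, 0, cfg$haemoglobin_visit_sd)
    hb_obs <- pmax(5, hb_obs)

    acc_pid[[i]] <- rep(pid[i], 3 * K)
    acc_day[[i]] <- rep(days, 3)
    acc_analyte[[i]] <- rep(c("CD4", "VL", "HB"), each = K)
    acc_value[[i]] <- c(cd4_obs, vl_obs, hb_obs)

    ## events: baseline stage plus incident events within follow-up
    edays <- numeric(0); etypes <- character(0)
    if (stage0[i] == "TB_ADI") { edays <- c(edays, 0); etypes <- c(etypes, "TB_ADI") }
    if (stage0[i] == "NONTB_ADI") { edays <- c(edays, 0); etypes <- c(etypes, "NONTB_ADI") }
    if (tb_day[i] <= fu) { edays <- c(edays, round(tb_day[i])); etypes <- c(etypes, "TB_ADI") }
    if (adi_day[i] <= fu) { edays <- c(edays, round(adi_day[i])); etypes <- c(etypes, "NONTB_ADI") }
    ev_pid[[i]] <- rep(pid[i], length(edays))
    ev_day[[i]] <- edays
    ev_type[[i]] <- etypes

    ## treatments: initial episode, optionally one class change (with gap)
    init_classes <- paste(c("NRTI", "NRTI", third_class[[regimen[i]]]),
                          collapse = ",")
    if (change_day[i] < fu) {
      stop1 <- round(change_day[i])
      start2 <- min(fu, stop1 + round(gap_len[i]))
      new_third <- if (third_class[[regimen[i]]] == "NNRTI") "BPI" else "NNRTI"
      tr_pid[[i]] <- rep(pid[i], 2)
      tr_start[[i]] <- c(0, start2)
      tr_stop[[i]] <- c(stop1, fu)
      tr_classes[[i]] <- c(init_classes,
                           paste(c("NRTI", "NRTI", new_third), collapse = ","))
    } else {
      tr_pid[[i]] <- pid[i]
      tr_start[[i]] <- 0
      tr_stop[[i]] <- fu
      tr_classes[[i]] <- init_classes
    }
  }

  lab_pid <- unlist(acc_pid)
  lab_start <- cart_start[match(lab_pid, pid)]
  labs <- data.frame(patient_id = lab_pid,
                     date = lab_start + unlist(acc_day),
                     analyte = unlist(acc_analyte),
                     value = unlist(acc_value),
                     stringsAsFactors = FALSE)
  epid <- unlist(ev_pid)
  events <- data.frame(patient_id = epid,
                       date = cart_start[match(epid, pid)] + unlist(ev_day),
                       event = unlist(ev_type),
                       stringsAsFactors = FALSE)
  tpid <- unlist(tr_pid)
  treatments <- data.frame(patient_id = tpid,
                           start = cart_start[match(tpid, pid)] + unlist(tr_start),
                           stop = cart_start[match(tpid, pid)] + unlist(tr_stop),
                           classes = unlist(tr_classes),
                           stringsAsFactors = FALSE)
  patients <- data.frame(patient_id = pid,
                         sex = ifelse(female == 1L, "F", "M"),
                         birth_date = birth_date,
                         cart_start = cart_start,
                         regimen_nnrti = as.integer(regimen == "NNRTI"),
                         regimen_boosted_pi = as.integer(regimen == "BOOSTED_PI"),
                         regimen_nonboosted_pi = as.integer(regimen == "NONBOOSTED_PI"),
                         abacavir = abacavir,
                         hepatitis_bc = hepatitis,
                         stringsAsFactors = FALSE)
  cohort_tables(patients, labs, events, treatments,
                pretreatment_window_days = cfg$pretreatment_window_days)
}
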