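# Helper: endpoint-shaped data frame with simulated covariates and slopes.
make_fake_endpoints <- function(n_patients, per_patient, sigma_b = 20,
                                sigma_e = 60, tm = true_model()) {
  n <- n_patients * per_patient
  id <- rep(sprintf("P%04d", seq_len(n_patients)), each = per_patient)
  ep <- data.frame(
    patient_id = id,
    t_days = round(runif(n, 190, 1500)),
    female = rep(rbinom(n_patients, 1, 0.3), each = per_patient),
    age_decades = rep(runif(n_patients, 2, 6), each = per_patient),
    stage = sample(c("REF", "TB_ADI", "NONTB_ADI"), n, TRUE,
                   prob = c(0.6, 0.2, 0.2)),
    haemoglobin = runif(n, 9, 16),
    cd4_per100 = runif(n, 0.5, 6),
    log10_vl = runif(n, 2.3, 6),
    hepatitis = rep(rbinom(n_patients, 1, 0.15), each = per_patient),
    nnrti = rep(rbinom(n_patients, 1, 0.6), each = per_patient),
    boosted_pi = rep(rbinom(n_patients, 1, 0.2), each = per_patient),
    abacavir = rep(rbinom(n_patients, 1, 0.2), each = per_patient),
    stringsAsFactors = FALSE)
  ep$period <- as.character(period_of_days(ep$t_days))
  lp <- cd4slope:::true_model_lp(tm, ep$female, ep$age_decades, ep$stage,
                                 ep$haemoglobin, ep$cd4_per100, ep$log10_vl,
                                 ep$hepatitis, ep$period, ep$nnrti,
                                 ep$boosted_pi, ep$abacavir)
  b <- rep(rnorm(n_patients, 0, sigma_b), each = per_patient)
  ep$slope <- lp + b + rnorm(n, 0, sigma_e)
  ep
}

test_that("design matrix expands blocks against their reference levels", {
  ep <- data.frame(stage = c("REF", "TB_ADI", "NONTB_ADI"),
                   period = c("P6_12", "P18_24", "P24PLUS"),
                   log10_vl = c(3, 4, 5))
  X <- build_design(ep, c("stage", "vl", "period"))
  expect_identical(colnames(X),
                   c("(Intercept)", "stageTB_ADI", "stageNONTB_ADI",
                     "log10_vl", "periodP12_18", "periodP18_24",
                     "periodP24PLUS"))
  expect_equal(unname(X[, "stageTB_ADI"]), c(0, 1, 0))
  expect_equal(unname(X[, "periodP24PLUS"]), c(0, 0, 1))
  expect_equal(unname(X[, "(Intercept)"]), rep(1, 3))
  expect_error(build_design(ep, "viralload"), "unknown term")
})

test_that("with all-singleton groups the fit collapses to least squares", {
  set.seed(101)
  sim <- simulate_ri(80, 1, beta = c(5, 2, -3), sigma_b = 0, sigma_e = 4)
  fit <- fit_random_intercept(sim$y, sim$X, sim$g)
  expect_true("sigma_b2_not_identifiable_all_groups_singleton" %in%
                fit$flags)
  expect_equal(fit$lambda, 0)
  ols <- lm(sim$y ~ sim$X - 1)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-10)
})

test_that("zero between-patient variance is estimated at the boundary", {
  set.seed(102)
  sim <- simulate_ri(40, 5, beta = c(1, 2), sigma_b = 0, sigma_e = 1)
  fit <- fit_random_intercept(sim$y, sim$X, sim$g)
  # lambda-hat is 0 (flagged) or negligibly small
  expect_lt(fit$sigma_b2, 0.15 * fit$sigma_e2)
})

test_that("an exact linear fit is flagged as degenerate", {
  X <- cbind("(Intercept)" = 1, x = 1:20)
  y <- 3 + 2 * (1:20)
  fit <- fit_random_intercept(y, X, rep(1:5, each = 4))
  expect_true("residual_variance_degenerate" %in% fit$flags)
  expect_equal(unname(fit$coefficients), c(3, 2), tolerance = 1e-6)
})

test_that("singular designs are rejected naming the collinear column", {
  X <- cbind("(Intercept)" = 1, a = 1:10, b = 2 * (1:10))
  expect_error(fit_random_intercept(rnorm(10), X, rep(1:5, 2)),
               "collinear column\\(s\\): b")
  expect_error(fit_random_intercept(rnorm(3), cbind(1, 1:3, 3:1, rnorm(3)),
                                    rep(1, 3)),
               "more observations than fixed effects")
  expect_error(fit_random_intercept(rnorm(4), cbind(1, 1:4), rep(1, 3)),
               "must align")
})

test_that("profiled fit agrees with the dense-matrix oracle", {
  set.seed(103)
  cases <- list(
    list(G = 25, m = 4, beta = c(10, -3, 2), sb = 8, se = 5),
    list(G = 40, m = 5, beta = c(0, 1), sb = 0.5, se = 3),
    list(G = 10, m = 12, beta = c(-4, 2, 1, 0), sb = 20, se = 1),
    list(G = 60, m = 2, beta = c(2, -1), sb = 2, se = 2))
  for (cs in cases) {
    sim <- simulate_ri(cs$G, cs$m, cs$beta, cs$sb, cs$se)
    expect_lte(length(sim$y), 200)
    for (crit in c("REML", "ML")) {
      fit <- fit_random_intercept(sim$y, sim$X, sim$g, crit)
      orc <- oracle_fit(sim$y, sim$X, sim$g, crit)
      expect_equal(unname(fit$coefficients), unname(orc$beta),
                   tolerance = 1e-6)
      expect_equal(unname(fit$se), unname(orc$se), tolerance = 1e-5)
      expect_equal(fit$sigma_e2, orc$sigma_e2, tolerance = 1e-5)
      expect_equal(fit$sigma_b2, orc$sigma_b2, tolerance = 1e-4)
    }
  }
})

test_that("profiled REML agrees with lme4 on a grouped dataset", {
  set.seed(104)
  sim <- simulate_ri(60, 6, beta = c(100, -40, 5), sigma_b = 25,
                     sigma_e = 60)
  fit <- fit_random_intercept(sim$y, sim$X, sim$g, "REML")
  df <- data.frame(y = sim$y, x1 = sim$X[, 2], x2 = sim$X[, 3], g = sim$g)
  lfit <- lme4::lmer(y ~ x1 + x2 + (1 | g), data = df, REML = TRUE)
  expect_equal(unname(fit$coefficients), unname(lme4::fixef(lfit)),
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(fit$sigma_b2, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma_e2, vc$vcov[2], tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lfit)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(coef(summary(lfit))[, "Std. Error"]),
               tolerance = 1e-4)
})

test_that("the fit is invariant to row permutation", {
  set.seed(105)
  sim <- simulate_ri(30, 4, beta = c(2, -1, 0.5), sigma_b = 3, sigma_e = 2)
  fit <- fit_random_intercept(sim$y, sim$X, sim$g)
  perm <- sample(length(sim$y))
  fit2 <- fit_random_intercept(sim$y[perm], sim$X[perm, ], sim$g[perm])
  expect_equal(fit$coefficients, fit2$coefficients, tolerance = 1e-6)
  expect_equal(fit$sigma_b2, fit2$sigma_b2, tolerance = 1e-5)
})

test_that("confidence limits and p-values follow the Wald construction", {
  set.seed(106)
  sim <- simulate_ri(30, 4, beta = c(2, -1), sigma_b = 3, sigma_e = 2)
  fit <- fit_random_intercept(sim$y, sim$X, sim$g)
  expect_equal(fit$ci_low, fit$coefficients - 1.96 * fit$se)
  expect_equal(fit$ci_high, fit$coefficients + 1.96 * fit$se)
  z <- fit$coefficients / fit$se
  expect_equal(fit$wald_p, 2 * pnorm(-abs(z)))
  # single-coefficient block test equals the squared-z chi-square test
  expect_equal(cd4slope:::block_wald_p(fit, "x1"),
               unname(pchisq(z["x1"]^2, 1, lower.tail = FALSE)),
               tolerance = 1e-10)
})

test_that("model rows are restricted to beyond 183 days", {
  set.seed(107)
  ep <- make_fake_endpoints(30, 4)
  ep$t_days[1:10] <- 100
  fit <- cd4slope:::fit_terms(ep, c("vl", "period"))
  expect_equal(fit$n_obs, nrow(ep) - 10L)
})

test_that("univariate scan fits every block and survives degenerate ones", {
  set.seed(108)
  ep <- make_fake_endpoints(60, 4)
  ep$abacavir <- 0L                       # constant: singular design
  fits <- univariate_scan(ep)
  expect_named(fits, c("female", "age", "stage", "haemoglobin", "cd4",
                       "vl", "hepatitis", "period", "nnrti", "boosted_pi",
                       "abacavir"))
  expect_s3_class(fits$vl, "cd4_model_fit")
  expect_true(inherits(fits$abacavir, "condition"))
  expect_match(conditionMessage(fits$abacavir), "collinear")
  # the strong simulated VL effect is detected with the right sign
  expect_lt(fits$vl$coefficients[["log10_vl"]], 0)
  expect_lt(fits$vl$wald_p[["log10_vl"]], 0.001)
  expect_error(univariate_scan(ep[0, ]), "empty endpoint table")
})

test_that("forward selection retains strong effects and reports the rest", {
  set.seed(109)
  ep <- make_fake_endpoints(150, 5, sigma_b = 15, sigma_e = 45)
  sel <- forward_select(ep, c("vl", "period", "abacavir", "haemoglobin"))
  expect_true(all(c("vl", "period") %in% sel$selected))
  expect_setequal(c(sel$selected, names(sel$dropped)),
                  c("vl", "period", "abacavir", "haemoglobin"))
  expect_true(all(sel$trace$p_entry <= 0.20))
  expect_identical(sel$fit$source, "fitted")
  # selected blocks appear in canonical candidate order in the final fit
  expect_identical(sel$selected,
                   intersect(c("vl", "period", "abacavir", "haemoglobin"),
                             sel$selected))
  expect_error(forward_select(ep, character(0)), "no candidates")
})

test_that("selection stops when nothing meets the entry level", {
  set.seed(110)
  ep <- make_fake_endpoints(40, 3,
                            tm = true_model(constant = 0, beta_female = 0,
                                            beta_age_per10 = 0, beta_tb = 0,
                                            beta_nontb_adi = 0,
                                            beta_haemoglobin = 0,
                                            beta_cd4_per100 = 0,
                                            beta_log10vl = 0,
                                            beta_hepatitis = 0,
                                            beta_period_12_18 = 0,
                                            beta_period_18_24 = 0,
                                            beta_period_24plus = 0,
                                            beta_nnrti = 0,
                                            beta_boosted_pi = 0,
                                            beta_abacavir = 0))
  ep$slope <- rnorm(nrow(ep), 0, 1)      # pure noise
  # with a single noise candidate, selection usually fails at alpha = 0.2;
  # force certain failure with a tiny alpha
  expect_error(forward_select(ep, "haemoglobin", alpha = 1e-12),
               "no candidate met the entry level")
})

test_that("a pure-noise candidate enters at roughly the entry level", {
  set.seed(111)
  n_reps <- 300
  entered <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    n_g <- 30; m <- 4; n <- n_g * m
    ep <- data.frame(
      patient_id = rep(sprintf("G%03d", 1:n_g), each = m),
      t_days = 200, slope = rnorm(n, 50, 30),
      haemoglobin = runif(n, 9, 16), stringsAsFactors = FALSE)
    sel <- tryCatch(forward_select(ep, "haemoglobin", alpha = 0.20),
                    error = function(e) NULL)
    entered[r] <- !is.null(sel)
  }
  rate <- mean(entered)
  expect_gt(rate, 0.13)
  expect_lt(rate, 0.27)
})

test_that("the report table lays out both fits in the published format", {
  set.seed(112)
  ep <- make_fake_endpoints(80, 4)
  uni <- univariate_scan(ep, c("female", "vl"))
  tab <- report_table(uni, published_coefficients())
  expect_identical(names(tab),
                   c("covariate", "level", "uni_est", "uni_ci", "uni_p",
                     "multi_est", "multi_ci", "multi_p"))
  # reference rows show 0.0 in both estimate columns
  male <- tab[tab$level == "Male*", ]
  expect_identical(male$uni_est, "0.0")
  expect_identical(male$multi_est, "0.0")
  fem <- tab[tab$level == "Female", ]
  expect_identical(fem$multi_est, "7.8")
  expect_identical(fem$multi_ci, "(-1.5, 17.2)")
  expect_identical(fem$multi_p, "0.099")
  vl <- tab[tab$level == "per log10 copies/mL higher", ]
  expect_identical(vl$multi_est, "-40.5")
  expect_identical(vl$multi_p, "< 0.001")
  expect_identical(tab[tab$covariate == "Constant", "multi_est"], "205.5")
  # blocks not scanned leave their univariate cells blank
  expect_identical(vl$uni_est == "", FALSE)
  expect_identical(tab[tab$level == "Yes" &
                       tab$covariate == "Hepatitis B or C coinfection",
                       "uni_est"], "")
})

test_that("the report table handles empty input and boundary footnotes", {
  tab <- report_table()
  expect_identical(nrow(tab), 0L)
  expect_identical(attr(tab, "footnotes"), character(0))

  set.seed(113)
  sim <- simulate_ri(40, 5, beta = c(1, 2), sigma_b = 0, sigma_e = 1)
  fit <- fit_random_intercept(sim$y, sim$X, sim$g)
  tab2 <- report_table(list(), fit)
  if ("sigma_b2_boundary_zero" %in% fit$flags)
    expect_match(attr(tab2, "footnotes"), "zero boundary")
})
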