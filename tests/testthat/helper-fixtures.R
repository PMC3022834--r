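# Small hand-built cohort fixtures shared across test files.

BASE_DATE <- as.Date("2005-01-01")

# A minimal cohort: one patient, lab days and values supplied directly.
tiny_cohort <- function(cd4_days, cd4_values,
                        vl_days = cd4_days,
                        vl_values = rep(1000, length(vl_days)),
                        hb_days = numeric(0), hb_values = numeric(0),
                        classes = "NRTI,NRTI,NNRTI",
                        sex = "M", hepatitis = 0L, age_years = 30,
                        events = data.frame(day = numeric(0),
                                            event = character(0)),
                        id = "P1") {
  patients <- data.frame(
    patient_id = id, sex = sex,
    birth_date = BASE_DATE - round(age_years * 365.25),
    cart_start = BASE_DATE,
    regimen_nnrti = as.integer(grepl("NNRTI", classes)),
    regimen_boosted_pi = as.integer(grepl("BPI", classes)),
    regimen_nonboosted_pi = 0L, abacavir = 0L,
    hepatitis_bc = hepatitis, stringsAsFactors = FALSE)
  labs <- data.frame(
    patient_id = id,
    date = BASE_DATE + c(cd4_days, vl_days, hb_days),
    analyte = rep(c("CD4", "VL", "HB"),
                  c(length(cd4_days), length(vl_days), length(hb_days))),
    value = c(cd4_values, vl_values, hb_values),
    stringsAsFactors = FALSE)
  ev <- data.frame(patient_id = rep(id, nrow(events)),
                   date = BASE_DATE + events$day,
                   event = events$event, stringsAsFactors = FALSE)
  treatments <- data.frame(patient_id = id, start = BASE_DATE,
                           stop = BASE_DATE + max(c(cd4_days, vl_days, 1)),
                           classes = classes, stringsAsFactors = FALSE)
  cohort_tables(patients, labs, ev, treatments)
}

# Merge several tiny cohorts (distinct ids) into one cohort object.
bind_cohorts <- function(...) {
  parts <- list(...)
  cohort_tables(
    patients = do.call(rbind, lapply(parts, `[[`, "patients")),
    labs = do.call(rbind, lapply(parts, `[[`, "labs")),
    events = do.call(rbind, lapply(parts, `[[`, "events")),
    treatments = do.call(rbind, lapply(parts, `[[`, "treatments")))
}

# Simulate a grouped random-intercept dataset with known parameters.
simulate_ri <- function(n_groups, per_group, beta, sigma_b, sigma_e,
                        x_fun = function(n) cbind(1, matrix(rnorm(n * (length(beta) - 1)),
                                                            nrow = n))) {
  n <- n_groups * per_group
  g <- rep(seq_len(n_groups), each = per_group)
  X <- x_fun(n)
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  b <- rnorm(n_groups, 0, sigma_b)
  y <- drop(X %*% beta) + b[g] + rnorm(n, 0, sigma_e)
  list(y = y, X = X, g = g)
}
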