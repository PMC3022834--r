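# End-to-end pipeline: generate -> pair -> endpoints -> fit -> predict,
# with a run manifest and full determinism under a fixed seed.

#' Virological suppression at 6 and 12 months
#'
#' Per patient, the viral load nearest day 183 (respectively 365) within a
#' +/- \code{window_days} window; the summary is the fraction below the
#' threshold among patients with a test in the window.
#'
#' @param cohort a \code{\link{cohort_tables}} object.
#' @param threshold copies/mL defining suppression (default 400).
#' @param window_days half-width of the search window (default 90).
#' @return list with frac_6m, frac_12m, n_6m, n_12m and an
#'   \code{undefined} flag set when a denominator is zero.
#' @export
suppression_summary <- function(cohort, threshold = 400, window_days = 90) {
  labs <- cohort$labs[cohort$labs$analyte == "VL", , drop = FALSE]
  start <- cohort$patients$cart_start[match(labs$patient_id,
                                            cohort$patients$patient_id)]
  day <- as.numeric(labs$date - start)
  frac_at <- function(target) {
    sel <- abs(day - target) <= window_days
    if (!any(sel)) return(list(frac = NA_real_, n = 0L))
    d <- abs(day - target)[sel]
    sub <- data.frame(id = labs$patient_id[sel], d = d,
                      v = labs$value[sel])
    sub <- sub[order(sub$id, sub$d), ]
    first <- !duplicated(sub$id)
    list(frac = mean(sub$v[first] < threshold), n = sum(first))
  }
  s6 <- frac_at(DAYS_PER_YEAR / 2)
  s12 <- frac_at(DAYS_PER_YEAR)
  list(frac_6m = s6$frac, frac_12m = s12$frac,
       n_6m = s6$n, n_12m = s12$n,
       undefined = s6$n == 0L || s12$n == 0L)
}

fit_to_list <- function(fit) {
  list(coefficients = as.list(fit$coefficients),
       se = as.list(fit$se),
       ci_low = as.list(fit$ci_low),
       ci_high = as.list(fit$ci_high),
       wald_p = as.list(fit$wald_p),
       sigma_b2 = fit$sigma_b2,
       sigma_e2 = fit$sigma_e2,
       loglik = fit$loglik,
       criterion = fit$criterion,
       n_obs = fit$n_obs,
       n_patients = fit$n_patients,
       constant = fit$constant,
       flags = fit$flags)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a cohort, writes it out, builds concurrent pairs
#' and slope endpoints, fits the final random-intercept model by forward
#' selection, renders the coefficient report and a prediction grid, and
#' writes a manifest of row counts and file hashes.  Re-running with the
#' same configuration and seed reproduces identical numeric outputs.
#'
#' @param config a \code{\link{generator_config}} or path to a YAML file.
#' @param out_dir output directory.
#' @param seed optional root seed overriding the config's.
#' @param candidates candidate covariate blocks for forward selection.
#' @param alpha forward-selection entry level.
#' @return the manifest, invisibly (also written to manifest.json).
#' @export
run_all <- function(config, out_dir, seed = NULL,
                    candidates = DEFAULT_CANDIDATES, alpha = 0.20) {
  if (is.character(config)) config <- read_generator_config(config)
  validate_generator_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(stage, e) {
    unlink(written, recursive = TRUE)
    stop_named(stage, conditionMessage(e))
  }

  cohort <- tryCatch(generate_cohort(config),
                     error = function(e) on_fail("cohortgen", e))
  cohort_dir <- file.path(out_dir, "cohort")
  written <- c(written, cohort_dir)
  write_cohort(cohort, cohort_dir)

  endpoints_path <- file.path(out_dir, "endpoints.csv")
  res <- tryCatch({
    pairs <- pair_concurrent(cohort)
    elig <- eligible_patients(cohort, pairs)
    if (!length(elig)) stop("no eligible patients", call. = FALSE)
    pairs_elig <- pairs[pairs$patient_id %in% elig, , drop = FALSE]
    endpoints <- build_endpoints(cohort, pairs_elig)
    list(pairs = pairs, elig = elig, endpoints = endpoints)
  }, error = function(e) on_fail("endpoints", e))
  utils::write.csv(res$endpoints, endpoints_path, row.names = FALSE)
  written <- c(written, endpoints_path)

  phase <- phase_slope_summary(res$endpoints)
  suppression <- suppression_summary(cohort)

  sel <- tryCatch(forward_select(res$endpoints, candidates, alpha = alpha),
                  error = function(e) on_fail("fit", e))
  fit_path <- file.path(out_dir, "fit.json")
  jsonlite::write_json(fit_to_list(sel$fit), fit_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  written <- c(written, fit_path)

  uni <- tryCatch(univariate_scan(res$endpoints),
                  error = function(e) on_fail("fit", e))
  report <- report_table(uni, sel$fit)
  report_path <- file.path(out_dir, "report.md")
  writeLines(c("| covariate | level | univariate | 95% CI | p | multivariate | 95% CI | p |",
               "|---|---|---|---|---|---|---|---|",
               apply(report, 1, function(r)
                 paste0("| ", paste(r, collapse = " | "), " |")),
               if (length(attr(report, "footnotes")))
                 paste0("\n", attr(report, "footnotes"))),
             report_path)
  written <- c(written, report_path)

  grid <- tryCatch(build_grid(patient_profile(), sel$fit),
                   error = function(e) on_fail("predict", e))
  grid_path <- file.path(out_dir, "grid.tsv")
  utils::write.table(grid$rounded, grid_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  written <- c(written, grid_path)

  n_model <- sum(res$endpoints$t_days > PHASE_BOUNDARY_DAYS)
  counts <- list(n_patients = nrow(cohort$patients),
                 n_pairs = nrow(res$pairs),
                 n_eligible = length(res$elig),
                 n_endpoints = nrow(res$endpoints),
                 n_model_obs = sel$fit$n_obs,
                 n_model_patients = sel$fit$n_patients)
  if (counts$n_endpoints > counts$n_pairs ||
      counts$n_model_obs > counts$n_endpoints)
    on_fail("manifest", simpleError("row counts not monotone"))
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cd4slope")),
    config_hash = unname(tools::md5sum(file.path(cohort_dir,
                                                 "patients.csv"))),
    counts = counts,
    phase_summary = phase[c("mean_slope_early", "mean_slope_late",
                            "n_early", "n_late", "p_value")],
    suppression = suppression[c("frac_6m", "frac_12m")],
    selected_terms = sel$selected,
    outputs = list(cohort = cohort_dir, endpoints = endpoints_path,
                   fit = fit_path, report = report_path, grid = grid_path))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
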