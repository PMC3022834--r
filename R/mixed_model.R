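# Random-intercept linear regression by profile (RE)ML.
#
# Model: y_ij = x_ij' beta + b_i + e_ij, b_i ~ N(0, sigma_b^2),
# e_ij ~ N(0, sigma_e^2).  Writing lambda = sigma_b^2 / sigma_e^2 and
# W = (I + lambda Z Z')^{-1}, beta and sigma_e^2 have closed-form GLS
# solutions at fixed lambda; the criterion is minimised over log(lambda) in
# one dimension, with the boundary lambda = 0 (no between-patient
# variance) checked explicitly.  For grouped data the profiled criterion is
# computed from sufficient statistics (X'X, X'y, y'y and per-group sums),
# so each lambda evaluation costs O(G p^2) after a single O(n p^2) pass.

MODEL_BLOCKS <- list(
  female = "female",
  age = "age_decades",
  stage = c("stageTB_ADI", "stageNONTB_ADI"),
  haemoglobin = "haemoglobin",
  cd4 = "cd4_per100",
  vl = "log10_vl",
  hepatitis = "hepatitis",
  period = c("periodP12_18", "periodP18_24", "periodP24PLUS"),
  nnrti = "nnrti",
  boosted_pi = "boosted_pi",
  abacavir = "abacavir"
)

DEFAULT_CANDIDATES <- names(MODEL_BLOCKS)

#' Design matrix for the slope model
#'
#' Builds the fixed-effects design (with intercept) for the requested
#' covariate blocks; categorical blocks (stage, period) expand to indicator
#' contrasts against their reference level (CDC category A; 6-12 months).
#'
#' @param endpoints endpoint table (see \code{\link{build_endpoints}}).
#' @param terms character vector of block names among
#'   \code{female, age, stage, haemoglobin, cd4, vl, hepatitis, period,
#'   nnrti, boosted_pi, abacavir}.
#' @return numeric matrix with an \code{"(Intercept)"} column.
#' @export
build_design <- function(endpoints, terms = DEFAULT_CANDIDATES) {
  unknown <- setdiff(terms, names(MODEL_BLOCKS))
  if (length(unknown))
    stop("build_design: unknown term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- nrow(endpoints)
  cols <- list("(Intercept)" = rep(1, n))
  for (term in terms) {
    if (term == "stage") {
      cols[["stageTB_ADI"]] <- as.numeric(endpoints$stage == "TB_ADI")
      cols[["stageNONTB_ADI"]] <- as.numeric(endpoints$stage == "NONTB_ADI")
    } else if (term == "period") {
      cols[["periodP12_18"]] <- as.numeric(endpoints$period == "P12_18")
      cols[["periodP18_24"]] <- as.numeric(endpoints$period == "P18_24")
      cols[["periodP24PLUS"]] <- as.numeric(endpoints$period == "P24PLUS")
    } else {
      v <- MODEL_BLOCKS[[term]]
      cols[[v]] <- as.numeric(endpoints[[v]])
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

model_rows <- function(endpoints) {
  endpoints[endpoints$t_days > PHASE_BOUNDARY_DAYS, , drop = FALSE]
}

# Profiled -2 criterion at lambda, from sufficient statistics.
ri_criterion <- function(lambda, ss, criterion) {
  c_g <- lambda / (1 + lambda * ss$m)
  A <- ss$XtX - crossprod(ss$SX, ss$SX * c_g)
  b <- ss$Xty - drop(crossprod(ss$SX, c_g * ss$SY))
  beta <- solve(A, b)
  rss <- max(ss$yty - sum(c_g * ss$SY^2) - sum(b * beta), 1e-300)
  sumlog <- sum(log1p(lambda * ss$m))
  ldA <- determinant(A, logarithm = TRUE)$modulus
  if (criterion == "REML") {
    df <- ss$n - ss$p
    list(crit = df * log(rss / df) + sumlog + as.numeric(ldA),
         beta = beta, A = A, rss = rss)
  } else {
    list(crit = ss$n * log(rss / ss$n) + sumlog,
         beta = beta, A = A, rss = rss)
  }
}

#' Fit a random-intercept linear model by profile (RE)ML
#'
#' @param y numeric response (CD4 slopes, cells/uL/year).
#' @param X design matrix including an intercept column.
#' @param groups patient identifiers (one per row of \code{X}).
#' @param criterion \code{"REML"} (default) or \code{"ML"}.
#' @return an object of class \code{cd4_model_fit} with coefficients,
#'   standard errors, 95\% Wald confidence limits
#'   (estimate +/- 1.96 se), two-sided Wald p-values against the standard
#'   normal, variance components, log-likelihood and fit metadata.
#' @export
fit_random_intercept <- function(y, X, groups, criterion = c("REML", "ML")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || length(groups) != n)
    stop("fit_random_intercept: y, X and groups must align", call. = FALSE)
  if (n <= p)
    stop("fit_random_intercept: need more observations than fixed effects",
         call. = FALSE)
  qr_X <- qr(X)
  if (qr_X$rank < p) {
    bad <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):p]]
    stop("fit_random_intercept: singular design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  g <- factor(groups)
  m <- as.numeric(table(g))
  SX <- rowsum(X, g)                      # per-group column sums, G x p
  SY <- as.numeric(rowsum(y, g))
  ss <- list(XtX = crossprod(X), Xty = drop(crossprod(X, y)),
             yty = sum(y^2), SX = SX, SY = SY, m = m, n = n, p = p)

  flags <- character(0)
  all_singletons <- all(m == 1)
  if (all_singletons) {
    lambda <- 0
    flags <- c(flags, "sigma_b2_not_identifiable_all_groups_singleton")
  } else {
    obj <- function(loglam) ri_criterion(exp(loglam), ss, criterion)$crit
    opt <- stats::optimize(obj, interval = c(-16, 16), tol = 1e-10)
    crit0 <- ri_criterion(0, ss, criterion)$crit
    lambda <- if (crit0 <= opt$objective) 0 else exp(opt$minimum)
    if (lambda == 0) flags <- c(flags, "sigma_b2_boundary_zero")
  }
  at <- ri_criterion(lambda, ss, criterion)
  df <- if (criterion == "REML") n - p else n
  sigma_e2 <- at$rss / df
  sigma_b2 <- lambda * sigma_e2
  if (sigma_e2 < 1e-10) flags <- c(flags, "residual_variance_degenerate")
  Ainv <- solve(at$A)
  se <- sqrt(pmax(diag(Ainv), 0) * sigma_e2)
  beta <- drop(at$beta)
  names(se) <- names(beta) <- colnames(X)
  z <- ifelse(se > 0, beta / se, NA_real_)
  sumlog <- sum(log1p(lambda * m))
  ldA <- as.numeric(determinant(at$A, logarithm = TRUE)$modulus)
  loglik <- if (criterion == "REML") {
    -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma_e2) + sumlog +
            ldA + at$rss / sigma_e2)
  } else {
    -0.5 * (n * log(2 * pi) + n * log(sigma_e2) + sumlog +
            at$rss / sigma_e2)
  }
  structure(list(coefficients = beta,
                 se = se,
                 ci_low = beta - 1.96 * se,
                 ci_high = beta + 1.96 * se,
                 wald_z = z,
                 wald_p = 2 * stats::pnorm(-abs(z)),
                 sigma_b2 = sigma_b2,
                 sigma_e2 = sigma_e2,
                 lambda = lambda,
                 loglik = loglik,
                 criterion = criterion,
                 n_obs = n,
                 n_patients = nlevels(g),
                 constant = unname(beta["(Intercept)"]),
                 vcov = Ainv * sigma_e2,
                 flags = flags,
                 source = "fitted"),
            class = "cd4_model_fit")
}

#' @export
print.cd4_model_fit <- function(x, ...) {
  cat("Random-intercept slope model (", x$criterion, "), ",
      x$n_obs, " observations / ", x$n_patients, " patients\n", sep = "")
  tab <- data.frame(estimate = round(x$coefficients, 2),
                    se = round(x$se, 2),
                    ci_low = round(x$ci_low, 2),
                    ci_high = round(x$ci_high, 2),
                    p = signif(x$wald_p, 3))
  print(tab)
  cat("sigma_b^2 =", signif(x$sigma_b2, 4),
      " sigma_e^2 =", signif(x$sigma_e2, 4),
      " logLik =", signif(x$loglik, 6), "\n")
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Joint Wald test for a set of coefficients of a fit.
block_wald_p <- function(fit, cols) {
  cols <- intersect(cols, names(fit$coefficients))
  b <- fit$coefficients[cols]
  V <- fit$vcov[cols, cols, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  stats::pchisq(stat, df = length(cols), lower.tail = FALSE)
}

fit_terms <- function(endpoints, terms, criterion = "REML") {
  ep <- model_rows(endpoints)
  X <- build_design(ep, terms)
  fit_random_intercept(ep$slope, X, ep$patient_id, criterion)
}

#' Univariate random-intercept scans
#'
#' One fit per covariate block (categorical blocks fitted jointly with
#' their reference level).  A block whose design is singular (e.g. a
#' constant covariate) yields the error condition in place of a fit and the
#' scan continues.
#'
#' @param endpoints endpoint table; rows beyond 183 days are used.
#' @param terms blocks to scan (default: the published covariate list).
#' @param criterion \code{"REML"} or \code{"ML"}.
#' @return named list of \code{cd4_model_fit} objects (or error conditions).
#' @export
univariate_scan <- function(endpoints, terms = DEFAULT_CANDIDATES,
                            criterion = "REML") {
  if (!nrow(endpoints))
    stop("univariate_scan: empty endpoint table", call. = FALSE)
  fits <- lapply(terms, function(term) {
    tryCatch(fit_terms(endpoints, term, criterion),
             error = function(e) e)
  })
  names(fits) <- terms
  fits
}

#' Forward covariate selection at a fixed significance level
#'
#' Repeatedly adds the candidate block with the smallest Wald p-value
#' (joint chi-square for categorical blocks) while that p-value does not
#' exceed \code{alpha}.  After convergence each excluded candidate is refit
#' once added to the final model and its adjusted p-value reported without
#' retention.
#'
#' @param endpoints endpoint table; rows beyond 183 days are used.
#' @param candidates candidate blocks (default: published covariate list).
#' @param alpha retention level (default 0.20).
#' @param criterion \code{"REML"} or \code{"ML"}.
#' @return list with elements \code{fit} (final \code{cd4_model_fit}),
#'   \code{trace} (data.frame step/term/p_entry) and \code{dropped}
#'   (named vector of adjusted p-values of unretained candidates).
#' @export
forward_select <- function(endpoints, candidates = DEFAULT_CANDIDATES,
                           alpha = 0.20, criterion = "REML") {
  if (!length(candidates))
    stop("forward_select: no candidates", call. = FALSE)
  selected <- character(0)
  remaining <- candidates
  trace <- data.frame(step = integer(), term = character(),
                      p_entry = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (!length(remaining)) break
    ps <- vapply(remaining, function(term) {
      f <- tryCatch(fit_terms(endpoints, c(selected, term), criterion),
                    error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      block_wald_p(f, MODEL_BLOCKS[[term]])
    }, numeric(1))
    if (all(is.na(ps))) break
    best <- names(ps)[which.min(ps)]
    if (ps[best] > alpha) break
    step <- step + 1L
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    trace <- rbind(trace, data.frame(step = step, term = best,
                                     p_entry = unname(ps[best]),
                                     stringsAsFactors = FALSE))
  }
  if (!length(selected))
    stop("forward_select: no candidate met the entry level", call. = FALSE)
  canonical <- candidates[candidates %in% selected]
  final <- fit_terms(endpoints, canonical, criterion)
  dropped <- vapply(remaining, function(term) {
    f <- tryCatch(fit_terms(endpoints, c(canonical, term), criterion),
                  error = function(e) NULL)
    if (is.null(f)) NA_real_ else block_wald_p(f, MODEL_BLOCKS[[term]])
  }, numeric(1))
  list(fit = final, trace = trace, dropped = dropped,
       selected = canonical, alpha = alpha)
}

# Display order and labels of the published covariate table.
REPORT_ROWS <- list(
  list(block = "female", label = "Sex", ref = "Male", level = "Female",
       col = "female"),
  list(block = "age", label = "Current age", ref = NA,
       level = "per 10 years older", col = "age_decades"),
  list(block = "stage", label = "Disease stage", ref = "CDC Category A",
       level = "TB with or without other ADI", col = "stageTB_ADI"),
  list(block = "stage", label = "Disease stage", ref = NA,
       level = "Non-TB ADI(s)", col = "stageNONTB_ADI"),
  list(block = "haemoglobin", label = "Haemoglobin level", ref = NA,
       level = "per 1 g/dL higher", col = "haemoglobin"),
  list(block = "cd4", label = "Concurrent CD4 count", ref = NA,
       level = "per 100 cells/uL higher", col = "cd4_per100"),
  list(block = "vl", label = "Concurrent viral load", ref = NA,
       level = "per log10 copies/mL higher", col = "log10_vl"),
  list(block = "hepatitis", label = "Hepatitis B or C coinfection",
       ref = "No", level = "Yes", col = "hepatitis"),
  list(block = "period", label = "Time since cART initiation",
       ref = "> 6 to <= 12 months", level = "> 12 to <= 18 months",
       col = "periodP12_18"),
  list(block = "period", label = "Time since cART initiation", ref = NA,
       level = "> 18 to <= 24 months", col = "periodP18_24"),
  list(block = "period", label = "Time since cART initiation", ref = NA,
       level = "> 24 or more months", col = "periodP24PLUS"),
  list(block = "nnrti", label = "Initial cART containing NNRTI", ref = "No",
       level = "Yes", col = "nnrti"),
  list(block = "boosted_pi", label = "Initial cART containing boosted PI",
       ref = "No", level = "Yes", col = "boosted_pi"),
  list(block = "abacavir", label = "Initial cART containing abacavir",
       ref = "No", level = "Yes", col = "abacavir")
)

fmt_est_ci <- function(fit, col) {
  if (is.null(fit) || inherits(fit, "condition") ||
      !col %in% names(fit$coefficients)) return(c("", "", ""))
  est <- fit$coefficients[col]
  c(sprintf("%.1f", est),
    sprintf("(%.1f, %.1f)", fit$ci_low[col], fit$ci_high[col]),
    fmt_p(fit$wald_p[col]))
}

fmt_p <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "< 0.001" else sprintf("%.3f", p)
}

#' Coefficient report table
#'
#' Formats univariate and multivariate fits in the conventional layout:
#' rows in the standard covariate order, reference levels shown as 0.0,
#' estimates to 1 decimal place and p-values to 3.  A footnote records a
#' between-patient variance estimated at the zero boundary.
#'
#' @param univariate named list of fits from \code{\link{univariate_scan}}
#'   (may be empty).
#' @param final the final multivariate \code{cd4_model_fit} (or a published
#'   coefficient fixture).
#' @return data.frame of formatted strings, with a \code{footnotes}
#'   attribute; the constant row is included when available.
#' @export
report_table <- function(univariate = list(), final = NULL) {
  header <- c("covariate", "level", "uni_est", "uni_ci", "uni_p",
              "multi_est", "multi_ci", "multi_p")
  if (!length(univariate) && is.null(final)) {
    out <- as.data.frame(matrix(character(0), ncol = length(header),
                                dimnames = list(NULL, header)),
                         stringsAsFactors = FALSE)
    attr(out, "footnotes") <- character(0)
    return(out)
  }
  rows <- list()
  for (spec_row in REPORT_ROWS) {
    uni <- univariate[[spec_row$block]]
    if (!is.na(spec_row$ref))
      rows[[length(rows) + 1L]] <- c(spec_row$label, paste0(spec_row$ref, "*"),
                                     "0.0", "", "", "0.0", "", "")
    rows[[length(rows) + 1L]] <- c(spec_row$label, spec_row$level,
                                   fmt_est_ci(uni, spec_row$col),
                                   fmt_est_ci(final, spec_row$col))
  }
  if (!is.null(final) && "(Intercept)" %in% names(final$coefficients))
    rows[[length(rows) + 1L]] <- c("Constant", "",
                                   "", "", "",
                                   fmt_est_ci(final, "(Intercept)"))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("covariate", "level", "uni_est", "uni_ci", "uni_p",
                  "multi_est", "multi_ci", "multi_p")
  notes <- character(0)
  if (!is.null(final) && "sigma_b2_boundary_zero" %in% final$flags)
    notes <- c(notes,
               "Between-patient variance estimated at the zero boundary.")
  attr(out, "footnotes") <- notes
  out
}
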