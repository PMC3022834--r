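# Independent dense-matrix (RE)ML oracle for the random-intercept model.
#
# Works from the full n x n marginal covariance V = I + lambda Z Z' using
# solve()/determinant() directly, and locates lambda by zooming grid search
# over log(lambda) plus an explicit lambda = 0 evaluation.  Shares no code
# with the package implementation (which profiles a sufficient-statistics
# criterion), so agreement is a genuine cross-check.

oracle_criterion <- function(lambda, y, X, g, criterion) {
  n <- length(y)
  p <- ncol(X)
  Z <- 1 * outer(as.character(g), levels(g), `==`)
  V <- diag(n) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Vi %*% r)
  ldV <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  crit <- if (criterion == "REML") {
    ldX <- as.numeric(determinant(XtVX, logarithm = TRUE)$modulus)
    (n - p) * log(rss / (n - p)) + ldV + ldX
  } else {
    n * log(rss / n) + ldV
  }
  list(crit = crit, beta = drop(beta), rss = rss,
       cov_unit = solve(XtVX))
}

oracle_fit <- function(y, X, g, criterion = "REML") {
  X <- as.matrix(X)
  g <- factor(g)
  lo <- -16; hi <- 16; step <- 0.4
  best <- NA_real_
  for (pass in 1:6) {
    grid <- seq(lo, hi, by = step)
    crits <- vapply(grid, function(ll)
      oracle_criterion(exp(ll), y, X, g, criterion)$crit, numeric(1))
    best <- grid[which.min(crits)]
    lo <- best - step; hi <- best + step; step <- step / 20
  }
  at_best <- oracle_criterion(exp(best), y, X, g, criterion)
  at_zero <- oracle_criterion(0, y, X, g, criterion)
  if (at_zero$crit <= at_best$crit) {
    lambda <- 0; at <- at_zero
  } else {
    lambda <- exp(best); at <- at_best
  }
  df <- if (criterion == "REML") length(y) - ncol(X) else length(y)
  sigma_e2 <- at$rss / df
  list(lambda = lambda, beta = at$beta, sigma_e2 = sigma_e2,
       sigma_b2 = lambda * sigma_e2, crit = at$crit,
       se = sqrt(diag(at$cov_unit) * sigma_e2))
}
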