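# shared fixtures and independent oracles

# a six-marker-complete reference panel (canonical units)
reference_panel <- function(...) {
  panel <- tibble::tibble(mcv = 90, wbc = 5.8, albumin = 45,
                          creatinine = 80, glucose = 5.5, chron_age = 50)
  overrides <- list(...)
  for (nm in names(overrides)) panel[[nm]] <- overrides[[nm]]
  panel
}

# residuals by explicit normal equations: independent of the qr path used
# in the package
oracle_residualize <- function(y, covariates = NULL) {
  x <- cbind(1, covariates)
  beta <- solve(t(x) %*% x, t(x) %*% y)
  as.numeric(y - x %*% beta)
}

# partial correlation by the two-step normal-equations construction plus
# the t formula
oracle_partial_corr <- function(x, y, covariates = NULL) {
  rx <- oracle_residualize(x, covariates)
  ry <- oracle_residualize(y, covariates)
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  n <- length(x)
  k <- if (is.null(covariates)) 0 else ncol(covariates)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), df))
}

# exhaustive best-subset oracle: enumerate every candidate subset with lm()
oracle_best_subset <- function(data, outcome, candidates, forced = character()) {
  n <- nrow(data)
  best <- NULL
  best_aic <- Inf
  for (mask in 0:(2^length(candidates) - 1)) {
    sel <- candidates[bitwAnd(mask, bitwShiftL(1, seq_along(candidates) - 1)) > 0]
    rhs <- c("1", forced, sel)
    fit <- lm(stats::reformulate(rhs, response = outcome), data = data)
    rss <- sum(stats::residuals(fit)^2)
    k <- length(forced) + length(sel)
    aic <- n * log(rss / n) + 2 * (k + 2) + n * (log(2 * pi) + 1)
    if (aic < best_aic - 1e-9 ||
        (abs(aic - best_aic) <= 1e-9 && length(sel) < length(best))) {
      best_aic <- aic
      best <- sel
    }
  }
  list(selected = sort(best), aic = best_aic)
}

# small random regression instance with correlated predictors
random_instance <- function(n, p, seed) {
  set.seed(seed)
  z <- matrix(rnorm(n * p), n, p)
  x <- z + 0.5 * rnorm(n)  # shared component induces correlation
  colnames(x) <- sprintf("v%02d", seq_len(p))
  active <- sample(p, sample(0:min(3, p), 1))
  beta <- numeric(p)
  beta[active] <- runif(length(active), 0.2, 0.8)
  d <- tibble::as_tibble(as.data.frame(x))
  d$f1 <- rnorm(n)
  d$y <- x %*% beta + 0.7 * d$f1 + rnorm(n)
  d$y <- as.numeric(d$y)
  d
}
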