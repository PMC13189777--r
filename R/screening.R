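# least-squares machinery shared by the screen: QR of [1 | covariates]
covariate_qr <- function(covariates, n) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    x <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(intercept)"))
  } else {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("covariate", seq_len(ncol(covariates)))
    }
    if (nrow(covariates) != n) stop_domain("covariates and values differ in length")
    x <- cbind("(intercept)" = 1, covariates)
  }
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    offending <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop_singular(offending[1])
  }
  qx
}

#' Residualize a vector on a covariate set
#'
#' Least-squares residuals of `values` regressed on an intercept plus the
#' covariate columns; with no covariates this is mean-centering. The
#' residuals are orthogonal to the intercept and to every covariate column.
#'
#' @param values numeric vector.
#' @param covariates numeric matrix or data frame (may be `NULL` / empty).
#' @return numeric vector of residuals, same length as `values`.
#' @examples
#' residualize(c(1, 2, 4), NULL)  # mean-centering
#' @export
residualize <- function(values, covariates = NULL) {
  values <- as.numeric(values)
  qr.resid(covariate_qr(covariates, length(values)), values)
}

#' Partial Pearson correlation with Fisher-z confidence interval
#'
#' Correlates the residuals of `x` and `y` after each is regressed on an
#' intercept plus the shared covariates. The two-sided p-value uses
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees of
#' freedom (`k` = number of covariate columns); the confidence interval is
#' the Fisher-z interval with standard error `1 / sqrt(n - 3 - k)`,
#' back-transformed, using the normal critical value.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates numeric matrix / data frame of adjusting covariates,
#'   or `NULL` for a plain Pearson correlation.
#' @param conf_level confidence level for the Fisher-z interval.
#' @param factor_name optional label stored in the result.
#' @return one-row tibble: `factor_name`, `r`, `ci_low`, `ci_high`, `p`,
#'   `n`, `k`.
#' @examples
#' set.seed(1)
#' z <- rnorm(50); x <- z + rnorm(50); y <- z + rnorm(50)
#' partial_correlation(x, y, cbind(z = z))
#' @export
partial_correlation <- function(x, y, covariates = NULL, conf_level = 0.95,
                                factor_name = NA_character_) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop_domain("x and y differ in length")
  k <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (n <= k + 3) stop_domain("need n > k + 3 observations")
  qx <- covariate_qr(covariates, n)
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  # relative tolerance: a vector lying in the covariate span leaves only
  # floating-point dust in its residuals
  if (sd(rx) <= 1e-10 * max(1, sd(x)) || sd(ry) <= 1e-10 * max(1, sd(y))) {
    abort("degenerate input: zero residual variance",
          class = "phenodelta_degenerate_error")
  }
  r <- cor(rx, ry)
  r <- min(1, max(-1, r))
  df <- n - 2 - k
  if (abs(r) < 1) {
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tval), df)
  } else {
    p <- 0
  }
  zcrit <- qnorm(1 - (1 - conf_level) / 2)
  if (abs(r) < 1) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3 - k)
    ci <- tanh(z + c(-1, 1) * zcrit * se)
  } else {
    ci <- c(r, r)
  }
  tibble(factor_name = factor_name, r = r,
         ci_low = ci[1], ci_high = ci[2], p = p,
         n = as.integer(n), k = as.integer(k))
}

#' Screen lifestyle factors against an outcome by partial correlation
#'
#' Stage-1 exploratory screen: for each factor column, the partial Pearson
#' correlation with the outcome adjusting for the covariate set, with
#' Fisher-z confidence intervals and two-sided p-values. Rows with a
#' missing value in the outcome, any covariate, or any factor are dropped
#' once, globally (complete-case). Constant factor columns are excluded
#' with a warning. Results are sorted by the correlation coefficient;
#' factors with (optionally adjusted) `p < alpha` are flagged selected.
#'
#' @param data cohort data frame.
#' @param outcome name of the outcome column (e.g. `"delta_phenoage"`).
#' @param factors character vector of factor column names to screen.
#' @param covariates character vector of adjusting covariate columns
#'   (character/factor columns are expanded to 0/1 indicators). The
#'   pooled-analysis default is sex and the follow-up gap.
#' @param alpha selection threshold on the (adjusted) p-value.
#' @param conf_level confidence level for the intervals.
#' @param p_adjust multiplicity correction passed to [stats::p.adjust()];
#'   the default `"none"` matches an exploratory raw-p screen.
#' @return a `pheno_screen` tibble (one row per screened factor, sorted by
#'   `r`) with columns `factor_name`, `r`, `ci_low`, `ci_high`, `p`, `n`,
#'   `k`, `selected`; attributes record `alpha`, dropped-row count and
#'   excluded constant factors.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 500, seed = 1))
#' screen_factors(cohort, "delta_phenoage", c("delta_bmi", "incense"),
#'                covariates = c("sex", "delta_age"))
#' @export
screen_factors <- function(data, outcome, factors,
                           covariates = c("sex", "delta_age"),
                           alpha = 0.05, conf_level = 0.95,
                           p_adjust = "none") {
  if (alpha <= 0 || alpha > 1) stop_domain("alpha must lie in (0, 1]")
  missing_cols <- setdiff(c(outcome, factors, covariates), names(data))
  if (length(missing_cols) > 0) {
    stop_domain(paste0("column(s) not found: ",
                       paste(missing_cols, collapse = ", ")))
  }
  used <- data[c(outcome, covariates, factors)]
  keep <- complete.cases(used)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(paste0("screen_factors: dropped ", n_dropped,
                  " incomplete row(s); ", sum(keep), " retained"))
  }
  used <- used[keep, , drop = FALSE]

  cov_mat <- NULL
  if (length(covariates) > 0) {
    cov_mat <- do.call(cbind, lapply(covariates, function(nm) {
      col <- used[[nm]]
      if (is.character(col) || is.factor(col)) {
        col <- as.integer(factor(col)) - 1L  # 0/1 (or 0..L-1) indicator
      }
      matrix(as.numeric(col), ncol = 1, dimnames = list(NULL, nm))
    }))
  }

  constant <- vapply(factors, function(nm) {
    v <- used[[nm]]
    length(unique(v)) < 2
  }, logical(1))
  if (any(constant)) {
    warn(paste0("excluding constant factor column(s): ",
                paste(factors[constant], collapse = ", ")))
  }
  screened <- factors[!constant]

  results <- map(screened, function(nm) {
    partial_correlation(used[[nm]], used[[outcome]], cov_mat,
                        conf_level = conf_level, factor_name = nm)
  })
  out <- if (length(results) > 0) bind_rows(results) else {
    tibble(factor_name = character(), r = numeric(), ci_low = numeric(),
           ci_high = numeric(), p = numeric(), n = integer(), k = integer())
  }
  out$p_adjusted <- stats::p.adjust(out$p, method = p_adjust)
  out$selected <- out$p_adjusted < alpha
  out <- arrange(out, .data$r)
  structure(out,
            class = c("pheno_screen", class(out)),
            alpha = alpha, p_adjust = p_adjust,
            n_dropped = n_dropped,
            excluded_constant = factors[constant],
            covariates = covariates, outcome = outcome)
}

#' Factors selected by a screen, split by correlation sign
#'
#' @param screen a [screen_factors()] result.
#' @return list with elements `positive` and `negative`, each a character
#'   vector of selected factor names ordered by `r`.
#' @export
selected_factors <- function(screen) {
  stopifnot(inherits(screen, "pheno_screen"))
  sel <- screen[screen$selected, ]
  list(positive = sel$factor_name[sel$r > 0],
       negative = sel$factor_name[sel$r < 0])
}
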