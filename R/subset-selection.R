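#' Ordinary least squares fit with AIC and adjusted R-squared
#'
#' @param design numeric matrix or data frame of predictors (no intercept
#'   column; one is prepended).
#' @param outcome numeric vector.
#' @return an `ols_fit` object: list with `coefficients` (tibble: `term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`), `rss`, `n`, `k`
#'   (non-intercept predictors), `r2_adj`, `sigma2`, `aic`.
#' @examples
#' ols_fit(cbind(x = 1:6), c(1.1, 1.9, 3.2, 3.8, 5.1, 5.9))
#' @export
ols_fit <- function(design, outcome) {
  design <- as.matrix(design)
  if (is.null(colnames(design)) && ncol(design) > 0) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  y <- as.numeric(outcome)
  n <- length(y)
  if (nrow(design) != n) stop_domain("design and outcome differ in length")
  k <- ncol(design)
  if (n <= k + 1) stop_domain("need n > k + 1 observations")
  x <- cbind("(intercept)" = 1, design)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    stop_singular(colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]][1])
  }
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - k - 1)
  xtx_inv <- solve(crossprod(x))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  stat <- beta / se
  p <- 2 * pt(-abs(stat), n - k - 1)
  structure(
    list(
      coefficients = tibble(term = colnames(x), estimate = unname(beta),
                            std_error = unname(se), statistic = unname(stat),
                            p_value = unname(p)),
      rss = rss, tss = tss, n = n, k = k,
      r2_adj = 1 - (rss / (n - k - 1)) / (tss / (n - 1)),
      sigma2 = sigma2,
      aic = aic_gaussian(rss, n, k)
    ),
    class = "ols_fit"
  )
}

#' Gaussian AIC from a residual sum of squares
#'
#' `n * log(rss / n) + 2 * (k + 2) + n * (log(2 * pi) + 1)`: the maximized
#' Gaussian log-likelihood form with `k + 2` estimated parameters
#' (intercept, `k` slopes, error variance), including the full constant so
#' values match standard statistical software. A perfect fit (`rss = 0`)
#' returns `-Inf` with a warning, so it dominates any selection.
#'
#' @param rss residual sum of squares (>= 0).
#' @param n number of observations.
#' @param k number of non-intercept predictors.
#' @return AIC value (dimensionless).
#' @examples
#' aic_gaussian(10, 100, 3)
#' @export
aic_gaussian <- function(rss, n, k) {
  if (n <= 0) stop_domain("n must be positive")
  if (rss < 0) stop_domain("rss must be non-negative")
  if (rss == 0) {
    warn("rss = 0: returning -Inf (perfect fit dominates selection)")
    return(-Inf)
  }
  n * log(rss / n) + 2 * (k + 2) + n * (log(2 * pi) + 1)
}

# RSS of the model spanned by Gram-submatrix columns idx (always includes
# the intercept column 1). Returns NA if the submatrix is singular.
rss_from_gram <- function(gram, gy, yy, idx) {
  ch <- tryCatch(chol(gram[idx, idx, drop = FALSE]), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  b <- backsolve(ch, forwardsolve(t(ch), gy[idx]))
  max(0, yy - sum(b * gy[idx]))
}

#' Exact best-subset selection minimizing Gaussian AIC
#'
#' Searches over all `2^m` subsets of the candidate predictors (always
#' keeping the forced-in predictors and the intercept) for the ordinary
#' least squares model with the smallest [aic_gaussian()]. The default
#' branch-and-bound search prunes a branch only when no completion of it
#' can beat the incumbent (the RSS of a model never increases when
#' predictors are added, giving a valid lower bound on any completion's
#' AIC), so it provably returns the global minimum; `method = "exhaustive"`
#' enumerates every subset. Ties are broken toward fewer predictors, then
#' lexicographic label order.
#'
#' @param data data frame holding outcome and predictor columns (numeric).
#' @param outcome name of the outcome column.
#' @param candidates character vector of candidate predictor columns
#'   (at most 30; disjoint from `forced`).
#' @param forced character vector of predictor columns kept in every model
#'   (e.g. the follow-up gap in a longitudinal change model).
#' @param method `"branch_bound"` (default) or `"exhaustive"`.
#' @return a `pheno_subset` object: list with `selected` (candidate labels
#'   chosen), `forced`, `fit` (an [ols_fit()] on forced + selected), `vif`
#'   (tibble, `NULL` when the final model has fewer than two predictors),
#'   `aic`, and `search_stats` (subsets evaluated / branches pruned).
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(x1 = rnorm(100), x2 = rnorm(100), z = rnorm(100))
#' d$y <- 0.8 * d$x1 + 0.5 * d$z + rnorm(100)
#' best_subset(d, "y", candidates = c("x1", "x2"), forced = "z")
#' @export
best_subset <- function(data, outcome, candidates, forced = character(),
                        method = c("branch_bound", "exhaustive")) {
  method <- match.arg(method)
  m <- length(candidates)
  if (m > 30) {
    stop_domain(paste0(
      m, " candidate predictors exceed the exact-search limit of 30; ",
      "tighten the screening threshold or pre-filter the candidate list"))
  }
  if (length(intersect(forced, candidates)) > 0) {
    stop_domain("forced and candidate predictor sets must be disjoint")
  }
  cols <- c(outcome, forced, candidates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop_domain(paste0("column(s) not found: ",
                       paste(missing_cols, collapse = ", ")))
  }
  used <- data[cols]
  keep <- complete.cases(used)
  used <- used[keep, , drop = FALSE]
  y <- as.numeric(used[[outcome]])
  n <- length(y)
  x_all <- cbind("(intercept)" = 1,
                 as.matrix(used[c(forced, candidates)]))
  qx <- qr(x_all)
  if (qx$rank < ncol(x_all)) {
    stop_singular(colnames(x_all)[qx$pivot[(qx$rank + 1):ncol(x_all)]][1])
  }

  gram <- crossprod(x_all)
  gy <- crossprod(x_all, y)[, 1]
  yy <- sum(y^2)
  base_idx <- seq_len(1 + length(forced))          # intercept + forced
  cand_idx <- 1 + length(forced) + seq_len(m)      # columns of candidates
  k_base <- length(forced)
  tol <- 1e-9

  aic_of <- function(sel) {
    rss <- rss_from_gram(gram, gy, yy, c(base_idx, cand_idx[sel]))
    k <- k_base + length(sel)
    if (is.na(rss)) return(Inf)
    if (rss <= 0) return(-Inf)
    n * log(rss / n) + 2 * (k + 2) + n * (log(2 * pi) + 1)
  }

  # lexicographic comparison of sorted label sets
  labels_before <- function(a, b) {
    la <- sort(candidates[a]); lb <- sort(candidates[b])
    len <- min(length(la), length(lb))
    for (i in seq_len(len)) {
      if (la[i] != lb[i]) return(la[i] < lb[i])
    }
    length(la) < length(lb)
  }

  state <- new.env(parent = emptyenv())
  state$best_aic <- Inf
  state$best_sel <- integer()
  state$evaluated <- 0L
  state$pruned <- 0L

  consider <- function(sel) {
    state$evaluated <- state$evaluated + 1L
    a <- aic_of(sel)
    better <- a < state$best_aic - tol ||
      (abs(a - state$best_aic) <= tol &&
         (length(sel) < length(state$best_sel) ||
            (length(sel) == length(state$best_sel) &&
               labels_before(sel, state$best_sel))))
    if (better) {
      state$best_aic <- a
      state$best_sel <- sel
    }
  }

  if (method == "exhaustive" || m == 0) {
    if (m == 0) {
      consider(integer())
    } else {
      for (mask in 0:(2^m - 1)) {
        consider(which(bitwAnd(mask, bitwShiftL(1, seq_len(m) - 1)) > 0))
      }
    }
  } else {
    # order candidates by full-model explanatory weight for tighter pruning
    full_rss <- rss_from_gram(gram, gy, yy, c(base_idx, cand_idx))
    drop_cost <- vapply(seq_len(m), function(j) {
      rss_from_gram(gram, gy, yy, c(base_idx, cand_idx[-j])) - full_rss
    }, numeric(1))
    ord <- order(drop_cost, decreasing = TRUE)

    recurse <- function(sel, depth) {
      if (depth > m) {
        consider(sel)
        return(invisible(NULL))
      }
      remaining <- ord[depth:m]
      rss_lb <- rss_from_gram(gram, gy, yy,
                              c(base_idx, cand_idx[c(sel, remaining)]))
      k_lb <- k_base + length(sel)
      aic_lb <- if (is.na(rss_lb) || rss_lb <= 0) -Inf else
        n * log(rss_lb / n) + 2 * (k_lb + 2) + n * (log(2 * pi) + 1)
      if (aic_lb > state$best_aic + tol) {
        state$pruned <- state$pruned + 1L
        return(invisible(NULL))
      }
      recurse(c(sel, ord[depth]), depth + 1)  # include branch first
      recurse(sel, depth + 1)
    }
    recurse(integer(), 1)
  }

  selected <- sort(candidates[sort(state$best_sel)])
  final_cols <- c(forced, selected)
  fit <- ols_fit(as.matrix(used[final_cols]), y)
  vif_tbl <- if (length(final_cols) >= 2) vif(as.matrix(used[final_cols])) else NULL
  structure(
    list(selected = selected, forced = forced, candidates = candidates,
         fit = fit, vif = vif_tbl, aic = state$best_aic, n = n,
         search_stats = list(method = method,
                             subsets_evaluated = state$evaluated,
                             branches_pruned = state$pruned,
                             subsets_total = 2^m)),
    class = "pheno_subset"
  )
}

#' @export
print.pheno_subset <- function(x, ...) {
  cat("<pheno_subset> AIC-best model over ", length(x$candidates),
      " candidates (", x$search_stats$method, ")\n", sep = "")
  cat("  forced:   ", paste(x$forced, collapse = ", "), "\n", sep = "")
  cat("  selected: ", paste(x$selected, collapse = ", "), "\n", sep = "")
  cat("  AIC ", format(x$aic), "; adjusted R^2 ",
      format(round(100 * x$fit$r2_adj, 2)), "%; n ", x$n, "\n", sep = "")
  invisible(x)
}

#' Variance inflation factors
#'
#' For each predictor column, `1 / (1 - R^2)` from regressing that column
#' on the remaining predictors plus an intercept. Perfectly collinear
#' predictors are flagged with an infinite VIF rather than an error.
#'
#' @param design numeric matrix or data frame with at least two predictor
#'   columns (no intercept column).
#' @return tibble with columns `term` and `vif` (each `>= 1`).
#' @examples
#' set.seed(1)
#' vif(cbind(a = rnorm(50), b = rnorm(50)))
#' @export
vif <- function(design) {
  design <- as.matrix(design)
  if (ncol(design) < 2) stop_domain("vif needs at least two predictors")
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  out <- vapply(seq_len(ncol(design)), function(j) {
    yj <- design[, j]
    # project on the span of the others; a rank-deficient co-predictor set
    # is fine here (perfect collinearity maps to an infinite VIF below)
    res <- qr.resid(qr(cbind(1, design[, -j, drop = FALSE])), yj)
    tssj <- sum((yj - mean(yj))^2)
    if (tssj == 0) return(Inf)
    r2 <- 1 - sum(res^2) / tssj
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(term = colnames(design), vif = pmax(out, 1))
}

#' Interpret a regression coefficient over a stated contrast
#'
#' Multiplies a fitted coefficient by a number of predictor units, e.g. the
#' 4-point span of a 1-5 diet item, giving the associated difference in
#' outcome units.
#'
#' @param fit a [best_subset()] result, an [ols_fit()], or a data frame
#'   with `term` and `estimate` columns.
#' @param predictor coefficient label.
#' @param delta_units contrast width in predictor units.
#' @return numeric: `estimate[predictor] * delta_units`, in outcome units.
#' @examples
#' effect_contrast(tibble::tibble(term = "diet5", estimate = -0.0921),
#'                 "diet5", 4)
#' @export
effect_contrast <- function(fit, predictor, delta_units) {
  coefs <- if (inherits(fit, "pheno_subset")) fit$fit$coefficients
  else if (inherits(fit, "ols_fit")) fit$coefficients
  else as_tibble(fit)
  row <- match(predictor, coefs$term)
  if (is.na(row)) {
    stop_domain(paste0("predictor '", predictor, "' not in the fitted model"))
  }
  coefs$estimate[row] * delta_units
}
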