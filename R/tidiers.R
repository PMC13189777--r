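#' Tidy a factor screen
#'
#' @param x a [screen_factors()] result.
#' @param ... unused.
#' @return tibble, one row per screened factor sorted by `r`.
#' @method tidy pheno_screen
#' @export
tidy.pheno_screen <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "pheno_screen")
  out
}

#' Tidy a best-subset model
#'
#' @param x a [best_subset()] result.
#' @param ... unused.
#' @return coefficient tibble (`term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`) with per-predictor `vif` joined on.
#' @method tidy pheno_subset
#' @export
tidy.pheno_subset <- function(x, ...) {
  out <- x$fit$coefficients
  if (!is.null(x$vif)) out <- left_join(out, x$vif, by = "term")
  out
}

#' One-row summary of a best-subset model
#'
#' @param x a [best_subset()] result.
#' @param ... unused.
#' @return tibble: `aic`, `r2_adj`, `n`, `k`, `max_vif`,
#'   `subsets_evaluated`, `branches_pruned`.
#' @method glance pheno_subset
#' @export
glance.pheno_subset <- function(x, ...) {
  tibble(aic = x$aic, r2_adj = x$fit$r2_adj, n = x$fit$n, k = x$fit$k,
         max_vif = if (is.null(x$vif)) NA_real_ else max(x$vif$vif),
         subsets_evaluated = x$search_stats$subsets_evaluated,
         branches_pruned = x$search_stats$branches_pruned)
}

#' Tidy an OLS fit
#'
#' @param x an [ols_fit()] result.
#' @param ... unused.
#' @return the coefficient tibble.
#' @method tidy ols_fit
#' @export
tidy.ols_fit <- function(x, ...) x$coefficients

#' One-row summary of an OLS fit
#'
#' @param x an [ols_fit()] result.
#' @param ... unused.
#' @return tibble: `rss`, `r2_adj`, `aic`, `n`, `k`.
#' @method glance ols_fit
#' @export
glance.ols_fit <- function(x, ...) {
  tibble(rss = x$rss, r2_adj = x$r2_adj, aic = x$aic, n = x$n, k = x$k)
}

#' Forest plot of a factor screen
#'
#' Partial correlation coefficients with their confidence intervals,
#' factors sorted by the coefficient, selected factors starred.
#'
#' @param object a [screen_factors()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pheno_screen
#' @export
autoplot.pheno_screen <- function(object, ...) {
  d <- tidy(object)
  d$factor_name <- factor(d$factor_name, levels = d$factor_name)
  d$label <- ifelse(d$selected, paste0(d$factor_name, " *"),
                    as.character(d$factor_name))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$factor_name)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.25, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 1.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey55"),
                                 name = paste0("p < ",
                                               attr(object, "alpha"))) +
    ggplot2::labs(x = "partial correlation with ΔPhenoAge (95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a best-subset model
#'
#' @param object a [best_subset()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pheno_subset
#' @export
autoplot.pheno_subset <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$term != "(intercept)", ]
  d <- d[order(d$estimate), ]
  d$term <- factor(d$term, levels = d$term)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std_error,
                                         xmax = .data$estimate + 1.96 * .data$std_error),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(size = 1.8, colour = "#2166ac") +
    ggplot2::labs(x = "coefficient (years per predictor unit, 95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
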