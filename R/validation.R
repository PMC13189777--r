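#' Type-I error of the partial-correlation screen under the null
#'
#' Monte-Carlo calibration check: in each replicate a pure-noise factor is
#' screened against a pure-noise outcome, adjusting for a binary sex
#' indicator and a follow-up-gap covariate, and the rejection at
#' `p < alpha` is recorded. Under the null the rejection rate should match
#' `alpha` up to binomial error.
#'
#' @param reps number of null replicates.
#' @param n observations per replicate.
#' @param alpha nominal level of the screen.
#' @param seed RNG seed.
#' @return list: `rate` (observed rejection rate), `reps`, `n`,
#'   `band` (the binomial 95% band around `alpha`).
#' @examples
#' type1_error_study(reps = 200, n = 200, seed = 1)$rate
#' @export
type1_error_study <- function(reps = 2000, n = 1000, alpha = 0.05, seed = 1) {
  set.seed(seed)
  rejected <- vapply(seq_len(reps), function(i) {
    covs <- cbind(sex = rbinom(n, 1, 0.365),
                  delta_age = rnorm(n, 4.9, 1.5))
    res <- partial_correlation(rnorm(n), rnorm(n), covs)
    res$p < alpha
  }, logical(1))
  half <- 1.96 * sqrt(alpha * (1 - alpha) / reps)
  list(rate = mean(rejected), reps = reps, n = n,
       band = c(alpha - half, alpha + half))
}

#' Two-stage pipeline recovery study on synthetic cohorts
#'
#' Repeatedly generates an all-male cohort with the published male
#' coefficient pattern planted on the outcome, scores the biomarker panels,
#' runs the stage-1 partial-correlation screen (adjusting for the
#' follow-up gap) and the stage-2 AIC best-subset selection (follow-up gap
#' forced in), and evaluates: (a) whether every detectable planted factor
#' — implied partial correlation magnitude at least `detect_rho` — was
#' selected, and (b) whether refitting the full planted predictor set
#' recovers each planted coefficient within three estimated standard
#' errors.
#'
#' @param reps number of replicate cohorts.
#' @param n participants per cohort.
#' @param seed RNG seed (per-replicate seeds are derived from it).
#' @param detect_rho detectability bound on the implied partial correlation
#'   `|beta| * sd(factor) / noise_sd` below which a planted factor is not
#'   required to be recovered.
#' @param alpha stage-1 screening threshold.
#' @return list: `support_recovery_rate`, `beta_coverage_rate`, `reps`,
#'   `n`, `detectable` (factor names required to be recovered in the last
#'   replicate), and `per_rep` (tibble with one row per replicate).
#' @export
recovery_study <- function(reps = 100, n = 25000, seed = 1,
                           detect_rho = 0.02, alpha = 0.05) {
  betas <- planted_beta_defaults()$male
  planted <- setdiff(names(betas), "delta_age")
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, reps)
  per_rep <- map(seq_len(reps), function(i) {
    cfg <- generator_config(
      n = n, sex_fraction_male = 1,
      planted_betas = list(male = betas, female = planted_beta_defaults()$female))
    cohort <- generate_cohort(cfg, seed = seeds[i])
    cohort <- score_cohort(cohort)
    screen <- screen_factors(cohort, "delta_phenoage", factor_roster(),
                             covariates = "delta_age", alpha = alpha)
    candidates <- screen$factor_name[screen$selected]
    if (length(candidates) > 30) {
      candidates <- screen$factor_name[order(screen$p)][1:30]
    }
    model <- best_subset(cohort, "delta_phenoage", candidates,
                         forced = "delta_age")
    sds <- vapply(planted, function(f) sd(cohort[[f]]), numeric(1))
    detectable <- planted[abs(betas[planted]) * sds / cfg$noise_sd >= detect_rho]
    support_ok <- all(detectable %in% model$selected)
    refit <- ols_fit(as.matrix(cohort[c("delta_age", planted)]),
                     cohort$delta_phenoage)
    cf <- refit$coefficients
    terms <- c("delta_age", planted)
    idx <- match(terms, cf$term)
    within3 <- abs(cf$estimate[idx] - betas[terms]) <= 3 * cf$std_error[idx]
    tibble(rep = i, support_recovered = support_ok,
           betas_covered = all(within3),
           n_candidates = length(candidates),
           n_selected = length(model$selected),
           n_detectable = length(detectable),
           detectable = list(detectable),
           within3 = list(setNames(within3, terms)))
  }) |> bind_rows()
  coverage <- colMeans(do.call(rbind, per_rep$within3))
  list(support_recovery_rate = mean(per_rep$support_recovered),
       beta_coverage = coverage,
       beta_coverage_rate = min(coverage),
       all_beta_coverage_rate = mean(per_rep$betas_covered),
       reps = reps, n = n,
       detectable = per_rep$detectable[[reps]],
       per_rep = per_rep[setdiff(names(per_rep), c("detectable", "within3"))])
}
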