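#' Published descriptive counts for the ordinal and binary lifestyle factors
#'
#' The printed per-sex counts and percentages for the ordinal (cooking,
#' betel nut, supplement use) and dichotomous lifestyle factors of the
#' Taiwan Biobank follow-up cohort, shipped as a plain-text table. These
#' are the calibration targets of the synthetic cohort generator.
#'
#' @return tibble with columns `factor`, `level`, `men_count`, `men_pct`,
#'   `women_count`, `women_pct` (first row holds the per-sex sample sizes).
#' @export
twb_reference_counts <- function() {
  path <- system.file("extdata", "twb-descriptives-categorical.csv",
                      package = "phenodelta", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Published per-sex means and SDs for the ordinal diet / education items
#'
#' @return tibble with columns `factor`, `men_mean`, `men_sd`,
#'   `women_mean`, `women_sd`.
#' @export
twb_reference_continuous <- function() {
  path <- system.file("extdata", "twb-descriptives-likert.csv",
                      package = "phenodelta", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' The 43 lifestyle factors screened against the change in PhenoAge
#'
#' Five obesity-index changes, seventeen 1-5 diet items, education (1-7),
#' three 3-level ordinal items, twelve binary indicators, four exercise
#' transition indicators, and chronological age at follow-up.
#'
#' @return character vector of 43 canonical column names.
#' @export
factor_roster <- function() {
  c("delta_bmi", "delta_bfp", "delta_wc", "delta_hc", "delta_whr",
    paste0("diet", 1:17), "education",
    "cooking", "nut", "supplement",
    "alone", "job", "jobsame", "medication", "coffee", "tea",
    "drinking", "smoking", "smk2nd", "incense", "vege", "supper",
    "spo_yesyes", "spo_yesno", "spo_noyes", "spo_nono",
    "chron_age_fu")
}

# published per-sex regression patterns planted on the outcome (years per
# predictor unit), per sex
planted_beta_defaults <- function() {
  list(
    male = c(delta_age = 1.2535, chron_age_fu = 0.0155,
             delta_bfp = 0.0379, delta_wc = 0.0174, alone = 0.4032,
             diet2 = -0.0672, diet5 = -0.0921, diet16 = 0.0941,
             diet17 = 0.0321, cooking = 0.0576, incense = 0.2747,
             job = -0.1185, jobsame = -0.3710, tea = -0.1053),
    female = c(delta_age = 1.1960, chron_age_fu = 0.0236,
               delta_bmi = 0.1478, diet2 = -0.0683, diet5 = -0.0502,
               diet16 = 0.0664, diet17 = 0.0220, cooking = -0.0566,
               incense = 0.1633, jobsame = -0.0981, supper = 0.0700,
               supplement = 0.0462)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the published study conditions: the sex mix, the
#' truncated-normal follow-up gap, per-sex baseline age distributions,
#' published prevalences and ordinal-item distributions for all 43
#' lifestyle factors, the published per-sex regression patterns planted on
#' the outcome, residual noise of 3.3 years, and mean outcome calibrated to
#' the published per-sex mean change in PhenoAge. SDs for the obesity-index
#' changes are not published and use realistic defaults.
#'
#' @param n number of participants.
#' @param sex_fraction_male probability a participant is male.
#' @param planted_betas list with `male` / `female` named numeric vectors
#'   (outcome years per predictor unit); names must be factor columns or
#'   `delta_age`.
#' @param noise_sd residual SD of the outcome, years (> 0).
#' @param target_mean_delta named vector, per-sex target mean of the
#'   outcome in years (the per-sex intercept is calibrated to it).
#' @param seed default RNG seed used by [generate_cohort()].
#' @param ... overrides for the remaining defaults (see the returned list).
#' @return a `generator_config` list.
#' @examples
#' cfg <- generator_config(n = 1000, seed = 42)
#' names(cfg)
#' @export
generator_config <- function(n = 50000, sex_fraction_male = 0.365,
                             planted_betas = planted_beta_defaults(),
                             noise_sd = 3.3,
                             target_mean_delta = c(male = 4.75, female = 4.61),
                             seed = NULL, ...) {
  if (sex_fraction_male < 0 || sex_fraction_male > 1) {
    stop_domain("sex_fraction_male must lie in [0, 1]")
  }
  if (noise_sd <= 0) stop_domain("noise_sd must be > 0")
  counts <- twb_reference_counts()
  sizes <- counts[counts$factor == "sample_size", ]
  ordinal_probs <- function(f) {
    rows <- counts[counts$factor == f, ]
    list(male = rows$men_count / sizes$men_count,
         female = rows$women_count / sizes$women_count)
  }
  binary_prev <- function(f) {
    row <- counts[counts$factor == f & counts$level == 1, ]
    c(male = row$men_count / sizes$men_count,
      female = row$women_count / sizes$women_count)
  }
  binaries <- c("alone", "job", "jobsame", "medication", "coffee", "tea",
                "drinking", "smoking", "smk2nd", "incense", "vege", "supper")
  spo_rows <- counts[counts$factor %in%
                       c("spo_yesyes", "spo_yesno", "spo_noyes", "spo_nono"), ]
  spo_probs <- list(male = spo_rows$men_count / sizes$men_count,
                    female = spo_rows$women_count / sizes$women_count)
  names(spo_probs$male) <- names(spo_probs$female) <- spo_rows$factor

  cfg <- list(
    n = n,
    sex_fraction_male = sex_fraction_male,
    delta_age = list(male = c(mean = 4.91, sd = 1.51),
                     female = c(mean = 4.88, sd = 1.53),
                     low = 1.6, high = 15.9),
    age_base = list(male = c(mean = 50.15, sd = 11.28),
                    female = c(mean = 49.87, sd = 10.41),
                    low = 20, high = 90),
    # changes in the obesity indices: published means, unpublished SDs
    # (realistic defaults; see the methods vignette)
    obesity_delta = tibble(
      factor = c("delta_bmi", "delta_bfp", "delta_wc", "delta_hc",
                 "delta_whr"),
      male_mean = c(0.19, 0.12, 1.02, -0.18, 0.01),
      female_mean = c(0.27, 0.68, 0.96, 0.20, 0.01),
      male_sd = c(1.3, 3.0, 4.5, 3.0, 0.04),
      female_sd = c(1.3, 3.0, 4.5, 3.0, 0.04)
    ),
    likert = twb_reference_continuous(),       # diet items + education
    ordinal = list(cooking = ordinal_probs("cooking"),
                   nut = ordinal_probs("nut"),
                   supplement = ordinal_probs("supplement")),
    binary = setNames(lapply(binaries, binary_prev), binaries),
    spo = spo_probs,
    # cross-sectional offset of baseline PhenoAge from chronological age
    accel = list(male = c(mean = -5.18, sd = 4.0),
                 female = c(mean = -7.86, sd = 3.6),
                 trunc_sd = 3.5),
    # reference marker levels the back-fill perturbs around
    markers = list(mcv = c(mean = 90, sd = 3),
                   wbc = c(mean = 5.8, sd = 1.0),
                   albumin = c(mean = 45, sd = 2.0),
                   creatinine = list(male = c(mean = 80, sd = 8),
                                     female = c(mean = 62, sd = 7))),
    planted_betas = planted_betas,
    noise_sd = noise_sd,
    target_mean_delta = target_mean_delta,
    coefficient_path = NULL,
    seed = seed
  )
  cfg <- modifyList(cfg, list(...))
  unknown <- setdiff(names(c(cfg$planted_betas$male, cfg$planted_betas$female)),
                     c(factor_roster(), "delta_age"))
  if (length(unknown) > 0) {
    stop_domain(paste0("planted coefficient names not in the factor roster: ",
                       paste(unique(unknown), collapse = ", ")))
  }
  structure(cfg, class = c("generator_config", "list"))
}

# integer Likert draw: discretized normal clamped to the item range
rlikert <- function(n, mean, sd, low, high) {
  pmin(pmax(round(rnorm(n, mean, sd)), low), high)
}

#' Generate a synthetic two-visit cohort
#'
#' Draws a cohort with the schema and marginal structure of the study data:
#' sex, truncated-normal follow-up gap, all 43 lifestyle factors at their
#' published per-sex marginals, an outcome built as the planted linear
#' combination of factors plus Gaussian noise, and biomarker panels at both
#' visits back-filled (by inverting the six-marker score through fasting
#' glucose) so that scoring the panels reproduces the planted change in
#' PhenoAge.
#'
#' @param config a [generator_config()].
#' @param seed RNG seed; overrides `config$seed` when supplied.
#' @return a cohort tibble, one row per participant: `id`, `sex`,
#'   chronological ages, `delta_age`, biomarker panels (`*_base`, `*_fu`),
#'   the 43 factors, and `delta_phenoage` (years). The configuration is
#'   attached as attribute `"config"`.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 200, seed = 7))
#' dim(cohort)
#' @export
generate_cohort <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  sex <- ifelse(runif(n) < config$sex_fraction_male, "male", "female")
  is_m <- sex == "male"

  by_sex <- function(male_par, female_par, fun) {
    out <- numeric(n)
    out[is_m] <- fun(sum(is_m), male_par)
    out[!is_m] <- fun(sum(!is_m), female_par)
    out
  }
  # the configured mean is the target mean of the *truncated* law, so the
  # parent location is solved to offset the truncation bias
  da <- config$delta_age
  delta_age <- by_sex(da$male, da$female, function(m, p) {
    mu <- truncnorm_parent_mean(p[["mean"]], p[["sd"]], da$low, da$high)
    rtruncnorm(m, mu, p[["sd"]], da$low, da$high)
  })
  ab <- config$age_base
  chron_age_base <- by_sex(ab$male, ab$female, function(m, p) {
    rtruncnorm(m, p[["mean"]], p[["sd"]], ab$low, ab$high)
  })
  chron_age_fu <- chron_age_base + delta_age

  cohort <- tibble(
    id = sprintf("SYN%06d", seq_len(n)),
    sex = sex,
    chron_age_base = chron_age_base,
    chron_age_fu = chron_age_fu,
    delta_age = delta_age
  )

  ob <- config$obesity_delta
  for (i in seq_len(nrow(ob))) {
    cohort[[ob$factor[i]]] <- by_sex(
      c(ob$male_mean[i], ob$male_sd[i]), c(ob$female_mean[i], ob$female_sd[i]),
      function(m, p) rnorm(m, p[1], p[2]))
  }
  lk <- config$likert
  for (i in seq_len(nrow(lk))) {
    f <- lk$factor[i]
    high <- if (f == "education") 7 else 5
    cohort[[f]] <- by_sex(c(lk$men_mean[i], lk$men_sd[i]),
                          c(lk$women_mean[i], lk$women_sd[i]),
                          function(m, p) rlikert(m, p[1], p[2], 1, high))
  }
  for (f in names(config$ordinal)) {
    pr <- config$ordinal[[f]]
    cohort[[f]] <- by_sex(pr$male, pr$female, function(m, p) {
      sample.int(length(p), m, replace = TRUE, prob = p)
    })
  }
  for (f in names(config$binary)) {
    pr <- config$binary[[f]]
    cohort[[f]] <- by_sex(pr[["male"]], pr[["female"]],
                          function(m, p) rbinom(m, 1, p))
  }
  spo_levels <- names(config$spo$male)
  spo_draw <- by_sex(config$spo$male, config$spo$female, function(m, p) {
    sample.int(length(p), m, replace = TRUE, prob = p)
  })
  for (j in seq_along(spo_levels)) {
    cohort[[spo_levels[j]]] <- as.integer(spo_draw == j)
  }

  # outcome: planted linear model with per-sex intercept calibrated to the
  # target mean, plus Gaussian noise
  eta <- numeric(n)
  for (s in c("male", "female")) {
    betas <- config$planted_betas[[s]]
    rows <- sex == s
    if (!any(rows)) next
    contrib <- numeric(sum(rows))
    for (nm in names(betas)) {
      contrib <- contrib + betas[[nm]] * cohort[[nm]][rows]
    }
    contrib <- contrib + (config$target_mean_delta[[s]] - mean(contrib))
    eta[rows] <- contrib
  }
  cohort$delta_phenoage <- eta + rnorm(n, 0, config$noise_sd)

  # baseline PhenoAge tracks chronological age with a cross-sectional offset
  acc <- config$accel
  accel <- by_sex(acc$male, acc$female, function(m, p) {
    rtruncnorm(m, p[["mean"]], p[["sd"]],
               p[["mean"]] - acc$trunc_sd * p[["sd"]],
               p[["mean"]] + acc$trunc_sd * p[["sd"]])
  })
  phenoage_base <- chron_age_base + accel
  phenoage_fu <- phenoage_base + cohort$delta_phenoage

  spec <- six_marker_spec(config$coefficient_path)
  mk <- config$markers
  mcv <- pmax(rnorm(n, mk$mcv[["mean"]], mk$mcv[["sd"]]), 60)
  wbc <- pmax(rnorm(n, mk$wbc[["mean"]], mk$wbc[["sd"]]), 1)
  albumin <- pmax(rnorm(n, mk$albumin[["mean"]], mk$albumin[["sd"]]), 25)
  creatinine <- pmax(by_sex(mk$creatinine$male, mk$creatinine$female,
                            function(m, p) rnorm(m, p[["mean"]], p[["sd"]])),
                     20)
  offsets <- sex_mapping(sex)
  w <- spec$weights
  backfill <- function(phenoage, chron_age) {
    six_target <- (phenoage - offsets$offset) / offsets$slope
    xb_target <- xb_for_six_marker(six_target, spec)
    rest <- spec$intercept + w[["mcv"]] * mcv + w[["wbc"]] * wbc +
      w[["albumin"]] * albumin + w[["creatinine"]] * creatinine +
      w[["chron_age"]] * chron_age
    glucose <- (xb_target - rest) / w[["glucose"]]
    mcv_v <- mcv
    low <- glucose < 0.3  # absorb the deficit into MCV, keeping xb exact
    if (any(low)) {
      mcv_v[low] <- mcv[low] - (0.3 - glucose[low]) * w[["glucose"]] / w[["mcv"]]
      glucose[low] <- 0.3
    }
    tibble(mcv = mcv_v, wbc = wbc, albumin = albumin,
           creatinine = creatinine, glucose = glucose)
  }
  base_panel <- backfill(phenoage_base, chron_age_base)
  fu_panel <- backfill(phenoage_fu, chron_age_fu)
  names(base_panel) <- paste0(names(base_panel), "_base")
  names(fu_panel) <- paste0(names(fu_panel), "_fu")

  out <- bind_cols(
    cohort[c("id", "sex", "chron_age_base", "chron_age_fu", "delta_age")],
    base_panel, fu_panel,
    cohort[setdiff(names(cohort),
                   c("id", "sex", "chron_age_base", "chron_age_fu",
                     "delta_age", "delta_phenoage"))],
    cohort["delta_phenoage"]
  )
  attr(out, "config") <- config
  out
}

#' Per-sex descriptive summary of a cohort
#'
#' Mean and SD for continuous columns, count and percentage per level for
#' ordinal and binary factors, and the per-sex fraction of participants
#' whose PhenoAge decreased over follow-up.
#'
#' @param cohort a cohort tibble ([generate_cohort()] / [read_cohort()]).
#' @return list with tibbles `continuous` (`factor`, `sex`, `mean`, `sd`),
#'   `categorical` (`factor`, `level`, `sex`, `count`, `pct`), `outcome`
#'   (`sex`, `n`, `mean_delta_phenoage`, `sd_delta_phenoage`,
#'   `frac_negative`).
#' @examples
#' cohort <- generate_cohort(generator_config(n = 300, seed = 1))
#' summarize_cohort(cohort)$outcome
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) stop_domain("cohort is empty")
  categorical <- c("cooking", "nut", "supplement",
                   "alone", "job", "jobsame", "medication", "coffee", "tea",
                   "drinking", "smoking", "smk2nd", "incense", "vege",
                   "supper", "spo_yesyes", "spo_yesno", "spo_noyes",
                   "spo_nono")
  categorical <- intersect(categorical, names(cohort))
  continuous <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))],
                        categorical)

  cont <- cohort |>
    select(dplyr::all_of(c("sex", continuous))) |>
    tidyr::pivot_longer(-"sex", names_to = "factor") |>
    group_by(.data$factor, .data$sex) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop")

  cat_tbl <- cohort |>
    select(dplyr::all_of(c("sex", categorical))) |>
    tidyr::pivot_longer(-"sex", names_to = "factor", values_to = "level") |>
    group_by(.data$factor, .data$sex, .data$level) |>
    summarise(count = n(), .groups = "drop_last") |>
    mutate(pct = 100 * .data$count / sum(.data$count)) |>
    ungroup() |>
    arrange(.data$factor, .data$sex, .data$level)

  outcome <- NULL
  if ("delta_phenoage" %in% names(cohort)) {
    outcome <- cohort |>
      group_by(.data$sex) |>
      summarise(n = n(),
                mean_delta_phenoage = mean(.data$delta_phenoage),
                sd_delta_phenoage = sd(.data$delta_phenoage),
                frac_negative = mean(.data$delta_phenoage < 0),
                .groups = "drop")
  }
  list(continuous = cont, categorical = cat_tbl, outcome = outcome)
}
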