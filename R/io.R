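#' Pipeline configuration
#'
#' Bundles everything the end-to-end analysis needs: the column map from
#' dataset names to canonical names, the units each biomarker column is
#' recorded in, the outcome / covariate / factor declarations, the
#' screening threshold, the forced-in predictors, the sex strata, and the
#' seed.
#'
#' @param column_map named character vector mapping dataset column names to
#'   canonical names (`c(ALBUMIN = "albumin_base", ...)`); empty when the
#'   file already uses canonical names.
#' @param units named character vector giving the unit of any biomarker
#'   column not already in canonical units (e.g.
#'   `c(glucose_base = "mg/dL")`).
#' @param sex_codes named character vector translating dataset sex codes to
#'   `"male"` / `"female"`.
#' @param outcome outcome column name.
#' @param covariates stage-1 adjusting covariates.
#' @param factors factor columns to screen (default: the 43-factor roster).
#' @param alpha stage-1 selection threshold, in (0, 1).
#' @param forced predictors forced into every stage-2 model.
#' @param strata sex strata fitted in stage 2.
#' @param seed RNG seed recorded in output provenance.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(column_map = character(), units = character(),
                            sex_codes = c(male = "male", female = "female"),
                            outcome = "delta_phenoage",
                            covariates = c("sex", "delta_age"),
                            factors = factor_roster(),
                            alpha = 0.05, forced = "delta_age",
                            strata = c("male", "female"), seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop_domain("alpha must lie in (0, 1)")
  if (anyDuplicated(unname(column_map)) > 0) {
    stop_domain("column_map maps two dataset columns to the same name")
  }
  structure(list(column_map = column_map, units = units,
                 sex_codes = sex_codes, outcome = outcome,
                 covariates = covariates, factors = factors, alpha = alpha,
                 forced = forced, strata = strata, seed = seed),
            class = c("pipeline_config", "list"))
}

#' Read and validate a cohort CSV
#'
#' Reads a delimited cohort table (missing values as empty fields), renames
#' columns through the config's column map, translates sex codes, converts
#' biomarker columns to canonical units, and applies a single global
#' complete-case filter over the columns the analysis uses, logging the
#' number of dropped rows.
#'
#' @param path CSV file path.
#' @param config a [pipeline_config()].
#' @return a validated cohort tibble.
#' @export
read_cohort <- function(path, config = pipeline_config()) {
  if (!file.exists(path)) stop_domain(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                         comment = "#", progress = FALSE)
  if (length(config$column_map) > 0) {
    hits <- match(names(config$column_map), names(raw))
    if (anyNA(hits)) {
      stop_domain(paste0("column_map names absent from file: ",
                         paste(names(config$column_map)[is.na(hits)],
                               collapse = ", ")))
    }
    names(raw)[hits] <- unname(config$column_map)
  }
  # delta_phenoage can be computed from the panels, so it is not required
  required <- unique(c("sex", config$covariates, config$factors))
  if (config$outcome != "delta_phenoage") {
    required <- unique(c(required, config$outcome))
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_domain(paste0("cohort file lacks declared column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  raw$sex <- as.character(raw$sex)
  known <- raw$sex %in% names(config$sex_codes)
  if (!all(known)) {
    stop_domain(paste0("unknown sex code(s): ",
                       paste(unique(raw$sex[!known]), collapse = ", ")))
  }
  raw$sex <- unname(config$sex_codes[raw$sex])
  for (col in names(config$units)) {
    if (!col %in% names(raw)) next
    marker <- sub("_(base|fu)$", "", col)
    raw[[col]] <- convert_units(raw[[col]], marker, config$units[[col]])
  }
  used_cols <- intersect(unique(c("sex", config$outcome, config$covariates,
                                  config$factors)), names(raw))
  keep <- complete.cases(raw[used_cols])
  if (any(!keep)) {
    inform(paste0("read_cohort: dropped ", sum(!keep),
                  " incomplete row(s); ", sum(keep), " retained"))
  }
  raw[keep, , drop = FALSE]
}

#' Write a cohort (or any tibble) as CSV with a provenance header
#'
#' @param data tibble to write.
#' @param path output file.
#' @param provenance named character vector written as leading `#` comment
#'   lines.
#' @return `path`, invisibly.
#' @export
write_provenance_csv <- function(data, path, provenance = character()) {
  header <- c(
    paste0("# phenodelta ", as.character(utils::packageVersion("phenodelta"))),
    paste0("# ", names(provenance), ": ", unname(provenance))
  )
  writeLines(header, path)
  readr::write_csv(data, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

read_provenance_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Run the full two-stage analysis pipeline
#'
#' Scores the biomarker panels at both visits, computes the change in
#' PhenoAge, screens every declared factor by partial correlation (pooled,
#' adjusting for the configured covariates), then fits a sex-stratified
#' exact best-subset model over the screen-selected candidates with the
#' configured predictors forced in. Candidates that are constant within a
#' stratum are dropped from that stratum with a warning.
#'
#' @param cohort cohort tibble ([generate_cohort()] or [read_cohort()]).
#' @param config a [pipeline_config()].
#' @param out_dir if non-`NULL`, the report bundle is also written there as
#'   CSV files with provenance headers (screen, one model per stratum,
#'   summaries).
#' @return a `pheno_pipeline` list: `cohort` (scored), `screen`, `models`
#'   (one [best_subset()] per stratum), `summary`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  scored <- score_cohort(cohort)
  screen <- screen_factors(scored, config$outcome, config$factors,
                           covariates = config$covariates,
                           alpha = config$alpha)
  candidates <- setdiff(screen$factor_name[screen$selected], config$forced)

  models <- lapply(config$strata, function(s) {
    stratum <- scored[scored$sex == s, , drop = FALSE]
    usable <- candidates[vapply(candidates, function(f) {
      length(unique(stratum[[f]])) > 1
    }, logical(1))]
    if (length(usable) < length(candidates)) {
      warn(paste0("stratum ", s, ": dropping constant candidate(s): ",
                  paste(setdiff(candidates, usable), collapse = ", ")))
    }
    best_subset(stratum, config$outcome, usable, forced = config$forced)
  })
  names(models) <- config$strata

  bundle <- structure(
    list(cohort = scored, screen = screen, models = models,
         summary = summarize_cohort(scored), config = config),
    class = "pheno_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(bundle, out_dir)
  bundle
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Write a pipeline report bundle to disk
#'
#' @param bundle a [run_pipeline()] result.
#' @param out_dir output directory (created if absent).
#' @return character vector of files written, invisibly.
#' @export
write_pipeline <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "pheno_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(seed = as.character(bundle$config$seed),
            config_hash = config_hash(bundle$config))
  files <- character()
  p <- file.path(out_dir, "screen.csv")
  write_provenance_csv(tidy(bundle$screen), p, prov)
  files <- c(files, p)
  for (s in names(bundle$models)) {
    p <- file.path(out_dir, paste0("model_", s, ".csv"))
    write_provenance_csv(tidy(bundle$models[[s]]), p, prov)
    files <- c(files, p)
  }
  p <- file.path(out_dir, "summary_continuous.csv")
  write_provenance_csv(bundle$summary$continuous, p, prov)
  files <- c(files, p)
  p <- file.path(out_dir, "summary_categorical.csv")
  write_provenance_csv(bundle$summary$categorical, p, prov)
  files <- c(files, p)
  if (!is.null(bundle$summary$outcome)) {
    p <- file.path(out_dir, "summary_outcome.csv")
    write_provenance_csv(bundle$summary$outcome, p, prov)
    files <- c(files, p)
  }
  invisible(files)
}
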