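#' Load a Gompertz mortality-score specification
#'
#' A specification bundles the linear-predictor intercept and per-marker
#' weights, the Gompertz rate and horizon used to turn the linear predictor
#' into a 120-month mortality risk, and the constants of the affine-log-log
#' inversion that maps that risk onto an age scale. The packaged default is
#' the ten-term clinical specification of the original PhenoAge publication,
#' shipped as a versioned YAML file that users may replace with their own.
#'
#' @param path path to a YAML coefficient file; `NULL` uses the packaged
#'   ten-term specification.
#' @param quiet suppress the checksum message emitted at load.
#' @return an object of class `gompertz_spec`: a list with elements
#'   `version`, `intercept`, `weights` (named numeric), `transforms`
#'   (named character, e.g. `"log"` for CRP), `units` (named character),
#'   `gamma` (per-month rate), `horizon` (months), and `inversion`
#'   (list with `offset`, `scale`, `rate`).
#' @examples
#' spec <- phenoage_spec()
#' names(spec$weights)
#' @export
phenoage_spec <- function(path = NULL, quiet = TRUE) {
  path <- path %||% system.file("extdata", "levine2018-phenoage.yaml",
                                package = "phenodelta", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  needed <- c("gamma", "horizon_months", "intercept", "inversion", "markers")
  miss <- setdiff(needed, names(raw))
  if (length(miss) > 0) {
    stop_domain(paste0("coefficient file lacks field(s): ",
                       paste(miss, collapse = ", ")))
  }
  weights <- vapply(raw$markers, function(m) as.numeric(m$weight), numeric(1))
  names(weights) <- vapply(raw$markers, function(m) m$name, character(1))
  transforms <- vapply(raw$markers, function(m) m$transform %||% "identity",
                       character(1))
  names(transforms) <- names(weights)
  units <- vapply(raw$markers, function(m) m$unit %||% "", character(1))
  names(units) <- names(weights)
  spec <- structure(
    list(
      version   = raw$version %||% "unversioned",
      intercept = as.numeric(raw$intercept),
      weights   = weights,
      transforms = transforms,
      units     = units,
      gamma     = as.numeric(raw$gamma),
      horizon   = as.numeric(raw$horizon_months),
      inversion = list(offset = as.numeric(raw$inversion$offset),
                       scale  = as.numeric(raw$inversion$scale),
                       rate   = as.numeric(raw$inversion$rate)),
      checksum  = unname(tools::md5sum(path))
    ),
    class = "gompertz_spec"
  )
  if (spec$gamma <= 0) stop_domain("gamma must be > 0")
  if (spec$horizon <= 0) stop_domain("horizon must be > 0")
  if (!quiet) {
    inform(paste0("loaded coefficient file ", basename(path),
                  " (", spec$version, "), md5 ", spec$checksum))
  }
  spec
}

#' Six-marker reduction of a PhenoAge specification
#'
#' Drops the weights for markers not assayed in the Taiwan Biobank panel
#' (lymphocyte percentage, red cell distribution width, alkaline
#' phosphatase, C-reactive protein), retaining the original intercept and
#' the weights of the six remaining terms (MCV, WBC, albumin, creatinine,
#' fasting glucose, chronological age). The downstream sex-specific linear
#' mapping absorbs the systematic offset this truncation introduces.
#'
#' @inheritParams phenoage_spec
#' @param keep markers to retain; defaults to the six-marker panel.
#' @return a `gompertz_spec` covering only the retained markers.
#' @examples
#' six_marker_spec()$weights
#' @export
six_marker_spec <- function(path = NULL,
                            keep = c("mcv", "wbc", "albumin", "creatinine",
                                     "glucose", "chron_age")) {
  spec <- phenoage_spec(path)
  unknown <- setdiff(keep, names(spec$weights))
  if (length(unknown) > 0) {
    stop_domain(paste0("marker(s) not in specification: ",
                       paste(unknown, collapse = ", ")))
  }
  spec$weights <- spec$weights[keep]
  spec$transforms <- spec$transforms[keep]
  spec$units <- spec$units[keep]
  spec$version <- paste0(spec$version, "+reduced", length(keep))
  spec
}

#' @export
print.gompertz_spec <- function(x, ...) {
  cat("<gompertz_spec> ", x$version, "\n", sep = "")
  cat("  intercept: ", format(x$intercept), "; gamma: ", format(x$gamma),
      "/month; horizon: ", x$horizon, " months\n", sep = "")
  cat("  markers: ", paste0(names(x$weights), " (", x$units, ")",
                            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Sex-specific linear mapping from six-marker PhenoAge to PhenoAge
#'
#' Returns the offset (years) and slope of the published linear calibration
#' from the six-marker score to full PhenoAge, estimated sex-stratified on
#' NHANES III.
#'
#' @param sex character vector of `"male"` / `"female"`.
#' @return tibble with columns `sex`, `offset`, `slope`, one row per input.
#' @examples
#' sex_mapping(c("male", "female"))
#' @export
sex_mapping <- function(sex = c("male", "female")) {
  sex <- as.character(sex)
  bad <- setdiff(unique(sex), c("male", "female"))
  if (length(bad) > 0) {
    stop_domain(paste0("unknown sex code(s): ", paste(bad, collapse = ", "),
                       " (expected 'male' or 'female')"))
  }
  constants <- tibble(
    sex = c("male", "female"),
    offset = c(45.846752, 46.527973),
    slope = c(1.068403, 1.023272)
  )
  constants[match(sex, constants$sex), ]
}

# canonical units for each biomarker and the conversions accepted at ingest
unit_table <- function() {
  tibble(
    marker = c("albumin", "albumin", "creatinine", "creatinine",
               "glucose", "glucose", "mcv", "wbc", "crp",
               "lymphocyte_pct", "rdw", "alp", "chron_age"),
    unit   = c("g/L", "g/dL", "umol/L", "mg/dL",
               "mmol/L", "mg/dL", "fL", "1000 cells/uL", "mg/dL",
               "percent", "percent", "U/L", "years"),
    factor = c(1, 10, 1, 88.42,
               1, 1 / 18.016, 1, 1, 1,
               1, 1, 1, 1)
  )
}

#' Convert biomarker values to the units the score expects
#'
#' @param value numeric vector of raw values.
#' @param marker canonical marker name (e.g. `"glucose"`).
#' @param from unit the values are currently in (e.g. `"mg/dL"`).
#' @return numeric vector in the canonical unit of `marker`.
#' @examples
#' convert_units(100, "glucose", "mg/dL") # -> mmol/L
#' @export
convert_units <- function(value, marker, from) {
  tab <- unit_table()
  row <- tab[tab$marker == marker & tab$unit == from, ]
  if (nrow(row) == 0) {
    stop_domain(paste0("no conversion registered for marker '", marker,
                       "' from unit '", from, "'"))
  }
  value * row$factor[[1]]
}
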