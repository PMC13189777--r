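#' Linear predictor of the mortality score
#'
#' Computes `intercept + sum(weight * marker)` over the markers a
#' specification covers. Markers in the panel that the specification does
#' not cover are ignored; markers the specification covers must be present
#' and strictly positive. CRP (when covered) enters as its natural log.
#'
#' @param panel a data frame (one row per panel) or a named numeric vector /
#'   list with one element per marker, named by canonical marker name
#'   (`mcv`, `wbc`, `albumin`, `creatinine`, `glucose`, `chron_age`, and
#'   optionally `lymphocyte_pct`, `rdw`, `alp`, `crp`), in the
#'   specification's units.
#' @param spec a [phenoage_spec()] / [six_marker_spec()] object.
#' @return numeric vector, one dimensionless linear-predictor value per row.
#' @examples
#' panel <- tibble::tibble(mcv = 90, wbc = 5.8, albumin = 45,
#'                         creatinine = 80, glucose = 5.5, chron_age = 50)
#' linear_predictor(panel, six_marker_spec())
#' @export
linear_predictor <- function(panel, spec = six_marker_spec()) {
  if (!inherits(spec, "gompertz_spec")) stop_domain("spec must be a gompertz_spec")
  if (!is.data.frame(panel)) panel <- as_tibble(as.list(panel))
  xb <- rep(spec$intercept, nrow(panel))
  for (marker in names(spec$weights)) {
    if (!marker %in% names(panel)) stop_missing_marker(marker)
    value <- panel[[marker]]
    if (anyNA(value)) stop_missing_marker(marker)
    if (any(value <= 0)) {
      if (spec$transforms[[marker]] == "log") {
        stop_domain(paste0("non-positive value for log-transformed marker: ",
                           marker))
      }
      stop_domain(paste0("non-positive value for marker: ", marker))
    }
    if (spec$transforms[[marker]] == "log") value <- log(value)
    xb <- xb + spec$weights[[marker]] * value
  }
  unname(xb)
}

# cumulative Gompertz hazard multiplier over the spec horizon:
# integral of exp(gamma * t) over (0, horizon)
gompertz_cumhaz <- function(spec) (exp(spec$gamma * spec$horizon) - 1) / spec$gamma

#' Mortality risk over the specification horizon
#'
#' Transforms a linear predictor through the Gompertz mortality model:
#' `risk = 1 - exp(-exp(xb) * (exp(gamma * horizon) - 1) / gamma)`.
#' Strictly increasing in `xb`; in (0, 1) for any finite `xb` (values very
#' close to 1 saturate at double precision).
#'
#' @param xb numeric vector of linear-predictor values (finite).
#' @inheritParams linear_predictor
#' @return numeric vector of probabilities.
#' @examples
#' mortality_risk(-13, six_marker_spec())
#' @export
mortality_risk <- function(xb, spec = six_marker_spec()) {
  if (any(!is.finite(xb))) stop_domain("xb must be finite")
  -expm1(-exp(xb) * gompertz_cumhaz(spec))
}

#' PhenoAge from a mortality risk
#'
#' Applies the affine-log-log inversion
#' `offset + log(scale * (-log(1 - risk))) / rate` mapping a horizon
#' mortality risk onto the age scale. The complement `1 - risk` is taken in
#' log space (`log1p(-risk)`) to avoid cancellation near `risk = 1`; a
#' pre-computed log-complement may be supplied instead of `risk` for risks
#' that are not representable below 1.
#'
#' @param risk numeric vector of probabilities, strictly inside (0, 1).
#' @inheritParams linear_predictor
#' @param log_complement optional: `log(1 - risk)` supplied directly, in
#'   which case `risk` is ignored. Must be strictly negative and finite.
#' @return numeric vector, PhenoAge in years.
#' @examples
#' phenoage_from_risk(0.5, six_marker_spec())
#' @export
phenoage_from_risk <- function(risk, spec = six_marker_spec(),
                               log_complement = NULL) {
  inv <- spec$inversion
  if (is.null(log_complement)) {
    if (any(!is.finite(risk)) || any(risk <= 0) || any(risk >= 1)) {
      stop_domain("risk must lie strictly inside (0, 1)")
    }
    log_complement <- log1p(-risk)
  } else {
    if (any(!is.finite(log_complement)) || any(log_complement >= 0)) {
      stop_domain("log_complement must be finite and strictly negative")
    }
  }
  inv$offset + log(inv$scale * (-log_complement)) / inv$rate
}

# exact composition phenoage(mortality_risk(xb)) without forming the risk:
# -log(1 - risk) = exp(xb) * cumhaz, so the composition is affine in xb.
phenoage_from_xb <- function(xb, spec) {
  if (any(!is.finite(xb))) stop_domain("xb must be finite")
  inv <- spec$inversion
  inv$offset + (log(inv$scale) + xb + log(gompertz_cumhaz(spec))) / inv$rate
}

#' Six-marker PhenoAge
#'
#' Scores a six-marker-complete panel through the full chain
#' linear predictor -> Gompertz horizon risk -> age-scale inversion. The
#' composition is evaluated in log space so extreme panels never saturate
#' at `risk = 1`.
#'
#' @inheritParams linear_predictor
#' @return numeric vector, six-marker PhenoAge in years.
#' @examples
#' panel <- tibble::tibble(mcv = 90, wbc = 5.8, albumin = 45,
#'                         creatinine = 80, glucose = 5.5, chron_age = 50)
#' six_marker_phenoage(panel)
#' @export
six_marker_phenoage <- function(panel, spec = six_marker_spec()) {
  phenoage_from_xb(linear_predictor(panel, spec), spec)
}

#' Map six-marker PhenoAge to PhenoAge with the sex-specific calibration
#'
#' @param six_marker_value numeric vector, six-marker PhenoAge in years.
#' @param sex character vector (`"male"`/`"female"`), recycled if length 1.
#' @return numeric vector, PhenoAge in years.
#' @examples
#' map_to_phenoage(0, "male")   # the male calibration offset
#' map_to_phenoage(0, "female")
#' @export
map_to_phenoage <- function(six_marker_value, sex) {
  if (any(!is.finite(six_marker_value))) {
    stop_domain("six_marker_value must be finite")
  }
  if (length(sex) == 1) sex <- rep(sex, length(six_marker_value))
  m <- sex_mapping(sex)
  m$offset + m$slope * six_marker_value
}

#' Within-individual change in PhenoAge
#'
#' @param baseline,followup PhenoAge in years at the two visits (finite).
#' @return `followup - baseline`, in years.
#' @examples
#' delta_phenoage(40, 44.9)
#' @export
delta_phenoage <- function(baseline, followup) {
  if (any(!is.finite(baseline)) || any(!is.finite(followup))) {
    stop_domain("baseline and followup must be finite")
  }
  followup - baseline
}

# invert the scoring chain: the xb that yields a given six-marker PhenoAge
xb_for_six_marker <- function(six_marker_value, spec) {
  inv <- spec$inversion
  inv$rate * (six_marker_value - inv$offset) - log(inv$scale) -
    log(gompertz_cumhaz(spec))
}

#' Score a data frame of biomarker panels
#'
#' Data-frame-first wrapper around the scoring chain: takes a table with
#' one row per panel (canonical marker columns plus a sex column) and
#' returns it with the linear predictor, horizon mortality risk, six-marker
#' PhenoAge, and mapped PhenoAge appended.
#'
#' @param data data frame with marker columns named as in
#'   [linear_predictor()] and a sex column.
#' @inheritParams linear_predictor
#' @param sex_col name of the sex column (values `"male"`/`"female"`).
#' @return `data` as a tibble with columns `xb`, `risk`, `phenoage_6marker`,
#'   `phenoage` appended.
#' @examples
#' tibble::tibble(sex = "male", mcv = 90, wbc = 5.8, albumin = 45,
#'                creatinine = 80, glucose = 5.5, chron_age = 50) |>
#'   score_phenoage()
#' @export
score_phenoage <- function(data, spec = six_marker_spec(), sex_col = "sex") {
  if (!sex_col %in% names(data)) {
    stop_domain(paste0("sex column '", sex_col, "' not found"))
  }
  xb <- linear_predictor(data, spec)
  out <- as_tibble(data)
  out$xb <- xb
  out$risk <- mortality_risk(xb, spec)
  out$phenoage_6marker <- phenoage_from_xb(xb, spec)
  out$phenoage <- map_to_phenoage(out$phenoage_6marker,
                                  as.character(data[[sex_col]]))
  out
}

#' Score a two-visit cohort and compute the change in PhenoAge
#'
#' Expects the cohort layout produced by [generate_cohort()] /
#' [read_cohort()]: marker columns suffixed `_base` and `_fu` for the two
#' visits plus `sex`. Appends `phenoage_base`, `phenoage_fu` and
#' `delta_phenoage` (scored, years).
#'
#' @param cohort two-visit cohort tibble.
#' @inheritParams linear_predictor
#' @return the cohort with the three scored columns appended (an existing
#'   `delta_phenoage` column is overwritten with the scored value).
#' @export
score_cohort <- function(cohort, spec = six_marker_spec()) {
  panel_at <- function(visit) {
    cols <- paste0(names(spec$weights), "_", visit)
    cols[names(spec$weights) == "chron_age"] <- paste0("chron_age_", visit)
    missing_cols <- setdiff(cols, names(cohort))
    if (length(missing_cols) > 0) {
      stop_missing_marker(sub(paste0("_", visit, "$"), "", missing_cols[1]))
    }
    panel <- cohort[cols]
    names(panel) <- names(spec$weights)
    panel
  }
  pa <- function(visit) {
    map_to_phenoage(six_marker_phenoage(panel_at(visit), spec),
                    as.character(cohort$sex))
  }
  out <- as_tibble(cohort)
  out$phenoage_base <- pa("base")
  out$phenoage_fu <- pa("fu")
  out$delta_phenoage <- delta_phenoage(out$phenoage_base, out$phenoage_fu)
  out
}
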