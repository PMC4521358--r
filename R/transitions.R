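# Annual transitions other than death: rural-urban migration hazards with
# linear secular trends, and education-category assignment for birth cohorts
# tracking the prevalence trend among women aged 20-24.

#' Migration parameter table
#'
#' One row per direction x education category with columns `direction`
#' (`rural_to_urban`/`urban_to_rural`), `education`, `base_rate` (moves per
#' person-year at the reference year) and `trend` (change per calendar year).
#' The effective rate is clamped to `[0, 1]`. A net parameterization (the
#' default in the synthetic scenarios) pins all urban-to-rural rates at 0.
#'
#' @param table data.frame with the columns above.
#' @param reference_year Calendar year at which `base_rate` applies.
#' @return An object of class `migration_params`.
#' @export
migration_params <- function(table, reference_year) {
  need <- c("direction", "education", "base_rate", "trend")
  if (!all(need %in% names(table)))
    stop("migration table needs columns: ", paste(need, collapse = ", "))
  if (!all(table$direction %in% c("rural_to_urban", "urban_to_rural")))
    stop("unknown migration direction")
  structure(list(table = table, reference_year = as.integer(reference_year)),
            class = "migration_params")
}

#' Migration hazard for a direction, education category and year
#'
#' `clamp(base_rate + trend * (year - reference_year), 0, 1)`; clamping absorbs
#' extrapolation beyond the fitted window.
#'
#' @param mp A [migration_params()] object.
#' @param direction `"rural_to_urban"` or `"urban_to_rural"`.
#' @param education Education category `"E0"`..`"E3"`.
#' @param year Calendar year.
#' @return Moves per person-year in `[0, 1]`.
#' @export
migration_hazard <- function(mp, direction, education, year) {
  tab <- mp$table
  i <- which(tab$direction == direction & tab$education == education)
  if (length(i) != 1L)
    stop("migration stratum not resolvable: ", direction, "/", education)
  pmin(1, pmax(0, tab$base_rate[i] + tab$trend[i] * (year - mp$reference_year)))
}

#' Education-trend parameters for birth cohorts
#'
#' Per residence: a baseline 4-vector of education-category proportions for the
#' reference birth cohort and a per-year trend 4-vector. The distribution for a
#' birth year is the baseline plus trend, with negative entries truncated to 0
#' and the vector renormalized to the simplex. Because education is fixed at
#' birth, the prevalence among women aged 20-24 in a survey year follows this
#' trend by construction.
#'
#' @param urban,rural Lists with components `baseline` (4-vector on the
#'   simplex) and `trend` (4-vector, proportions per calendar year).
#' @param reference_year Birth year at which the baselines apply.
#' @return An object of class `education_trend_params`.
#' @export
education_trend_params <- function(urban, rural, reference_year) {
  for (x in list(urban, rural)) {
    if (length(x$baseline) != 4L || length(x$trend) != 4L)
      stop("baseline and trend must be 4-vectors")
    if (any(x$baseline < 0) || abs(sum(x$baseline) - 1) > 1e-9)
      stop("baseline proportions must lie on the simplex")
  }
  structure(list(urban = urban, rural = rural,
                 reference_year = as.integer(reference_year)),
            class = "education_trend_params")
}

#' Education distribution assigned to a birth cohort
#'
#' @param etp An [education_trend_params()] object.
#' @param birth_year Calendar year of birth.
#' @param residence `"urban"` or `"rural"`.
#' @return Probability 4-vector over education categories (sums to 1).
#' @export
newborn_education_distribution <- function(etp, birth_year, residence) {
  if (!residence %in% c("urban", "rural")) stop("unknown residence")
  par <- etp[[residence]]
  v <- par$baseline + par$trend * (birth_year - etp$reference_year)
  project_simplex(v)
}

# truncate negatives at zero and renormalize; degenerate all-zero vectors fall
# back to the last category (cannot occur from valid baselines)
project_simplex <- function(v) {
  v <- pmax(v, 0)
  s <- sum(v)
  if (s <= 0) return(c(0, 0, 0, 1))
  v / s
}
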