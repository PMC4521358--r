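# Gompertz-Pasupuleti cumulative fertility with a linear secular trend in the
# lifetime quantum F. The curve's timing parameters (a = median age of
# fertility, b = 5%-95% rise interval) are time-invariant per stratum.

#' Gompertz-Pasupuleti cumulative fertility curve
#'
#' Cumulative births per woman up to exact age `t`:
#' `G(t) = F * (1/2) ^ (r ^ ((t - a) / b))` with shape constant
#' r = log(0.95) / log(0.05).
#' `G` is strictly increasing in `t`, approaches `F` at high ages, equals
#' `F / 2` at `t = a`, and rises from 5% to 95% of `F` over an age interval of
#' exactly `b` years.
#'
#' @param F Lifetime births per woman (> 0).
#' @param a Median age of fertility in years (> 0).
#' @param b Length in years of the 5%-95% rise interval (> 0).
#' @param t Age in years (vectorized).
#' @return Cumulative births per woman at each age in `t`.
#' @export
gp_cumulative <- function(F, a, b, t) {
  if (any(!is.finite(c(F, a, b))) || F <= 0 || a <= 0 || b <= 0)
    stop("F, a and b must be positive")
  F * gp_shape(t, a, b)
}

# shape s(t) in (0, 1): G(t) = F * s(t)
gp_shape <- function(t, a, b) {
  r <- log(0.95) / log(0.05)
  0.5 ^ (r ^ ((t - a) / b))
}

#' Fertility parameter table
#'
#' One row per fertility stratum (residence only in model variant v1; residence
#' x education in v2/v3) with columns `residence`, `education` (NA in v1), `F`
#' (lifetime births per woman at the reference year), `a`, `b` (years), and
#' `trend_F` (births per woman per calendar year). `reference_year` anchors the
#' linear trend; the effective quantum in year `y` is
#' `F_eff = max(0, F + trend_F * (y - reference_year))`.
#'
#' @param table data.frame with the columns above.
#' @param reference_year Calendar year at which `F` applies.
#' @return An object of class `fertility_params`.
#' @export
fertility_params <- function(table, reference_year) {
  need <- c("residence", "F", "a", "b", "trend_F")
  if (!all(need %in% names(table)))
    stop("fertility table needs columns: ", paste(need, collapse = ", "))
  if (!"education" %in% names(table)) table$education <- NA_character_
  if (any(table$F <= 0) || any(table$a <= 0) || any(table$b <= 0))
    stop("F, a and b must be positive at the reference year")
  structure(list(table = table, reference_year = as.integer(reference_year)),
            class = "fertility_params")
}

fert_row <- function(fp, residence, education) {
  tab <- fp$table
  if (all(is.na(tab$education))) {
    i <- which(tab$residence == residence)
  } else {
    i <- which(tab$residence == residence & tab$education == education)
  }
  if (length(i) != 1L)
    stop("fertility stratum not resolvable: ", residence, "/", education)
  tab[i, ]
}

fert_effective_F <- function(F, trend_F, year, reference_year) {
  pmax(0, F + trend_F * (year - reference_year))
}

#' Annual age-specific fertility rate
#'
#' Births per woman-year at a given attained age, computed as the increment of
#' the cumulative curve, `G(age + 1) - G(age)`, with the trend-adjusted quantum
#' of the requested calendar year.
#'
#' @param fp A [fertility_params()] object.
#' @param age Attained age in completed years.
#' @param year Calendar year.
#' @param residence,education Stratum selectors (education ignored when the
#'   parameter table is residence-only).
#' @return Births per woman-year (non-negative).
#' @export
annual_fertility_rate <- function(fp, age, year, residence, education = NA) {
  row <- fert_row(fp, residence, education)
  Feff <- fert_effective_F(row$F, row$trend_F, year, fp$reference_year)
  Feff * pmax(gp_shape(age + 1, row$a, row$b) - gp_shape(age, row$a, row$b), 0)
}

#' Period total fertility rate
#'
#' Sum of the annual age-specific rates over all ages 0..`age_cap`; telescopes
#' to the effective quantum `F_eff` of the year up to tail truncation.
#'
#' @inheritParams annual_fertility_rate
#' @param age_cap Maximum age.
#' @return Births per woman.
#' @export
total_fertility_rate <- function(fp, year, residence, education = NA,
                                 age_cap = 110L) {
  row <- fert_row(fp, residence, education)
  Feff <- fert_effective_F(row$F, row$trend_F, year, fp$reference_year)
  Feff * (gp_shape(age_cap + 1, row$a, row$b) - gp_shape(0, row$a, row$b))
}
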