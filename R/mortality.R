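# Mortality: an education decomposition of aggregate rates via relative risks
# against the lowest-attainment reference category, and a Lee-Carter-type
# log-linear surface (constant + calendar-year slope + age slope) fit per
# residence within three age clusters (<1, 1-10, >10 years).

#' Decompose an aggregate mortality rate into its reference-category rate
#'
#' Given an aggregate (education-pooled) mortality rate, the education
#' composition `p` of the group, and relative risks `rr` against the reference
#' (lowest attainment) category, the reference-category rate is
#' `mu_ref = mu_agg / sum(p * rr)` with `rr[1] = 1` by convention.
#' [aggregate_mortality()] is the exact inverse: `mu_agg = mu_ref * sum(p * rr)`.
#'
#' @param mu_agg Aggregate mortality rate (deaths per person-year, >= 0).
#' @param p Education proportions (length 4, non-negative, summing to 1).
#' @param rr Relative risks (length 4, positive; reference category first).
#' @return Deaths per person-year in the reference category.
#' @export
reference_mortality <- function(mu_agg, p, rr) {
  check_decomposition(mu_agg, p, rr)
  mu_agg / sum(p * rr)
}

#' @rdname reference_mortality
#' @param mu_ref Reference-category mortality rate (deaths per person-year).
#' @export
aggregate_mortality <- function(mu_ref, p, rr) {
  check_decomposition(mu_ref, p, rr)
  mu_ref * sum(p * rr)
}

check_decomposition <- function(mu, p, rr) {
  if (length(p) != 4L || length(rr) != 4L)
    stop("p and rr must have length 4 (education categories E0-E3)")
  if (any(p < 0)) stop("education proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("education proportions must sum to 1")
  if (any(rr <= 0)) stop("relative risks must be positive")
  if (mu < 0) stop("mortality rate must be non-negative")
  invisible(TRUE)
}

#' Map ages to mortality age clusters
#'
#' Clusters: `infant` (age 0), `child` (ages 1-10 inclusive), `adult` (11+).
#'
#' @param age Attained ages in completed years.
#' @return Character vector of cluster labels.
#' @export
age_cluster <- function(age) {
  if (any(age < 0)) stop("age must be non-negative")
  ifelse(age < 1, "infant", ifelse(age <= 10, "child", "adult"))
}

#' Lee-Carter-type mortality surface parameters
#'
#' One row per residence x age cluster with columns `residence`, `cluster`
#' (`infant`/`child`/`adult`), `c` (log-mortality intercept), `beta_year`
#' (per-calendar-year slope), `beta_age` (per-year-of-age slope),
#' `reference_year` and `reference_age` (centering constants).
#'
#' @param table data.frame with the columns above.
#' @return An object of class `lee_carter_params`.
#' @export
lee_carter_params <- function(table) {
  need <- c("residence", "cluster", "c", "beta_year", "beta_age",
            "reference_year", "reference_age")
  if (!all(need %in% names(table)))
    stop("Lee-Carter table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(table[, c("residence", "cluster")]))
    stop("duplicate (residence, cluster) rows")
  structure(list(table = table), class = "lee_carter_params")
}

#' Lee-Carter mortality rate for the reference education category
#'
#' `exp(c + beta_year * (year - reference_year) + beta_age * (age -
#' reference_age))` for the cluster containing `age`, per residence. Log
#' mortality is exactly additive in the three terms.
#'
#' @param lc A [lee_carter_params()] object.
#' @param age Attained age in completed years (within `[0, age_cap]`).
#' @param year Calendar year.
#' @param residence `"urban"` or `"rural"`.
#' @param age_cap Maximum valid age.
#' @return Deaths per person-year (strictly positive).
#' @export
lee_carter_rate <- function(lc, age, year, residence, age_cap = 110L) {
  if (any(age < 0) || any(age > age_cap)) stop("age outside [0, age_cap]")
  cl <- age_cluster(age)
  tab <- lc$table
  i <- match(paste(residence, cl), paste(tab$residence, tab$cluster))
  if (anyNA(i)) stop("Lee-Carter parameters missing for ", residence)
  exp(tab$c[i] + tab$beta_year[i] * (year - tab$reference_year[i]) +
        tab$beta_age[i] * (age - tab$reference_age[i]))
}

#' Stratified mortality hazard
#'
#' The reference-category Lee-Carter rate for the residence, multiplied by the
#' residence x education relative risk. In model variant v1 all relative risks
#' are 1 and the surface applies to aggregate rates directly.
#'
#' @inheritParams lee_carter_rate
#' @param rr Relative-risk matrix `[residence, education]` with the reference
#'   column (E0) equal to 1 in each residence; all entries positive.
#' @param education Education category (`"E0"`..`"E3"`).
#' @return Deaths per person-year.
#' @export
mortality_hazard <- function(lc, rr, age, year, residence, education,
                             age_cap = 110L) {
  check_rr_matrix(rr)
  lee_carter_rate(lc, age, year, residence, age_cap) * rr[residence, education]
}

check_rr_matrix <- function(rr) {
  if (!is.matrix(rr) || !all(c("urban", "rural") %in% rownames(rr)) ||
      !all(c("E0", "E1", "E2", "E3") %in% colnames(rr)))
    stop("rr must be a matrix with residence rows and education columns")
  if (any(rr <= 0)) stop("relative risks must be positive")
  if (any(abs(rr[, "E0"] - 1) > 1e-12))
    stop("reference category E0 must have rr = 1 in each residence")
  invisible(TRUE)
}
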