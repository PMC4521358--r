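# Calibration targets: five survey-style classes (children-ever-born,
# probability of death, education-category prevalence, migration lookback
# proportions, population size) plus validation-only life expectancy. Each row
# carries a point estimate with a 95% interval; the likelihood is independent
# Gaussian with a CI-derived standard deviation.

TARGET_CLASSES <- c("fertility", "mortality", "education", "migration",
                    "population_size", "life_expectancy_validation")

# value-column name used in the per-class CSV dialects
CLASS_VALUE_COLUMN <- c(
  fertility = "children_ever_born",
  mortality = "probability_of_death",
  education = "proportion",
  migration = "proportion",
  population_size = "population",
  life_expectancy_validation = "life_expectancy"
)

#' Construct a validated target set
#'
#' @param df data.frame with columns `class`, `year`, `age_low`, `age_high`,
#'   `residence`, `education`, `window`, `estimate`, `ci_low`, `ci_high`,
#'   `calibration`. Missing descriptor columns are added as NA.
#' @return The data.frame with class `target_set`, rows validated.
#' @export
target_set <- function(df) {
  cols <- c("class", "year", "age_low", "age_high", "residence", "education",
            "window", "estimate", "ci_low", "ci_high", "calibration")
  for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
  df <- df[, cols]
  if (nrow(df)) {
    bad <- which(!df$class %in% TARGET_CLASSES)
    if (length(bad))
      stop("unknown target class in rows ", paste(bad, collapse = ", "),
           ": ", paste(unique(df$class[bad]), collapse = ", "))
    bad <- which(df$ci_low > df$estimate | df$estimate > df$ci_high)
    if (length(bad))
      stop("CI does not bracket the estimate in rows ",
           paste(head(bad, 10), collapse = ", "))
    bad <- which(df$class == "population_size" & df$estimate <= 0)
    if (length(bad))
      stop("non-positive population size in rows ", paste(bad, collapse = ", "))
    # education prevalence groups must lie on the simplex
    ed <- df[df$class == "education" & !is.na(df$estimate), ]
    if (nrow(ed)) {
      grp <- paste(ed$year, ed$residence, ed$age_low, ed$age_high)
      sums <- tapply(ed$estimate, grp, sum)
      off <- names(sums)[abs(sums - 1) > 0.05]
      if (length(off))
        stop("education prevalence group off the simplex: ",
             paste(off, collapse = "; "))
    }
    # validation-only life expectancy never enters the likelihood
    df$calibration[df$class == "life_expectancy_validation"] <- FALSE
    df$calibration[is.na(df$calibration)] <- TRUE
  }
  class(df) <- c("target_set", "data.frame")
  df
}

#' Load calibration targets from a manifest
#'
#' The manifest (YAML) lists one entry per file:
#' ```
#' targets:
#'   - class: fertility
#'     file: fertility.csv
#'     calibration: true
#' ```
#' Each class has its own CSV dialect (see the value-column names in
#' [write_targets()]); malformed rows are reported with their line numbers.
#'
#' @param path Path to a manifest YAML file, or a directory containing
#'   `manifest.yaml`.
#' @return A `target_set`.
#' @export
load_targets <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.yaml")
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- yaml::read_yaml(path)
  entries <- man$targets
  base <- dirname(path)
  pieces <- list()
  for (en in entries) {
    cl <- en$class
    if (!cl %in% TARGET_CLASSES) stop("unknown target class in manifest: ", cl)
    f <- file.path(base, en$file)
    if (!file.exists(f)) stop("target file not found: ", f)
    raw <- read.csv(f, stringsAsFactors = FALSE)
    if (!nrow(raw)) next
    df <- normalize_target_csv(raw, cl, f)
    df$calibration <- if (is.null(en$calibration)) TRUE else isTRUE(en$calibration)
    pieces[[length(pieces) + 1L]] <- df
  }
  if (!length(pieces)) {
    empty <- data.frame(class = character(), year = integer(),
                        age_low = integer(), age_high = integer(),
                        residence = character(), education = character(),
                        window = character(), estimate = numeric(),
                        ci_low = numeric(), ci_high = numeric(),
                        calibration = logical())
    return(target_set(empty))
  }
  target_set(do.call(rbind, pieces))
}

normalize_target_csv <- function(raw, cl, file) {
  vcol <- CLASS_VALUE_COLUMN[[cl]]
  # migration dialect uses survey_year / residence_at_survey
  if ("survey_year" %in% names(raw) && !"year" %in% names(raw))
    names(raw)[names(raw) == "survey_year"] <- "year"
  if ("residence_at_survey" %in% names(raw) && !"residence" %in% names(raw))
    names(raw)[names(raw) == "residence_at_survey"] <- "residence"
  need <- c("year", vcol, "ci_low", "ci_high")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop(file, ": missing columns ", paste(miss, collapse = ", "))
  bad <- which(!complete.cases(raw[, need]))
  if (length(bad))
    stop(file, ": malformed rows at lines ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  bad <- which(raw$ci_low > raw[[vcol]] | raw[[vcol]] > raw$ci_high)
  if (length(bad))
    stop(file, ": CI inversion at lines ", paste(bad + 1L, collapse = ", "))
  data.frame(
    class = cl,
    year = as.integer(raw$year),
    age_low = if ("age_low" %in% names(raw)) raw$age_low else NA_integer_,
    age_high = if ("age_high" %in% names(raw)) raw$age_high else NA_integer_,
    residence = if ("residence" %in% names(raw)) raw$residence else NA_character_,
    education = if ("education" %in% names(raw)) raw$education else NA_character_,
    window = if ("window" %in% names(raw)) raw$window else NA_character_,
    estimate = raw[[vcol]],
    ci_low = raw$ci_low,
    ci_high = raw$ci_high,
    stringsAsFactors = FALSE
  )
}

#' Write a target set as per-class CSVs plus a manifest
#'
#' @param targets A `target_set`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_targets <- function(targets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (cl in unique(targets$class)) {
    sub <- targets[targets$class == cl, ]
    vcol <- CLASS_VALUE_COLUMN[[cl]]
    out <- data.frame(year = sub$year)
    if (cl == "migration") names(out) <- "survey_year"
    if (!all(is.na(sub$age_low))) {
      out$age_low <- sub$age_low
      out$age_high <- sub$age_high
    }
    if (!all(is.na(sub$residence))) {
      out[[if (cl == "migration") "residence_at_survey" else "residence"]] <-
        sub$residence
    }
    if (!all(is.na(sub$education))) out$education <- sub$education
    if (!all(is.na(sub$window))) out$window <- sub$window
    out[[vcol]] <- sub$estimate
    out$ci_low <- sub$ci_low
    out$ci_high <- sub$ci_high
    f <- paste0(cl, ".csv")
    write.csv(out, file.path(dir, f), row.names = FALSE)
    entries[[length(entries) + 1L]] <-
      list(class = cl, file = f, calibration = all(sub$calibration))
  }
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(targets = entries), manifest)
  invisible(manifest)
}

#' Gaussian log-likelihood of model outcomes against targets
#'
#' Independent Normal log-density per calibration row, with standard deviation
#' derived from the 95% interval, `sigma = (ci_high - ci_low) / 3.92`, floored
#' at `max(sigma_floor_rel * |estimate|, sigma_floor_abs)` so degenerate
#' zero-width intervals cannot dominate. Validation-only rows (life
#' expectancy) never contribute.
#'
#' @param outcomes Output of [extract_outcomes()]: a target set with a `model`
#'   column. Alternatively a bare `target_set` plus `model` vector.
#' @param model Optional numeric vector of model values aligned to `outcomes`
#'   rows (used when `outcomes` has no `model` column).
#' @param sigma_floor_rel,sigma_floor_abs Floors for the Gaussian sd.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(outcomes, model = NULL, sigma_floor_rel = 0.01,
                           sigma_floor_abs = 1e-8) {
  df <- as.data.frame(outcomes)
  if (!is.null(model)) {
    if (length(model) != nrow(df)) stop("model values misaligned with targets")
    df$model <- model
  }
  if (!"model" %in% names(df)) stop("outcomes must carry a model column")
  if (!"calibration" %in% names(df)) df$calibration <- TRUE
  df <- df[df$calibration, ]
  if (!nrow(df)) return(0)
  sigma <- pmax((df$ci_high - df$ci_low) / 3.92,
                sigma_floor_rel * abs(df$estimate), sigma_floor_abs)
  sum(dnorm(df$estimate, mean = df$model, sd = sigma, log = TRUE))
}

#' Deviance from a log-likelihood
#'
#' @param loglik Finite log-likelihood value(s).
#' @return `-2 * loglik`.
#' @export
deviance_from_loglik <- function(loglik) {
  if (any(!is.finite(loglik))) stop("log-likelihood must be finite")
  -2 * loglik
}
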