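# ParameterSet: everything the calibration estimates, for one model variant.
#   v1: age + residence; fertility and mortality with trends, education pooled,
#       no migration.
#   v2: + education stratification (RRs, education-specific fertility,
#       education-prevalence trends), no migration.
#   v3: + migration rates and their trends.
# The set always carries all components; the inactive ones are held at neutral
# values (rr = 1, zero migration, zero education trend) so that the three
# variants are strictly nested.

#' Construct a parameter set for one model variant
#'
#' @param variant `"v1"`, `"v2"` or `"v3"`.
#' @param fertility A [fertility_params()] object (residence-only rows for v1,
#'   residence x education rows for v2/v3).
#' @param lc A [lee_carter_params()] object (residence x age-cluster rows).
#' @param rr Relative-risk matrix `[residence, education]`, E0 column = 1.
#' @param migration A [migration_params()] object.
#' @param edu An [education_trend_params()] object.
#' @param primary_edu_year Optional calendar year from which a universal
#'   primary education intervention moves all rural E0 newborn mass to E1.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(variant, fertility, lc, rr, migration, edu,
                          primary_edu_year = NULL) {
  variant <- match.arg(variant, c("v1", "v2", "v3"))
  stopifnot(inherits(fertility, "fertility_params"),
            inherits(lc, "lee_carter_params"),
            inherits(migration, "migration_params"),
            inherits(edu, "education_trend_params"))
  check_rr_matrix(rr)
  if (variant == "v1" && !all(is.na(fertility$table$education)))
    stop("v1 fertility must be residence-only (education NA)")
  if (variant %in% c("v2", "v3") && anyNA(fertility$table$education))
    stop("v2/v3 fertility must be stratified by education")
  structure(list(variant = variant, fertility = fertility, lc = lc, rr = rr,
                 migration = migration, edu = edu,
                 primary_edu_year = primary_edu_year),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> variant %s: %d fertility strata, %d LC cells",
              x$variant, nrow(x$fertility$table), nrow(x$lc$table)))
  if (!is.null(x$primary_edu_year))
    cat(sprintf(", primary-education intervention from %d", x$primary_edu_year))
  cat("\n")
  invisible(x)
}

RESIDENCES <- c("urban", "rural")
EDUCATIONS <- c("E0", "E1", "E2", "E3")
CLUSTERS   <- c("infant", "child", "adult")

#' Free-parameter specification for a model variant
#'
#' Names, sampling blocks and vague-prior bounds for every parameter the MCMC
#' estimates under the given variant. Bounds are wide uniforms; callers may
#' pass an edited copy to [calibrate()] to change the prior ranges.
#'
#' @param variant `"v1"`, `"v2"` or `"v3"`.
#' @return data.frame with columns `name`, `block`, `lower`, `upper`.
#' @export
param_spec <- function(variant) {
  variant <- match.arg(variant, c("v1", "v2", "v3"))
  rows <- list()
  add <- function(name, block, lower, upper)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, block = block,
                                             lower = lower, upper = upper)
  fert_strata <- if (variant == "v1") {
    data.frame(residence = RESIDENCES, education = NA_character_)
  } else {
    expand.grid(education = EDUCATIONS, residence = RESIDENCES,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1]
  }
  for (i in seq_len(nrow(fert_strata))) {
    tag <- fert_tag(fert_strata$residence[i], fert_strata$education[i])
    add(paste0("fert_F_", tag), paste0("fert_", tag), 0.2, 10)
    add(paste0("fert_a_", tag), paste0("fert_", tag), 10, 40)
    add(paste0("fert_b_", tag), paste0("fert_", tag), 1, 30)
  }
  add("fert_trend", "fert_trend", -0.2, 0.2)
  for (res in RESIDENCES) for (cl in CLUSTERS) {
    blk <- paste0("lc_", res, "_", cl)
    add(paste0("lc_c_", res, "_", cl), blk, -14, -0.5)
    add(paste0("lc_byear_", res, "_", cl), blk, -0.1, 0.1)
    add(paste0("lc_bage_", res, "_", cl), blk, -1, 1)
  }
  if (variant %in% c("v2", "v3")) {
    for (res in RESIDENCES)
      for (e in EDUCATIONS[-1])
        add(paste0("rr_", res, "_", e), paste0("rr_", res), 0.05, 2)
    for (res in RESIDENCES)
      for (e in EDUCATIONS)
        add(paste0("edu_trend_", res, "_", e), paste0("edu_", res), -0.05, 0.05)
  }
  if (variant == "v3") {
    for (e in EDUCATIONS) {
      add(paste0("mig_base_", e), paste0("mig_", e), 0, 0.2)
      add(paste0("mig_trend_", e), paste0("mig_", e), -0.01, 0.01)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fert_tag <- function(residence, education) {
  ifelse(is.na(education), residence, paste0(residence, "_", education))
}

#' Flatten a parameter set to a named vector of its free parameters
#'
#' The flat view round-trips losslessly with [vector_to_params()]; reference
#' years, education baselines and neutralized components are carried by the
#' template parameter set, not the vector.
#'
#' @param params A `parameter_set`.
#' @return Named numeric vector ordered as in [param_spec()].
#' @export
params_to_vector <- function(params) {
  spec <- param_spec(params$variant)
  ft <- params$fertility$table
  v <- numeric(nrow(spec))
  names(v) <- spec$name
  for (i in seq_len(nrow(ft))) {
    tag <- fert_tag(ft$residence[i], ft$education[i])
    v[paste0("fert_F_", tag)] <- ft$F[i]
    v[paste0("fert_a_", tag)] <- ft$a[i]
    v[paste0("fert_b_", tag)] <- ft$b[i]
  }
  v["fert_trend"] <- ft$trend_F[1]
  lt <- params$lc$table
  for (i in seq_len(nrow(lt))) {
    tag <- paste0(lt$residence[i], "_", lt$cluster[i])
    v[paste0("lc_c_", tag)] <- lt$c[i]
    v[paste0("lc_byear_", tag)] <- lt$beta_year[i]
    v[paste0("lc_bage_", tag)] <- lt$beta_age[i]
  }
  if (params$variant %in% c("v2", "v3")) {
    for (res in RESIDENCES) {
      for (e in EDUCATIONS[-1])
        v[paste0("rr_", res, "_", e)] <- params$rr[res, e]
      v[paste0("edu_trend_", res, "_", EDUCATIONS)] <- params$edu[[res]]$trend
    }
  }
  if (params$variant == "v3") {
    mt <- params$migration$table
    r2u <- mt[mt$direction == "rural_to_urban", ]
    for (e in EDUCATIONS) {
      v[paste0("mig_base_", e)] <- r2u$base_rate[r2u$education == e]
      v[paste0("mig_trend_", e)] <- r2u$trend[r2u$education == e]
    }
  }
  v
}

#' @rdname params_to_vector
#' @param v Named numeric vector as produced by `params_to_vector()`.
#' @param template A `parameter_set` of the same variant supplying everything
#'   the vector does not carry.
#' @export
vector_to_params <- function(v, template) {
  spec <- param_spec(template$variant)
  if (!all(spec$name %in% names(v)))
    stop("vector is missing parameters: ",
         paste(setdiff(spec$name, names(v)), collapse = ", "))
  p <- template
  ft <- p$fertility$table
  for (i in seq_len(nrow(ft))) {
    tag <- fert_tag(ft$residence[i], ft$education[i])
    ft$F[i] <- v[paste0("fert_F_", tag)]
    ft$a[i] <- v[paste0("fert_a_", tag)]
    ft$b[i] <- v[paste0("fert_b_", tag)]
  }
  ft$trend_F <- v["fert_trend"]
  p$fertility$table <- ft
  lt <- p$lc$table
  for (i in seq_len(nrow(lt))) {
    tag <- paste0(lt$residence[i], "_", lt$cluster[i])
    lt$c[i] <- v[paste0("lc_c_", tag)]
    lt$beta_year[i] <- v[paste0("lc_byear_", tag)]
    lt$beta_age[i] <- v[paste0("lc_bage_", tag)]
  }
  p$lc$table <- lt
  if (template$variant %in% c("v2", "v3")) {
    for (res in RESIDENCES) {
      for (e in EDUCATIONS[-1])
        p$rr[res, e] <- v[paste0("rr_", res, "_", e)]
      p$edu[[res]]$trend <- unname(v[paste0("edu_trend_", res, "_", EDUCATIONS)])
    }
  }
  if (template$variant == "v3") {
    mt <- p$migration$table
    for (e in EDUCATIONS) {
      i <- which(mt$direction == "rural_to_urban" & mt$education == e)
      mt$base_rate[i] <- v[paste0("mig_base_", e)]
      mt$trend[i] <- v[paste0("mig_trend_", e)]
    }
    p$migration$table <- mt
  }
  p
}

#' Neutral building blocks for inactive model components
#'
#' Helpers used when constructing v1/v2 parameter sets: a zero-rate migration
#' table and a unit relative-risk matrix.
#'
#' @param reference_year Calendar year for the migration table.
#' @return `zero_migration()`: a [migration_params()] with all rates and trends
#'   0; `unit_rr()`: a `[residence, education]` matrix of 1s.
#' @export
zero_migration <- function(reference_year) {
  tab <- expand.grid(direction = c("rural_to_urban", "urban_to_rural"),
                     education = EDUCATIONS,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$base_rate <- 0
  tab$trend <- 0
  migration_params(tab, reference_year)
}

#' @rdname zero_migration
#' @export
unit_rr <- function() {
  matrix(1, 2, 4, dimnames = list(RESIDENCES, EDUCATIONS))
}

#' Serialize / deserialize a parameter set as JSON
#'
#' @param params A `parameter_set`.
#' @param path File path.
#' @return `read_params_json()` returns a `parameter_set`.
#' @export
write_params_json <- function(params, path) {
  obj <- list(
    variant = params$variant,
    fertility = list(table = params$fertility$table,
                     reference_year = params$fertility$reference_year),
    lc = list(table = params$lc$table),
    rr = list(values = as.vector(params$rr),
              residences = rownames(params$rr),
              educations = colnames(params$rr)),
    migration = list(table = params$migration$table,
                     reference_year = params$migration$reference_year),
    edu = list(urban = params$edu$urban, rural = params$edu$rural,
               reference_year = params$edu$reference_year),
    primary_edu_year = params$primary_edu_year
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rr <- matrix(obj$rr$values, 2, 4,
               dimnames = list(obj$rr$residences, obj$rr$educations))
  parameter_set(
    variant = obj$variant,
    fertility = fertility_params(obj$fertility$table,
                                 obj$fertility$reference_year),
    lc = lee_carter_params(obj$lc$table),
    rr = rr,
    migration = migration_params(obj$migration$table,
                                 obj$migration$reference_year),
    edu = education_trend_params(
      urban = list(baseline = obj$edu$urban$baseline,
                   trend = obj$edu$urban$trend),
      rural = list(baseline = obj$edu$rural$baseline,
                   trend = obj$edu$rural$trend),
      reference_year = obj$edu$reference_year),
    primary_edu_year = obj$primary_edu_year
  )
}
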