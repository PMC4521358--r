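# Scenario analysis: a static comparator with all secular trends frozen at
# their start-year values (the conventional fixed-exposure health-policy
# model), a universal primary education intervention for rural birth cohorts,
# and difference-in-differences life-expectancy reporting across the four arms
# (dynamic/static x with/without intervention) under common random numbers.

#' Freeze all secular trends at their start-year values
#'
#' Levels are first re-anchored so that the frozen model reproduces the
#' dynamic model's effective rates exactly at `start_year`; then every trend
#' field (fertility `trend_F`, Lee-Carter `beta_year`, migration trends,
#' education trends) is set to 0. Idempotent.
#'
#' @param params A `parameter_set`.
#' @param start_year Calendar year whose effective levels are frozen.
#' @return A `parameter_set` with zero trends.
#' @export
make_static <- function(params, start_year) {
  p <- params
  ft <- p$fertility$table
  ft$F <- pmax(fert_effective_F(ft$F, ft$trend_F, start_year,
                                p$fertility$reference_year), 1e-9)
  ft$trend_F <- 0
  p$fertility$table <- ft
  p$fertility$reference_year <- as.integer(start_year)
  lt <- p$lc$table
  lt$c <- lt$c + lt$beta_year * (start_year - lt$reference_year)
  lt$beta_year <- 0
  lt$reference_year <- as.integer(start_year)
  p$lc$table <- lt
  mt <- p$migration$table
  mt$base_rate <- pmin(1, pmax(0, mt$base_rate +
                                 mt$trend * (start_year - p$migration$reference_year)))
  mt$trend <- 0
  p$migration$table <- mt
  p$migration$reference_year <- as.integer(start_year)
  for (res in RESIDENCES) {
    eff <- project_simplex(p$edu[[res]]$baseline +
                             p$edu[[res]]$trend * (start_year -
                                                     p$edu$reference_year))
    p$edu[[res]]$baseline <- eff
    p$edu[[res]]$trend <- rep(0, 4)
  }
  p$edu$reference_year <- as.integer(start_year)
  p
}

#' Universal primary education intervention for rural birth cohorts
#'
#' From `intervention_year` on, the education distribution assigned to rural
#' newborns moves all no-schooling (E0) probability mass into the primary
#' category (E1); urban distributions and cohorts born earlier are untouched
#' (education is fixed at birth in this model structure).
#'
#' @param params A `parameter_set`.
#' @param intervention_year First birth year affected.
#' @return A `parameter_set` carrying the intervention.
#' @export
apply_primary_education_intervention <- function(params, intervention_year) {
  p <- params
  p$primary_edu_year <- as.integer(intervention_year)
  p
}

#' Annual period life expectancy along a trajectory
#'
#' Count-weighted aggregate hazards per transition year, closed into a period
#' life table.
#'
#' @param trajectory A `trajectory`.
#' @param residence `"all"`, `"urban"` or `"rural"`.
#' @return Named vector of e(0) values, one per transition year.
#' @export
trajectory_life_expectancy <- function(trajectory, residence = "all") {
  yrs <- trajectory$schedules$years
  out <- numeric(length(yrs))
  for (u in seq_along(yrs)) {
    if (residence == "all") {
      w <- apply(trajectory$pop_are[, , , u], 1, sum)
      hw <- apply(trajectory$pop_are[, , , u] *
                    trajectory$schedules$hdie[, , , u], 1, sum)
    } else {
      r_i <- match(residence, RESIDENCES)
      w <- apply(trajectory$pop_are[, r_i, , u, drop = FALSE], 1, sum)
      hw <- apply(trajectory$pop_are[, r_i, , u, drop = FALSE] *
                    trajectory$schedules$hdie[, r_i, , u, drop = FALSE], 1, sum)
    }
    hbar <- ifelse(w > 0, hw / w, 0)
    out[u] <- life_expectancy(build_life_table(hbar))
  }
  names(out) <- yrs
  out
}

#' Run the four scenario arms under common random numbers
#'
#' Arms: dynamic and static (trends frozen at `config$start_year`), each with
#' and without the primary-education intervention. All arms share the start
#' year, initial base population and seed, so in stochastic mode a zero-effect
#' intervention reproduces its baseline arm draw for draw.
#'
#' @param params The dynamic `parameter_set`.
#' @param base_population data.frame (`age`, `residence`, `count`).
#' @param config A [simulation_config()].
#' @param intervention_year First birth year affected by the intervention.
#' @param residence Residence filter for the life-expectancy series.
#' @return A list of class `scenario_result` with per-arm trajectories and
#'   life-expectancy series (`le` entries), shared `config`.
#' @export
run_four_arms <- function(params, base_population, config, intervention_year,
                          residence = "all") {
  # all arms share one initial state, expanded under the dynamic parameters
  if (is.data.frame(base_population))
    base_population <- expand_initial_population(base_population, params,
                                                 config$start_year,
                                                 mode = config$mode,
                                                 age_cap = config$age_cap)
  arms <- list(
    dynamic_base = params,
    dynamic_intervention = apply_primary_education_intervention(params,
                                                                intervention_year),
    static_base = make_static(params, config$start_year),
    static_intervention = apply_primary_education_intervention(
      make_static(params, config$start_year), intervention_year)
  )
  out <- lapply(arms, function(p)
    simulate_population(p, base_population, config))
  le <- lapply(out, trajectory_life_expectancy, residence = residence)
  structure(list(trajectories = out, le = le, config = config,
                 intervention_year = intervention_year),
            class = "scenario_result")
}

#' Difference-in-differences life expectancy between dynamic and static arms
#'
#' Per posterior draw and year:
#' `(LE_dynamic_intervention - LE_dynamic_base) - (LE_static_intervention -
#' LE_static_base)`; the report gives the median and central 95% band over
#' draws.
#'
#' @param dynamic_pair,static_pair Lists with components `base` and
#'   `intervention`, each a draws x years matrix (or a single-year-series
#'   vector) of life expectancy on a common horizon.
#' @return data.frame with columns `year`, `median`, `ci_low`, `ci_high`.
#' @export
diff_in_diff_life_expectancy <- function(dynamic_pair, static_pair) {
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1,
                                                        dimnames = list(NULL, names(x)))
  db <- as_mat(dynamic_pair$base); di <- as_mat(dynamic_pair$intervention)
  sb <- as_mat(static_pair$base); si <- as_mat(static_pair$intervention)
  dims <- lapply(list(db, di, sb, si), dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("horizon mismatch between scenario arms")
  dd <- (di - db) - (si - sb)
  qs <- apply(dd, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  yrs <- colnames(db)
  data.frame(year = if (is.null(yrs)) seq_len(ncol(db)) else as.integer(yrs),
             median = qs[1, ], ci_low = qs[2, ], ci_high = qs[3, ])
}

#' Scenario uncertainty from posterior draws
#'
#' Samples parameter vectors from a calibration fit's pooled posterior, runs
#' the four arms for each, and returns the per-arm life-expectancy draw
#' matrices together with the difference-in-differences table.
#'
#' @param fit A `calibration_fit`.
#' @param base_population data.frame (`age`, `residence`, `count`).
#' @param config A [simulation_config()].
#' @param intervention_year First birth year affected.
#' @param n_draws Number of posterior draws (large for production bands,
#'   small for desk-scale work).
#' @param seed Seed for the draw selection.
#' @param residence Residence filter for life expectancy.
#' @return A list: `le` (per-arm draws x years matrices), `did`
#'   (difference-in-differences table), `draw_index`.
#' @export
posterior_scenarios <- function(fit, base_population, config,
                                intervention_year, n_draws = 200L,
                                seed = 1L, residence = "all") {
  draws <- do.call(rbind, lapply(fit$chains, function(ch) ch$draws))
  set.seed(seed)
  idx <- sample.int(nrow(draws), n_draws, replace = n_draws > nrow(draws))
  arms <- c("dynamic_base", "dynamic_intervention",
            "static_base", "static_intervention")
  le <- setNames(vector("list", 4), arms)
  for (k in seq_along(idx)) {
    p <- vector_to_params(draws[idx[k], ], fit$template)
    res <- run_four_arms(p, base_population, config, intervention_year,
                         residence = residence)
    for (a in arms) {
      if (is.null(le[[a]]))
        le[[a]] <- matrix(NA_real_, length(idx), length(res$le[[a]]),
                          dimnames = list(NULL, names(res$le[[a]])))
      le[[a]][k, ] <- res$le[[a]]
    }
  }
  did <- diff_in_diff_life_expectancy(
    list(base = le$dynamic_base, intervention = le$dynamic_intervention),
    list(base = le$static_base, intervention = le$static_intervention))
  list(le = le, did = did, draw_index = idx)
}
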