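# Annual-step simulation: death and migration are resolved jointly by a
# competing-risks translation of hazards into probabilities, survivors age one
# year, and births (from start-of-year exposures) enter at age 0 with the
# mother's residence and a birth-year education distribution.

#' Competing-risk event probabilities from annual hazards
#'
#' With total hazard `H = sum(hazards)`, each event's annual probability is
#' `(h_i / H) * (1 - exp(-H))` and the no-event probability is `exp(-H)`; the
#' returned vector sums to 1 exactly.
#'
#' @param hazards Named or unnamed non-negative per-year rates.
#' @return Numeric vector: one probability per hazard plus a final `survive`
#'   element.
#' @export
competing_risk_probabilities <- function(hazards) {
  if (any(!is.finite(hazards))) stop("hazards must be finite")
  if (any(hazards < 0)) stop("hazards must be non-negative")
  H <- sum(hazards)
  if (H > 0) {
    p <- hazards / H * (-expm1(-H))
  } else {
    p <- rep(0, length(hazards))
  }
  out <- c(p, survive = 1 - sum(p))
  if (!is.null(names(hazards)))
    names(out) <- c(names(hazards), "survive")
  out
}

#' Simulation configuration
#'
#' @param start_year,end_year Calendar years bounding the simulation
#'   (`start_year < end_year`; equal years give a length-1 trajectory).
#' @param mode `"expected_value"` (deterministic real-valued flows, used inside
#'   MCMC) or `"stochastic"` (integer sampling).
#' @param seed RNG seed, recorded in all outputs.
#' @param fraction_female Fraction of births that are girls (the model tracks
#'   females only while fertility counts all births).
#' @param age_cap Maximum single-year age (open-ended terminal class).
#' @param store_states `"all"`, `"none"`, or an integer vector of calendar
#'   years at which to keep full population states.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(start_year, end_year,
                              mode = c("expected_value", "stochastic"),
                              seed = 1L, fraction_female = 0.487,
                              age_cap = 110L, store_states = "all") {
  mode <- match.arg(mode)
  if (end_year < start_year) stop("end_year must be >= start_year")
  if (fraction_female <= 0 || fraction_female >= 1)
    stop("fraction_female must lie in (0, 1)")
  structure(list(start_year = as.integer(start_year),
                 end_year = as.integer(end_year), mode = mode,
                 seed = as.integer(seed), fraction_female = fraction_female,
                 age_cap = as.integer(age_cap), store_states = store_states),
            class = "simulation_config")
}

# Per-year hazard/probability schedules on the [age, residence, education]
# grid for transition years `years` (start..end-1). Returns probabilities for
# the C++ core plus the underlying death hazards (needed for death-probability
# and life-expectancy outcomes).
build_schedules <- function(params, years, config) {
  A <- config$age_cap + 1L
  Y <- length(years)
  ages <- 0:config$age_cap
  ft <- params$fertility$table
  # expand residence-only (v1) fertility to the full residence x education grid
  full <- expand.grid(residence = RESIDENCES, education = EDUCATIONS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fi <- if (all(is.na(ft$education))) match(full$residence, ft$residence)
        else match(paste(full$residence, full$education),
                   paste(ft$residence, ft$education))
  if (anyNA(fi)) stop("fertility table does not cover the stratum grid")
  # age shape increments ds[a, stratum] and per-year effective quantum
  ds <- sapply(seq_len(nrow(full)), function(k) {
    r <- ft[fi[k], ]
    pmax(gp_shape(ages + 1, r$a, r$b) - gp_shape(ages, r$a, r$b), 0)
  })
  fert <- array(0, dim = c(A, 2L, 4L, max(Y, 1L)))
  hdie <- array(0, dim = c(A, 2L, 4L, max(Y, 1L)))
  hmove <- array(0, dim = c(A, 2L, 4L, max(Y, 1L)))
  nb_edu <- array(0, dim = c(4L, 2L, max(Y, 1L)))
  if (Y > 0) {
    Feff <- sapply(seq_len(nrow(full)), function(k) {
      r <- ft[fi[k], ]
      fert_effective_F(r$F, r$trend_F, years, params$fertility$reference_year)
    })
    Feff <- matrix(Feff, nrow = Y)  # Y x strata
    # reference-category mortality by age and residence, then scaled by RR
    lt <- params$lc$table
    cl <- age_cluster(ages)
    for (res_i in 1:2) {
      res <- RESIDENCES[res_i]
      li <- match(paste(res, cl), paste(lt$residence, lt$cluster))
      age_part <- lt$c[li] + lt$beta_age[li] * (ages - lt$reference_age[li])
      yr_slope <- lt$beta_year[li]
      yr_ref <- lt$reference_year[li]
      for (y in seq_len(Y)) {
        href <- exp(age_part + yr_slope * (years[y] - yr_ref))
        for (e_i in 1:4)
          hdie[, res_i, e_i, y] <- href * params$rr[res, EDUCATIONS[e_i]]
      }
    }
    mt <- params$migration$table
    for (y in seq_len(Y)) {
      for (e_i in 1:4) {
        e <- EDUCATIONS[e_i]
        # moves out of rural are rural-to-urban and vice versa
        hmove[, 2, e_i, y] <- migration_hazard(params$migration,
                                               "rural_to_urban", e, years[y])
        hmove[, 1, e_i, y] <- migration_hazard(params$migration,
                                               "urban_to_rural", e, years[y])
      }
      for (k in seq_len(nrow(full))) {
        r_i <- match(full$residence[k], RESIDENCES)
        e_i <- match(full$education[k], EDUCATIONS)
        fert[, r_i, e_i, y] <- Feff[y, k] * ds[, k]
      }
      for (res_i in 1:2)
        nb_edu[, res_i, y] <- newborn_distribution_with_intervention(
          params, years[y], RESIDENCES[res_i])
    }
  }
  H <- hdie + hmove
  ptot <- -expm1(-H)
  frac <- ifelse(H > 0, ptot / pmax(H, .Machine$double.xmin), 0)
  list(fert = fert, hdie = hdie, hmove = hmove,
       pdie = hdie * frac, pmove = hmove * frac, nb_edu = nb_edu,
       years = years)
}

# birth-cohort education distribution including any primary-education
# intervention carried by the parameter set
newborn_distribution_with_intervention <- function(params, birth_year, residence) {
  d <- newborn_education_distribution(params$edu, birth_year, residence)
  iy <- params$primary_edu_year
  if (!is.null(iy) && residence == "rural" && birth_year >= iy) {
    d[2] <- d[2] + d[1]
    d[1] <- 0
  }
  d
}

# 4 x n matrix of birth-cohort education distributions (vectorized over years)
newborn_edu_matrix <- function(params, birth_years, residence) {
  par <- params$edu[[residence]]
  V <- par$baseline + outer(par$trend, birth_years - params$edu$reference_year)
  iy <- params$primary_edu_year
  if (!is.null(iy) && residence == "rural") {
    hit <- birth_years >= iy
    V[2, hit] <- V[2, hit] + pmax(V[1, hit], 0)
    V[1, hit] <- 0
  }
  V <- pmax(V, 0)
  s <- colSums(V)
  zero <- s <= 0
  if (any(zero)) { V[4, zero] <- 1; s[zero] <- 1 }
  sweep(V, 2, s, "/")
}

#' Expand a base population (age x residence) to the full stratum grid
#'
#' The education split of each pre-simulation birth cohort is generated from
#' the parameter set's birth-year education distribution (cohort born in
#' `start_year - age`), which is what makes the education-prevalence targets
#' informative about the education trend parameters. Migration history starts
#' at "never moved".
#'
#' @param base data.frame with columns `age`, `residence`, `count`.
#' @param params A `parameter_set`.
#' @param start_year First simulated calendar year.
#' @param mode,age_cap Passed to [population_state()].
#' @return A `population_state` for `start_year`.
#' @export
expand_initial_population <- function(base, params, start_year,
                                      mode = "expected_value", age_cap = 110L) {
  need <- c("age", "residence", "count")
  if (!all(need %in% names(base)))
    stop("base population needs columns: ", paste(need, collapse = ", "))
  A <- age_cap + 1L
  arr <- array(0, dim = c(A, 2L, 4L, nrow(mig_states())))
  for (res_i in 1:2) {
    res <- RESIDENCES[res_i]
    sub <- base[base$residence == res, ]
    cnt <- numeric(A)
    cnt[sub$age + 1L] <- sub$count
    V <- newborn_edu_matrix(params, start_year - (0:age_cap), res)  # 4 x A
    arr[, res_i, , 1L] <- cnt * t(V)
  }
  if (mode == "stochastic") arr <- round(arr)
  population_state(arr, year = start_year, mode = mode, age_cap = age_cap)
}

#' Advance a population state by one year
#'
#' Death and migration are resolved jointly by competing risks; survivors age
#' one year and their migration counters advance; births computed from
#' start-of-year exposures enter at age 0. Annual event tallies are attached as
#' the `"tallies"` attribute.
#'
#' @param state A `population_state`.
#' @param params A `parameter_set`.
#' @param config A [simulation_config()] (its `mode`/`age_cap` must match the
#'   state).
#' @return The `population_state` one calendar year later.
#' @export
step_year <- function(state, params, config) {
  stopifnot(inherits(state, "population_state"))
  if (state$age_cap != config$age_cap) stop("age_cap mismatch")
  sched <- build_schedules(params, state$year, config)
  res <- cpp_run_sim(state$counts, sched$pdie, sched$pmove, sched$fert,
                     sched$nb_edu, config$fraction_female,
                     config$mode == "stochastic", integer(0))
  if (any(res$counts < 0)) stop("negative flow: parameter pathology")
  out <- population_state(res$counts, state$year + 1L, mode = state$mode,
                          age_cap = state$age_cap)
  attr(out, "tallies") <- c(births = res$births, deaths = res$deaths,
                            moves = res$moves)
  out
}

#' Run the microsimulation over a calendar horizon
#'
#' @param params A `parameter_set`.
#' @param initial Either a `population_state` whose year equals
#'   `config$start_year`, or a base data.frame (`age`, `residence`, `count`)
#'   expanded with [expand_initial_population()].
#' @param config A [simulation_config()].
#' @return An object of class `trajectory`: per-year population summaries,
#'   event tallies, stored full states, the schedules used, and the inputs.
#' @export
simulate_population <- function(params, initial, config) {
  stopifnot(inherits(params, "parameter_set"),
            inherits(config, "simulation_config"))
  if (is.data.frame(initial))
    initial <- expand_initial_population(initial, params, config$start_year,
                                         mode = config$mode,
                                         age_cap = config$age_cap)
  if (initial$year != config$start_year)
    stop("initial state year must equal start_year")
  if (initial$mode != config$mode) stop("state mode does not match config")
  years_all <- config$start_year:config$end_year
  trans_years <- if (config$end_year > config$start_year)
    config$start_year:(config$end_year - 1L) else integer(0)
  sched <- build_schedules(params, trans_years, config)
  store_idx <- if (identical(config$store_states, "all")) {
    seq_along(years_all)
  } else if (identical(config$store_states, "none")) {
    integer(0)
  } else {
    idx <- match(as.integer(config$store_states), years_all)
    if (anyNA(idx)) stop("store_states years outside the horizon")
    idx
  }
  if (config$mode == "stochastic") set.seed(config$seed)
  if (length(trans_years)) {
    res <- cpp_run_sim(initial$counts,
                       sched$pdie, sched$pmove, sched$fert, sched$nb_edu,
                       config$fraction_female, config$mode == "stochastic",
                       as.integer(store_idx))
  } else {
    pop0 <- apply(initial$counts, c(1, 2, 3), sum)
    dim(pop0) <- c(dim(pop0), 1L)
    res <- list(counts = initial$counts, pop_are = pop0,
                deaths = numeric(0), births = numeric(0), moves = numeric(0),
                stored = if (length(store_idx)) list(initial$counts) else list(),
                stored_at = if (length(store_idx)) 1L else integer(0))
  }
  if (any(res$counts < 0)) stop("negative flow: parameter pathology")
  states <- NULL
  if (length(res$stored_at)) {
    states <- lapply(res$stored, function(cn)
      population_state(cn, NA, mode = config$mode, age_cap = config$age_cap))
    for (i in seq_along(states)) states[[i]]$year <- years_all[res$stored_at[i]]
    names(states) <- years_all[res$stored_at]
  }
  pop_year_res <- apply(res$pop_are, c(4, 2), sum)
  dimnames(pop_year_res) <- list(years_all, RESIDENCES)
  tallies <- data.frame(year = trans_years,
                        births = as.numeric(res$births),
                        deaths = as.numeric(res$deaths),
                        moves = as.numeric(res$moves))
  structure(list(years = years_all, pop_are = res$pop_are,
                 pop_year_res = pop_year_res, tallies = tallies,
                 states = states, schedules = sched, params = params,
                 config = config),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d-%d (%s mode, seed %d): %.0f -> %.0f persons\n",
              x$config$start_year, x$config$end_year, x$config$mode,
              x$config$seed, sum(x$pop_year_res[1, ]),
              sum(x$pop_year_res[nrow(x$pop_year_res), ])))
  invisible(x)
}

# ---- outcome extraction -----------------------------------------------------

#' Model-predicted values aligned to a target set
#'
#' For each target row the trajectory yields the model's answer: population
#' sizes from the per-year totals; children-ever-born from the cumulative
#' fertility curve at the wave year's effective parameters; death probabilities
#' as `1 - exp(-hazard)` averaged over the age band weighted by stratum counts;
#' education prevalence and migration lookback proportions from counts; period
#' life expectancy from the year's count-weighted aggregate hazard schedule.
#'
#' @param trajectory A `trajectory` covering all target years (full states must
#'   be stored at migration/education wave years).
#' @param targets A `target_set` (see [load_targets()]).
#' @return The target data.frame with a `model` column appended.
#' @export
extract_outcomes <- function(trajectory, targets) {
  stopifnot(inherits(trajectory, "trajectory"))
  tg <- as.data.frame(targets)
  years_all <- trajectory$years
  n_trans <- length(trajectory$schedules$years)
  model <- numeric(nrow(tg))
  yi <- match(tg$year, years_all)
  if (anyNA(yi)) stop("target year outside trajectory: ",
                      paste(unique(tg$year[is.na(yi)]), collapse = ", "))

  cls <- tg$class
  if (any(i <- cls == "population_size")) {
    ri <- match(tg$residence[i], RESIDENCES)
    model[i] <- trajectory$pop_year_res[cbind(yi[i], ri)]
  }
  if (any(i <- cls == "fertility")) {
    fp <- trajectory$params$fertility
    ft <- fp$table
    rows <- which(i)
    tmid <- (tg$age_low[rows] + tg$age_high[rows] + 1) / 2
    fi <- if (all(is.na(ft$education)))
      match(tg$residence[rows], ft$residence)
    else
      match(paste(tg$residence[rows], tg$education[rows]),
            paste(ft$residence, ft$education))
    if (anyNA(fi)) stop("fertility stratum not resolvable in targets")
    Feff <- fert_effective_F(ft$F[fi], ft$trend_F[fi], tg$year[rows],
                             fp$reference_year)
    model[rows] <- Feff * gp_shape(tmid, ft$a[fi], ft$b[fi])
  }
  if (any(cls == "mortality")) {
    rows <- which(cls == "mortality")
    key <- paste(tg$year[rows], tg$residence[rows])
    for (u in unique(key)) {
      sel <- rows[key == u]
      y <- yi[sel[1]]
      if (y > n_trans) stop("mortality target year has no transition hazards: ",
                            tg$year[sel[1]])
      r_i <- match(tg$residence[sel[1]], RESIDENCES)
      w <- trajectory$pop_are[, r_i, , y]           # A x E
      q <- 1 - exp(-trajectory$schedules$hdie[, r_i, , y])
      for (s in sel) {
        a_idx <- (tg$age_low[s]:tg$age_high[s]) + 1L
        ww <- w[a_idx, , drop = FALSE]
        model[s] <- if (sum(ww) > 0)
          sum(ww * q[a_idx, , drop = FALSE]) / sum(ww)
        else mean(q[a_idx, ])
      }
    }
  }
  if (any(cls == "education")) {
    rows <- which(cls == "education")
    key <- paste(tg$year[rows], tg$residence[rows], tg$age_low[rows],
                 tg$age_high[rows])
    for (u in unique(key)) {
      sel <- rows[key == u]
      y <- yi[sel[1]]
      r_i <- match(tg$residence[sel[1]], RESIDENCES)
      a_idx <- (tg$age_low[sel[1]]:tg$age_high[sel[1]]) + 1L
      w <- trajectory$pop_are[a_idx, r_i, , y, drop = FALSE]
      tot <- sum(w)
      prev <- if (tot > 0) apply(w, 3, sum) / tot else rep(0.25, 4)
      model[sel] <- prev[match(tg$education[sel], EDUCATIONS)]
    }
  }
  if (any(cls == "migration")) {
    rows <- which(cls == "migration")
    mig <- mig_states()
    win_states <- list(
      `6y`   = which(!is.na(mig$ysm) & mig$ysm <= 5),
      `12y`  = which(!is.na(mig$ysm) & mig$ysm <= 11),
      `ever` = which(mig$direction != "none")
    )
    for (s in rows) {
      st <- trajectory$states[[as.character(tg$year[s])]]
      if (is.null(st)) stop("no stored state at migration target year ",
                            tg$year[s])
      r_i <- match(tg$residence[s], RESIDENCES)
      e_i <- match(tg$education[s], EDUCATIONS)
      a_idx <- (tg$age_low[s]:tg$age_high[s]) + 1L
      grp <- st$counts[a_idx, r_i, e_i, , drop = FALSE]
      tot <- sum(grp)
      ws <- win_states[[tg$window[s]]]
      if (is.null(ws)) stop("unknown migration window: ", tg$window[s])
      model[s] <- if (tot > 0) sum(grp[, , , ws]) / tot else 0
    }
  }
  if (any(cls == "life_expectancy_validation")) {
    rows <- which(cls == "life_expectancy_validation")
    for (u in unique(yi[rows])) {
      sel <- rows[yi[rows] == u]
      if (u > n_trans) stop("life-expectancy target year has no hazards: ",
                            years_all[u])
      for (s in sel) {
        if (identical(tg$residence[s], "all") || is.na(tg$residence[s])) {
          w <- apply(trajectory$pop_are[, , , u], 1, sum)          # by age
          hw <- apply(trajectory$pop_are[, , , u] *
                        trajectory$schedules$hdie[, , , u], 1, sum)
        } else {
          r_i <- match(tg$residence[s], RESIDENCES)
          w <- apply(trajectory$pop_are[, r_i, , u, drop = FALSE], 1, sum)
          hw <- apply(trajectory$pop_are[, r_i, , u, drop = FALSE] *
                        trajectory$schedules$hdie[, r_i, , u, drop = FALSE],
                      1, sum)
        }
        hbar <- ifelse(w > 0, hw / w, 0)
        model[s] <- life_expectancy(build_life_table(hbar))
      }
    }
  }
  known <- c("population_size", "fertility", "mortality", "education",
             "migration", "life_expectancy_validation")
  if (any(!cls %in% known))
    stop("unknown target class: ", paste(setdiff(cls, known), collapse = ", "))
  tg$model <- model
  tg
}

#' Goodness of fit of model outcomes to a target set
#'
#' Per-class coefficients of determination on the natural scale, plus a pooled
#' value computed after standardizing each class by the spread of its target
#' estimates (so classes on different scales contribute comparably).
#'
#' @param outcomes Output of [extract_outcomes()] (targets with `model`).
#' @param calibration_only Restrict to calibration rows (default TRUE).
#' @return A list with `by_class` (named vector) and `pooled` (scalar).
#' @export
outcome_r2 <- function(outcomes, calibration_only = TRUE) {
  df <- outcomes
  if (calibration_only && "calibration" %in% names(df))
    df <- df[df$calibration, ]
  r2 <- function(est, mod) {
    sst <- sum((est - mean(est))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((est - mod)^2) / sst
  }
  by_class <- vapply(split(df, df$class),
                     function(d) r2(d$estimate, d$model), numeric(1))
  zs <- lapply(split(df, df$class), function(d) {
    s <- stats::sd(d$estimate)
    if (!is.finite(s) || s == 0) s <- max(abs(d$estimate), 1)
    list(e = (d$estimate - mean(d$estimate)) / s,
         m = (d$model - mean(d$estimate)) / s)
  })
  e <- unlist(lapply(zs, `[[`, "e"))
  m <- unlist(lapply(zs, `[[`, "m"))
  list(by_class = by_class, pooled = r2(e, m))
}
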