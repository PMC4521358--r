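# Bayesian calibration of a model variant to a target set: adaptive block
# random-walk Metropolis over the variant's free parameters under wide uniform
# priors, multi-chain convergence checking, DIC, and nested model selection.

#' MCMC calibration settings
#'
#' @param iterations Total block updates per chain.
#' @param burn_in Discarded (and adaptive) iterations; default half.
#' @param n_chains Number of chains (4 for desk-scale work; 10 mirrors a
#'   repeated-random-starts convention).
#' @param seed Base seed; chain `k` uses `seed + k`.
#' @param jitter Starting-point dispersion around the heuristic initial fit,
#'   as a fraction of each prior range.
#' @return A list of class `calibration_settings`.
#' @export
calibration_settings <- function(iterations = 20000L, burn_in = NULL,
                                 n_chains = 4L, seed = 1L, jitter = 0.03) {
  if (is.null(burn_in)) burn_in <- floor(iterations / 2)
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 jitter = jitter),
            class = "calibration_settings")
}

# template parameter set for a variant: reference years anchored at the start
# year (Lee-Carter age references at cluster mid-ages), education baselines
# taken from the first-wave prevalence targets, neutral values elsewhere
build_template <- function(variant, targets, start_year) {
  fert_strata <- if (variant == "v1") {
    data.frame(residence = RESIDENCES, education = NA_character_)
  } else {
    expand.grid(residence = RESIDENCES, education = EDUCATIONS,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  fert_strata$F <- 3; fert_strata$a <- 22; fert_strata$b <- 10
  fert_strata$trend_F <- 0
  lc <- expand.grid(residence = RESIDENCES, cluster = CLUSTERS,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lc$c <- -5; lc$beta_year <- 0; lc$beta_age <- 0
  lc$reference_year <- start_year
  lc$reference_age <- c(infant = 0, child = 5, adult = 60)[lc$cluster]
  ed <- targets[targets$class == "education", ]
  baselines <- list(urban = rep(0.25, 4), rural = rep(0.25, 4))
  ref_edu <- start_year - 22L
  if (nrow(ed)) {
    w1 <- min(ed$year)
    ref_edu <- as.integer(w1 - 22L)
    for (res in RESIDENCES) {
      sub <- ed[ed$year == w1 & ed$residence == res, ]
      if (nrow(sub) == 4L) {
        p <- sub$estimate[match(EDUCATIONS, sub$education)]
        baselines[[res]] <- pmax(p, 0) / sum(pmax(p, 0))
      }
    }
  }
  parameter_set(
    variant,
    fertility = fertility_params(fert_strata, start_year),
    lc = lee_carter_params(lc),
    rr = unit_rr(),
    migration = zero_migration(start_year),
    edu = education_trend_params(
      urban = list(baseline = baselines$urban, trend = rep(0, 4)),
      rural = list(baseline = baselines$rural, trend = rep(0, 4)),
      reference_year = ref_edu)
  )
}

# moment-matching starting values from the targets themselves; every value is
# clamped strictly inside the prior bounds
init_from_targets <- function(template, targets, spec) {
  v <- (spec$lower + spec$upper) / 2
  names(v) <- spec$name
  start_year <- template$fertility$reference_year
  ft <- template$fertility$table
  fe <- targets[targets$class == "fertility", ]
  trend_slopes <- c()
  for (i in seq_len(nrow(ft))) {
    res <- ft$residence[i]; edu <- ft$education[i]
    sub <- if (is.na(edu)) fe[fe$residence == res, ]
           else fe[fe$residence == res & fe$education == edu, ]
    if (!nrow(sub)) next
    tag <- fert_tag(res, edu)
    Fw <- tapply(sub$estimate, sub$year, max)
    yrs <- as.numeric(names(Fw))
    if (length(Fw) >= 2) {
      co <- stats::coef(stats::lm(Fw ~ I(yrs - start_year)))
      v[paste0("fert_F_", tag)] <- co[1]
      trend_slopes <- c(trend_slopes, co[2])
    } else {
      v[paste0("fert_F_", tag)] <- Fw[1]
    }
    # timing from the latest wave's cumulative curve
    wl <- max(sub$year)
    sw <- sub[sub$year == wl, ]
    tm <- (sw$age_low + sw$age_high + 1) / 2
    o <- order(tm)
    tm <- tm[o]; ce <- sw$estimate[o]
    Fhat <- max(ce)
    cross <- function(q) {
      y <- ce / Fhat
      if (all(y >= q)) return(tm[1])
      if (all(y < q)) return(tm[length(tm)])
      j <- which(y >= q)[1]
      if (j == 1) return(tm[1])
      tm[j - 1] + (q - y[j - 1]) / (y[j] - y[j - 1]) * (tm[j] - tm[j - 1])
    }
    v[paste0("fert_a_", tag)] <- cross(0.5)
    v[paste0("fert_b_", tag)] <- max(cross(0.95) - cross(0.05), 2)
  }
  if (length(trend_slopes)) v["fert_trend"] <- mean(trend_slopes)
  mo <- targets[targets$class == "mortality", ]
  if (nrow(mo)) {
    mo$mid <- (mo$age_low + mo$age_high) / 2
    mo$cluster <- age_cluster(pmax(mo$mid, 0))
    mo$h <- -log(pmax(1 - mo$estimate, 1e-12))
    for (res in RESIDENCES) for (cl in CLUSTERS) {
      sub <- mo[mo$residence == res & mo$cluster == cl & mo$h > 0, ]
      if (!nrow(sub)) next
      tag <- paste0(res, "_", cl)
      ra <- c(infant = 0, child = 5, adult = 60)[cl]
      dy <- sub$year - start_year
      da <- sub$mid - ra
      est <- tryCatch({
        if (length(unique(da)) > 1)
          stats::coef(stats::lm(log(sub$h) ~ dy + da))
        else c(stats::coef(stats::lm(log(sub$h) ~ dy)), 0)
      }, error = function(e) NULL)
      if (is.null(est) || anyNA(est)) next
      v[paste0("lc_c_", tag)] <- est[1]
      v[paste0("lc_byear_", tag)] <- est[2]
      v[paste0("lc_bage_", tag)] <- est[3]
    }
  }
  if (template$variant %in% c("v2", "v3")) {
    for (res in RESIDENCES)
      v[paste0("rr_", res, "_", EDUCATIONS[-1])] <- c(0.85, 0.7, 0.55)
    ed <- targets[targets$class == "education", ]
    if (nrow(ed) && length(unique(ed$year)) >= 2) {
      for (res in RESIDENCES) for (e in EDUCATIONS) {
        sub <- ed[ed$residence == res & ed$education == e, ]
        if (nrow(sub) >= 2) {
          sl <- stats::coef(stats::lm(sub$estimate ~ sub$year))[2]
          v[paste0("edu_trend_", res, "_", e)] <- sl
        }
      }
    }
  }
  if (template$variant == "v3") {
    mg <- targets[targets$class == "migration" & targets$window == "6y" &
                    targets$residence == "urban", ]
    po <- targets[targets$class == "population_size", ]
    ur_ratio <- 0.4
    if (nrow(po)) {
      u <- mean(po$estimate[po$residence == "urban"])
      r <- mean(po$estimate[po$residence == "rural"])
      if (r > 0) ur_ratio <- u / r
    }
    for (e in EDUCATIONS) {
      sub <- mg[mg$education == e, ]
      if (nrow(sub))
        v[paste0("mig_base_", e)] <- mean(sub$estimate) * ur_ratio / 6
      v[paste0("mig_trend_", e)] <- 0
    }
  }
  pmin(pmax(v, spec$lower + 0.02 * (spec$upper - spec$lower)),
       spec$upper - 0.02 * (spec$upper - spec$lower))
}

# reference (general-path) likelihood; make_loglik() in fast_loglik.R is the
# numerically identical production closure used inside the sampler
reference_loglik <- function(template, targets, base_population, config) {
  function(v) {
    p <- vector_to_params(v, template)
    ll <- tryCatch({
      traj <- simulate_population(p, base_population, config)
      out <- extract_outcomes(traj, targets)
      log_likelihood(out)
    }, error = function(e) -Inf)
    if (!is.finite(ll)) -Inf else ll
  }
}

#' Calibrate a model variant to a target set by MCMC
#'
#' Builds the variant's free-parameter space ([param_spec()]), initializes each
#' chain at a jittered moment-matched fit to the targets, and runs adaptive
#' block random-walk Metropolis chains whose likelihood is the Gaussian target
#' likelihood of the expected-value simulation ([log_likelihood()]). The
#' expected-value mode keeps the likelihood smooth; stochastic runs are for
#' final uncertainty propagation, not for calibration.
#'
#' @param variant `"v1"`, `"v2"` or `"v3"`.
#' @param targets A `target_set` (validation-only rows are ignored by the
#'   likelihood).
#' @param base_population data.frame (`age`, `residence`, `count`) for the
#'   start year.
#' @param settings A [calibration_settings()].
#' @param priors Optional data.frame like [param_spec()] with edited bounds.
#' @param fraction_female Fraction of births that are girls.
#' @return An object of class `calibration_fit`: the chains plus everything
#'   needed to re-evaluate the model (template, spec, config, targets).
#' @export
calibrate <- function(variant, targets, base_population,
                      settings = calibration_settings(),
                      priors = NULL, fraction_female = 0.487) {
  variant <- match.arg(variant, c("v1", "v2", "v3"))
  stopifnot(inherits(targets, "target_set"))
  spec <- param_spec(variant)
  if (!is.null(priors)) {
    i <- match(spec$name, priors$name)
    if (anyNA(i)) stop("priors must cover every parameter of the variant")
    spec$lower <- priors$lower[i]
    spec$upper <- priors$upper[i]
  }
  yrs <- range(targets$year)
  template <- build_template(variant, targets, yrs[1])
  wave_years <- sort(unique(targets$year[targets$class %in%
                                           c("education", "migration")]))
  config <- simulation_config(yrs[1], yrs[2], mode = "expected_value",
                              seed = settings$seed,
                              fraction_female = fraction_female,
                              store_states = if (length(wave_years))
                                wave_years else "none")
  loglik <- make_loglik(template, targets, base_population, config)
  init <- init_from_targets(template, targets, spec)
  blocks <- split(seq_len(nrow(spec)), spec$block)
  rng <- spec$upper - spec$lower
  chains <- vector("list", settings$n_chains)
  for (k in seq_len(settings$n_chains)) {
    seed_k <- settings$seed + k
    set.seed(seed_k)
    start <- NULL
    for (try in 1:20) {
      cand <- pmin(pmax(init + settings$jitter * rng * rnorm(length(init)),
                        spec$lower + 1e-9 * rng), spec$upper - 1e-9 * rng)
      names(cand) <- spec$name
      if (is.finite(loglik(cand))) { start <- cand; break }
    }
    if (is.null(start))
      stop("non-finite likelihood at all starting points (chain ", k, ")")
    chains[[k]] <- mcmc_sample(loglik, start, spec$lower, spec$upper,
                               n_iter = settings$iterations,
                               burn_in = settings$burn_in,
                               blocks = blocks, scale = 0.01 * rng,
                               seed = seed_k)
  }
  structure(list(chains = chains, variant = variant, template = template,
                 spec = spec, settings = settings, targets = targets,
                 base_population = base_population, config = config,
                 loglik = loglik),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> variant %s: %d chains x %d retained draws (%d parameters)\n",
              x$variant, length(x$chains), nrow(x$chains[[1]]$draws),
              nrow(x$spec)))
  invisible(x)
}

#' Pooled posterior mean parameter set of a calibration fit
#'
#' @param fit A `calibration_fit`.
#' @return A `parameter_set` at the (bounds-projected) posterior mean.
#' @export
posterior_mean_params <- function(fit) {
  draws <- do.call(rbind, lapply(fit$chains, function(ch) ch$draws))
  theta <- colMeans(draws)
  theta <- pmin(pmax(theta, fit$spec$lower), fit$spec$upper)
  vector_to_params(theta, fit$template)
}

#' DIC of a calibrated model
#'
#' Mean posterior deviance over the pooled post-burn-in draws, deviance
#' re-evaluated through the simulator at the posterior mean parameter vector
#' (projected into the prior bounds with a warning if it falls outside), and
#' the Spiegelhalter decomposition `p_D = mean(D) - D(mean)`,
#' `DIC = mean(D) + p_D`. Convergence is checked with [gelman_rubin()] and a
#' warning is issued above 1.1.
#'
#' @param fit A `calibration_fit`.
#' @param rhat_warn Threshold for the convergence warning.
#' @return A `dic_result` with the R-hat vector attached as attribute `rhat`.
#' @export
compute_dic <- function(fit, rhat_warn = 1.1) {
  stopifnot(inherits(fit, "calibration_fit"))
  devs <- unlist(lapply(fit$chains, function(ch) ch$deviance))
  if (!length(devs)) stop("empty chains")
  rhat <- NULL
  if (length(fit$chains) >= 2) {
    rhat <- gelman_rubin(fit$chains)
    if (max(rhat, na.rm = TRUE) > rhat_warn)
      warning(sprintf("chains may not have converged: max R-hat = %.3f",
                      max(rhat, na.rm = TRUE)))
  }
  draws <- do.call(rbind, lapply(fit$chains, function(ch) ch$draws))
  theta <- colMeans(draws)
  if (any(theta < fit$spec$lower | theta > fit$spec$upper)) {
    warning("posterior mean outside the prior bounds; projected")
    theta <- pmin(pmax(theta, fit$spec$lower), fit$spec$upper)
  }
  dev_at_mean <- -2 * fit$loglik(theta)
  out <- dic_from_deviances(devs, dev_at_mean)
  attr(out, "rhat") <- rhat
  attr(out, "variant") <- fit$variant
  out
}

#' Compare nested model variants by DIC
#'
#' @param dics Named list of `dic_result` objects ordered from the simplest to
#'   the most complex variant.
#' @return A list: `table` (variant, dic, delta versus the previous simpler
#'   variant, delta versus the best), `selected` (lowest DIC; ties go to the
#'   simplest variant) and `meaningful` (TRUE when the selected variant beats
#'   the runner-up by more than 10 DIC points).
#' @export
select_model <- function(dics) {
  if (length(dics) < 2) stop("need at least two variants to compare")
  if (is.null(names(dics))) names(dics) <- paste0("m", seq_along(dics))
  dic <- vapply(dics, function(d) d$dic, numeric(1))
  tab <- data.frame(
    variant = names(dics),
    dic = unname(dic),
    delta_vs_previous = c(NA, diff(unname(dic))),
    delta_vs_best = unname(dic - min(dic))
  )
  sel <- which(dic == min(dic))[1]   # tie-break: simplest
  margin <- if (length(dic) > 1) sort(dic)[2] - min(dic) else 0
  list(table = tab, selected = names(dics)[sel], meaningful = margin > 10)
}
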