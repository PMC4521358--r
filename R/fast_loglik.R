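# Fast likelihood path for MCMC. The general path
# (vector_to_params -> simulate_population -> extract_outcomes ->
# log_likelihood) builds user-facing objects on every call; inside a sampler
# that overhead dominates. make_loglik() therefore precomputes, once per
# calibration: index maps from the flat parameter vector into the hazard
# grids, the initial-population layout, and flat-index extraction plans for
# every target row. The closure then works purely on numeric arrays and the
# compiled stepping core. A consistency test keeps the two paths identical.

GP_RCONST <- log(0.95) / log(0.05)

# life expectancy at birth from a hazard vector (no data.frame plumbing);
# identical arithmetic to build_life_table()
e0_from_hazards <- function(h) {
  n <- length(h)
  lx <- c(1, cumprod(exp(-h)))
  Lx <- (lx[1:(n - 1)] + lx[2:n]) / 2
  term <- if (h[n] > 0) lx[n] / h[n] else lx[n]
  sum(Lx) + term
}

# flat indices into an [A, 2, 4] slice for ages `a_idx` (1-based), residence
# r_i (1..2, or 0 for both) and education e_i (1..4, or 0 for all)
slice_index <- function(a_idx, r_i, e_i, A) {
  rs <- if (r_i == 0) 1:2 else r_i
  es <- if (e_i == 0) 1:4 else e_i
  idx <- integer(0)
  for (e in es) for (r in rs)
    idx <- c(idx, a_idx + A * ((r - 1) + 2 * (e - 1)))
  idx
}

# extraction plan: everything needed to turn (pop_are, hdie, stored states)
# into the model-value vector for this target set
build_extract_plan <- function(targets, years_all, wave_years, A) {
  tg <- as.data.frame(targets)
  yi <- match(tg$year, years_all)
  if (anyNA(yi)) stop("target year outside trajectory: ",
                      paste(unique(tg$year[is.na(yi)]), collapse = ", "))
  n_trans <- length(years_all) - 1L
  cls <- tg$class
  ARE <- A * 8L
  plan <- list(n = nrow(tg), est = tg$estimate,
               sigma = pmax((tg$ci_high - tg$ci_low) / 3.92,
                            0.01 * abs(tg$estimate), 1e-8),
               calib = tg$calibration)
  rows <- which(cls == "population_size")
  plan$pop <- list(rows = rows,
                   idx = cbind(yi[rows], match(tg$residence[rows], RESIDENCES)))
  rows <- which(cls == "fertility")
  plan$fert <- list(rows = rows,
                    residence = tg$residence[rows],
                    education = tg$education[rows],
                    tmid = (tg$age_low[rows] + tg$age_high[rows] + 1) / 2,
                    year = tg$year[rows])
  rows <- which(cls == "mortality")
  if (length(rows) && any(yi[rows] > n_trans))
    stop("mortality target year has no transition hazards")
  if (length(rows)) {
    ix_list <- lapply(seq_along(rows), function(k) {
      s <- rows[k]
      ARE * (yi[s] - 1L) +
        slice_index((tg$age_low[s]:tg$age_high[s]) + 1L,
                    match(tg$residence[s], RESIDENCES), 0L, A)
    })
    len <- lengths(ix_list)
    ends <- cumsum(len)
    plan$mort <- list(rows = rows, big_ix = unlist(ix_list),
                      starts = c(1L, head(ends, -1L) + 1L), ends = ends,
                      len = len)
  } else plan$mort <- list(rows = integer(0))
  rows <- which(cls == "education")
  plan$edu <- list(rows = rows, t = yi[rows],
                   ix_num = lapply(rows, function(s)
                     slice_index((tg$age_low[s]:tg$age_high[s]) + 1L,
                                 match(tg$residence[s], RESIDENCES),
                                 match(tg$education[s], EDUCATIONS), A)),
                   ix_den = lapply(rows, function(s)
                     slice_index((tg$age_low[s]:tg$age_high[s]) + 1L,
                                 match(tg$residence[s], RESIDENCES), 0L, A)))
  rows <- which(cls == "migration")
  if (length(rows)) {
    mig <- mig_states()
    win_states <- list(
      `6y`   = which(!is.na(mig$ysm) & mig$ysm <= 5),
      `12y`  = which(!is.na(mig$ysm) & mig$ysm <= 11),
      `ever` = which(mig$direction != "none")
    )
    M <- nrow(mig)
    slot <- match(tg$year[rows], wave_years)
    if (anyNA(slot)) stop("no stored state at migration target year")
    win <- match(tg$window[rows], names(win_states))
    if (anyNA(win)) stop("unknown migration window: ",
                         paste(unique(tg$window[rows][is.na(win)]),
                               collapse = ", "))
    slice <- lapply(rows, function(s)
      slice_index((tg$age_low[s]:tg$age_high[s]) + 1L,
                  match(tg$residence[s], RESIDENCES),
                  match(tg$education[s], EDUCATIONS), A))
    plan$mig <- list(rows = rows, slot = slot, win = win, slice = slice)
  } else plan$mig <- list(rows = integer(0))
  rows <- which(cls == "life_expectancy_validation")
  if (length(rows) && any(yi[rows] > n_trans))
    stop("life-expectancy target year has no hazards")
  plan$le <- list(rows = rows, t = yi[rows],
                  r_i = ifelse(is.na(tg$residence[rows]) |
                                 tg$residence[rows] == "all", 0L,
                               match(tg$residence[rows], RESIDENCES)))
  known <- c("population_size", "fertility", "mortality", "education",
             "migration", "life_expectancy_validation")
  if (any(!cls %in% known))
    stop("unknown target class: ", paste(setdiff(cls, known), collapse = ", "))
  plan
}

# evaluate the model-value vector from raw simulation output
eval_extract_plan <- function(plan, pop_are, hdie, stored, A, Yp) {
  model <- numeric(plan$n)
  ARE <- A * 8L
  gsum <- function(x, starts, ends) {
    cs <- c(0, cumsum(x))
    cs[ends + 1L] - cs[starts]
  }
  if (length(plan$pop$rows)) {
    pv <- colSums(matrix(pop_are, A))
    dim(pv) <- c(2L, 4L, Yp)
    pop_yr <- pv[, 1L, ] + pv[, 2L, ] + pv[, 3L, ] + pv[, 4L, ]  # 2 x Yp
    model[plan$pop$rows] <- pop_yr[cbind(plan$pop$idx[, 2], plan$pop$idx[, 1])]
  }
  if (length(plan$mort$rows)) {
    w <- pop_are[plan$mort$big_ix]
    q <- 1 - exp(-hdie[plan$mort$big_ix])
    den <- gsum(w, plan$mort$starts, plan$mort$ends)
    num <- gsum(w * q, plan$mort$starts, plan$mort$ends)
    meanq <- gsum(q, plan$mort$starts, plan$mort$ends) / plan$mort$len
    model[plan$mort$rows] <- ifelse(den > 0, num / pmax(den, 1e-300), meanq)
  }
  if (length(plan$edu$rows)) {
    for (k in seq_along(plan$edu$rows)) {
      off <- ARE * (plan$edu$t[k] - 1L)
      den <- sum(pop_are[off + plan$edu$ix_den[[k]]])
      model[plan$edu$rows[k]] <- if (den > 0)
        sum(pop_are[off + plan$edu$ix_num[[k]]]) / den else 0.25
    }
  }
  if (length(plan$mig$rows)) {
    # `stored` carries the compiled core's per-wave window summaries:
    # columns all / moved within 6y / within 12y / ever, each [A, 2, 4]
    mp <- plan$mig
    for (k in seq_along(mp$rows)) {
      sm <- stored[[mp$slot[k]]]
      den <- sum(sm[mp$slice[[k]]])
      model[mp$rows[k]] <- if (den > 0)
        sum(sm[mp$slice[[k]] + ARE * mp$win[k]]) / den else 0
    }
  }
  if (length(plan$le$rows)) {
    for (k in seq_along(plan$le$rows)) {
      t <- plan$le$t[k]
      w_slice <- matrix(pop_are[(ARE * (t - 1L) + 1L):(ARE * t)], A)
      h_slice <- matrix(hdie[(ARE * (t - 1L) + 1L):(ARE * t)], A)
      cols <- if (plan$le$r_i[k] == 0L) 1:8 else seq(plan$le$r_i[k], 8L, by = 2L)
      w <- rowSums(w_slice[, cols, drop = FALSE])
      hw <- rowSums((w_slice * h_slice)[, cols, drop = FALSE])
      hbar <- hw / w
      hbar[w <= 0] <- 0
      model[plan$le$rows[k]] <- e0_from_hazards(hbar)
    }
  }
  model
}

# index maps from the flat free-parameter vector into the stratum grids;
# cells are ordered (residence fastest): (urban,E0), (rural,E0), (urban,E1)...
build_param_maps <- function(template, spec) {
  variant <- template$variant
  cells <- expand.grid(residence = RESIDENCES, education = EDUCATIONS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tag <- if (variant == "v1") cells$residence
         else paste0(cells$residence, "_", cells$education)
  m <- list(
    iF = match(paste0("fert_F_", tag), spec$name),
    ia = match(paste0("fert_a_", tag), spec$name),
    ib = match(paste0("fert_b_", tag), spec$name),
    itr = match("fert_trend", spec$name)
  )
  lc_tag <- as.vector(outer(RESIDENCES, CLUSTERS, paste, sep = "_"))  # r fastest
  m$ic <- matrix(match(paste0("lc_c_", lc_tag), spec$name), 2L)
  m$iby <- matrix(match(paste0("lc_byear_", lc_tag), spec$name), 2L)
  m$iba <- matrix(match(paste0("lc_bage_", lc_tag), spec$name), 2L)
  if (variant %in% c("v2", "v3")) {
    m$irr <- rbind(match(paste0("rr_urban_", EDUCATIONS[-1]), spec$name),
                   match(paste0("rr_rural_", EDUCATIONS[-1]), spec$name))
    m$ied <- rbind(match(paste0("edu_trend_urban_", EDUCATIONS), spec$name),
                   match(paste0("edu_trend_rural_", EDUCATIONS), spec$name))
  }
  if (variant == "v3") {
    m$imb <- match(paste0("mig_base_", EDUCATIONS), spec$name)
    m$imt <- match(paste0("mig_trend_", EDUCATIONS), spec$name)
  }
  stopifnot(!anyNA(unlist(m)))
  m
}

# the production likelihood closure used by calibrate(): numerically identical
# to log_likelihood(extract_outcomes(simulate_population(...), targets))
make_loglik <- function(template, targets, base_population, config) {
  spec <- param_spec(template$variant)
  maps <- build_param_maps(template, spec)
  A <- config$age_cap + 1L
  years_all <- config$start_year:config$end_year
  trans_years <- years_all[-length(years_all)]
  Y <- length(trans_years)
  Yp <- Y + 1L
  wave_years <- if (identical(config$store_states, "all")) years_all
                else if (identical(config$store_states, "none")) integer(0)
                else sort(as.integer(config$store_states))
  store_idx <- match(wave_years, years_all)
  plan <- build_extract_plan(targets, years_all, wave_years, A)
  # fertility target helper indices (into the cell order above)
  cells <- expand.grid(residence = RESIDENCES, education = EDUCATIONS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fcell <- if (template$variant == "v1")
    match(plan$fert$residence, RESIDENCES)
  else
    match(paste(plan$fert$residence, plan$fert$education),
          paste(cells$residence, cells$education))
  if (length(plan$fert$rows) && anyNA(fcell))
    stop("fertility stratum not resolvable in targets")
  # static pieces
  dy <- trans_years - config$start_year
  ages <- 0:config$age_cap
  cl_idx <- match(age_cluster(ages), CLUSTERS)
  ref_age <- c(0, 5, 60)[cl_idx]
  start_year <- config$start_year
  lc_ref_year <- template$lc$table$reference_year[1]
  fert_ref_year <- template$fertility$reference_year
  edu_ref_year <- template$edu$reference_year
  baselines <- rbind(template$edu$urban$baseline, template$edu$rural$baseline)
  mt <- template$migration$table
  mkey <- paste(mt$direction, mt$education)
  u2r_base <- mt$base_rate[match(paste("urban_to_rural", EDUCATIONS), mkey)]
  u2r_trend <- mt$trend[match(paste("urban_to_rural", EDUCATIONS), mkey)]
  r2u_base0 <- mt$base_rate[match(paste("rural_to_urban", EDUCATIONS), mkey)]
  r2u_trend0 <- mt$trend[match(paste("rural_to_urban", EDUCATIONS), mkey)]
  mig_ref_year <- template$migration$reference_year
  # base counts by age x residence
  cnt <- matrix(0, A, 2)
  for (r_i in 1:2) {
    sub <- base_population[base_population$residence == RESIDENCES[r_i], ]
    cnt[sub$age + 1L, r_i] <- sub$count
  }
  ff <- config$fraction_female
  M <- nrow(mig_states())
  tgrid <- c(ages, config$age_cap + 1L)
  est <- plan$est; sigma <- plan$sigma
  keep <- which(plan$calib)
  log_r <- log(GP_RCONST)
  # flat index maps for assembling the [A, 2, 4, Y] hazard grids from their
  # factorized pieces (enumeration order: a, r, e, y)
  eg <- expand.grid(a = seq_len(A), r = 1:2, e = 1:4, y = seq_len(Y),
                    KEEP.OUT.ATTRS = FALSE)
  ixb <- eg$a + A * (eg$r - 1L) + A * 2L * (eg$y - 1L)   # into B [A,2,Y]
  ixr <- eg$r + 2L * (eg$e - 1L)                          # into rr [2,4]
  ixd <- eg$a + A * (eg$r - 1L + 2L * (eg$e - 1L))        # into ds [A,8]
  ixf <- eg$y + Y * (eg$r - 1L + 2L * (eg$e - 1L))        # into Feff [Y,8]
  ixm <- eg$y + Y * (eg$r - 1L + 2L * (eg$e - 1L))        # into mrate [Y,2,4]
  hdim <- c(A, 2L, 4L, Y)
  dy_lc <- trans_years - lc_ref_year

  function(v) {
    # --- fertility schedules
    a8 <- v[maps$ia]; b8 <- v[maps$ib]; F8 <- v[maps$iF]; ftr <- v[maps$itr]
    if (any(a8 <= 0) || any(b8 <= 0) || any(F8 <= 0)) return(-Inf)
    S <- exp(log(0.5) * exp(sweep(outer(tgrid, a8, "-"), 2, b8, "/") * log_r))
    ds <- pmax(S[-1, , drop = FALSE] - S[-nrow(S), , drop = FALSE], 0)  # A x 8
    Feff <- pmax(outer(dy, rep(ftr, 8), "*") +
                   matrix(F8, Y, 8, byrow = TRUE), 0)           # Y x 8
    # --- mortality: reference-category surface x relative risks
    rr <- matrix(1, 2, 4)
    if (!is.null(maps$irr)) rr[, 2:4] <- v[maps$irr]
    if (any(rr <= 0)) return(-Inf)
    av <- as.vector(rbind(v[maps$ic[1, ]][cl_idx] +
                            v[maps$iba[1, ]][cl_idx] * (ages - ref_age),
                          v[maps$ic[2, ]][cl_idx] +
                            v[maps$iba[2, ]][cl_idx] * (ages - ref_age)))
    av <- matrix(av, nrow = 2)                  # 2 x A (r fastest when flat)
    bv <- rbind(v[maps$iby[1, ]][cl_idx], v[maps$iby[2, ]][cl_idx])
    Bv <- exp(rep(as.vector(t(av)), Y) +
                rep(as.vector(t(bv)), Y) * rep(dy_lc, each = 2L * A))
    hdie <- Bv[ixb] * as.vector(rr)[ixr]
    # --- migration schedules
    if (!is.null(maps$imb)) {
      r2u <- pmin(pmax(outer(trans_years - mig_ref_year, v[maps$imt]) +
                         matrix(v[maps$imb], Y, 4, byrow = TRUE), 0), 1)
    } else {
      r2u <- pmin(pmax(outer(trans_years - mig_ref_year, r2u_trend0) +
                         matrix(r2u_base0, Y, 4, byrow = TRUE), 0), 1)
    }
    u2r <- pmin(pmax(outer(trans_years - mig_ref_year, u2r_trend) +
                       matrix(u2r_base, Y, 4, byrow = TRUE), 0), 1)
    mrate <- array(0, dim = c(Y, 2L, 4L))
    mrate[, 1L, ] <- u2r
    mrate[, 2L, ] <- r2u
    hmove <- as.vector(mrate)[ixm]
    fert <- as.vector(ds)[ixd] * as.vector(Feff)[ixf]
    # --- competing risks
    H <- hdie + hmove
    frac <- -expm1(-H) / pmax(H, .Machine$double.xmin)
    frac[H <= 0] <- 0
    pdie <- hdie * frac
    pmove <- hmove * frac
    dim(pdie) <- hdim; dim(pmove) <- hdim; dim(fert) <- hdim
    # --- newborn education by birth year
    etr <- if (!is.null(maps$ied)) rbind(v[maps$ied[1, ]], v[maps$ied[2, ]])
           else matrix(0, 2, 4)
    nb_edu <- array(0, dim = c(4, 2, Y))
    for (r_i in 1:2) {
      V <- pmax(baselines[r_i, ] +
                  outer(etr[r_i, ], trans_years - edu_ref_year), 0)
      s <- colSums(V)
      bad <- s <= 0
      if (any(bad)) { V[4, bad] <- 1; s[bad] <- 1 }
      nb_edu[, r_i, ] <- V * rep(1 / s, each = 4)
    }
    # --- initial state (education split of pre-simulation cohorts follows the
    #     same birth-year distribution)
    counts <- array(0, dim = c(A, 2, 4, M))
    for (r_i in 1:2) {
      V <- pmax(baselines[r_i, ] +
                  outer(etr[r_i, ], start_year - ages - edu_ref_year), 0)
      s <- colSums(V)
      bad <- s <= 0
      if (any(bad)) { V[4, bad] <- 1; s[bad] <- 1 }
      counts[, r_i, , 1L] <- cnt[, r_i] * t(V * rep(1 / s, each = 4))
    }
    res <- cpp_run_sim(counts, pdie, pmove, fert, nb_edu, ff, FALSE,
                       as.integer(store_idx))
    dim(hdie) <- hdim
    model <- eval_extract_plan(plan, res$pop_are, hdie, res$stored_sums, A, Yp)
    if (length(plan$fert$rows)) {
      Ft <- pmax(F8[fcell] + ftr * (plan$fert$year - fert_ref_year), 0)
      model[plan$fert$rows] <- Ft *
        exp(log(0.5) * exp((plan$fert$tmid - a8[fcell]) / b8[fcell] * log_r))
    }
    ll <- sum(dnorm(est[keep], model[keep], sigma[keep], log = TRUE))
    if (!is.finite(ll)) -Inf else ll
  }
}
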