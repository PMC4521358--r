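# Competing risks, the annual stepping engine, and outcome extraction.

test_that("competing-risk probabilities match the closed form and sum to 1", {
  p <- competing_risk_probabilities(c(death = 0.01, move = 0.02))
  expect_equal(unname(p["death"]), 0.0098515, tolerance = 1e-5)
  expect_equal(unname(p["move"]), 0.0197030, tolerance = 1e-5)
  expect_equal(unname(p["survive"]), 0.9704455, tolerance = 1e-5)
  expect_identical(sum(p), 1)
  expect_equal(competing_risk_probabilities(c(0, 0)), c(0, 0, survive = 1),
               ignore_attr = TRUE)
  mu <- 0.3
  expect_equal(unname(competing_risk_probabilities(mu)[1]), 1 - exp(-mu))
  expect_error(competing_risk_probabilities(c(-0.1, 0.2)), "non-negative")
})

test_that("competing-risk split matches a continuous-time simulation oracle", {
  # exponential clocks: first event decides the outcome
  set.seed(12)
  n <- 2e5
  t_death <- rexp(n, 0.01)
  t_move <- rexp(n, 0.02)
  death <- t_death < 1 & t_death < t_move
  move <- t_move < 1 & t_move <= t_death
  p <- competing_risk_probabilities(c(0.01, 0.02))
  se <- sqrt(p[1] * (1 - p[1]) / n)
  expect_lt(abs(mean(death) - p[1]), 4 * se)
  expect_lt(abs(mean(move) - p[2]), 4 * sqrt(p[2] * (1 - p[2]) / n))
})

test_that("with all hazards and fertility zero the population just ages", {
  p <- toy_params("v3")
  p$fertility$table$F <- 1e-12
  p$lc$table$c <- -60
  p$migration$table$base_rate <- 0
  lv <- stratum_levels()
  arr <- array(0, dim = c(111, 2, 4, nrow(lv$mig)))
  arr[21, 1, 2, 1] <- 50
  arr[61, 2, 4, 1] <- 70
  st <- population_state(arr, 2000)
  nxt <- step_year(st, p, simulation_config(2000, 2001))
  expect_equal(nxt$year, 2001L)
  expect_equal(nxt$counts[22, 1, 2, 1], 50, tolerance = 1e-9)
  expect_equal(nxt$counts[62, 2, 4, 1], 70, tolerance = 1e-9)
  expect_equal(total_population(nxt), 120, tolerance = 1e-9)
})

test_that("annual bookkeeping holds in expected-value and stochastic modes", {
  p <- toy_params("v3")
  base <- toy_base_population(20000)
  cfg <- simulation_config(2000, 2015, store_states = "none")
  traj <- simulate_population(p, base, cfg)
  totals <- unname(rowSums(traj$pop_year_res))
  for (t in seq_len(nrow(traj$tallies))) {
    expect_equal(totals[t + 1],
                 totals[t] - traj$tallies$deaths[t] + traj$tallies$births[t],
                 tolerance = 1e-9)
  }
  expect_true(all(traj$pop_are >= 0))
  # stochastic: the identity holds exactly in integers
  cfg_s <- simulation_config(2000, 2015, mode = "stochastic", seed = 99,
                             store_states = "none")
  base_int <- base
  base_int$count <- round(base_int$count)
  traj_s <- simulate_population(p, base_int, cfg_s)
  tot_s <- unname(rowSums(traj_s$pop_year_res))
  for (t in seq_len(nrow(traj_s$tallies))) {
    expect_identical(tot_s[t + 1],
                     tot_s[t] - traj_s$tallies$deaths[t] + traj_s$tallies$births[t])
  }
  expect_true(all(traj_s$pop_are == round(traj_s$pop_are)))
})

test_that("simulation is reproducible and respects the trajectory contract", {
  p <- toy_params("v3")
  base <- toy_base_population(5000)
  base$count <- round(base$count)
  cfg <- simulation_config(2000, 2010, mode = "stochastic", seed = 7)
  t1 <- simulate_population(p, base, cfg)
  t2 <- simulate_population(p, base, cfg)
  expect_identical(t1$pop_year_res, t2$pop_year_res)
  expect_identical(t1$tallies, t2$tallies)
  # zero-length horizon: a single state, no transitions
  cfg0 <- simulation_config(2000, 2000)
  t0 <- simulate_population(p, toy_base_population(5000), cfg0)
  expect_equal(length(t0$years), 1L)
  expect_equal(nrow(t0$tallies), 0L)
})

test_that("pure rural-to-urban migration follows the geometric closed form", {
  p <- toy_params("v3")
  p$fertility$table$F <- 1e-12
  p$lc$table$c <- -60
  m <- 0.03
  p$migration$table$base_rate <-
    ifelse(p$migration$table$direction == "rural_to_urban", m, 0)
  p$migration$table$trend <- 0
  base <- toy_base_population(10000, urban_share = 0)
  cfg <- simulation_config(2000, 2020, store_states = "none")
  traj <- simulate_population(p, base, cfg)
  pmove <- 1 - exp(-m)
  t <- seq_along(traj$years) - 1
  expected_urban_share <- 1 - (1 - pmove)^t
  got <- traj$pop_year_res[, "urban"] / rowSums(traj$pop_year_res)
  expect_equal(unname(got), expected_urban_share, tolerance = 1e-9)
})

test_that("nested variants reproduce v1 when extra components are neutralized", {
  p1 <- toy_params("v1")
  # v2/v3 with education-invariant fertility, unit RRs, zero migration and
  # zero education trends
  neutral <- function(variant) {
    p <- toy_params(variant)
    ft <- p$fertility$table
    for (res in c("urban", "rural")) {
      i <- ft$residence == res
      j <- p1$fertility$table$residence == res
      ft$F[i] <- p1$fertility$table$F[j]
      ft$a[i] <- p1$fertility$table$a[j]
      ft$b[i] <- p1$fertility$table$b[j]
    }
    ft$trend_F <- p1$fertility$table$trend_F[1]
    p$fertility$table <- ft
    p$rr <- unit_rr()
    p$migration$table$base_rate <- 0
    p$migration$table$trend <- 0
    p$edu$urban$trend <- rep(0, 4)
    p$edu$rural$trend <- rep(0, 4)
    p$edu$urban$baseline <- p1$edu$urban$baseline
    p$edu$rural$baseline <- p1$edu$rural$baseline
    p$edu$reference_year <- p1$edu$reference_year
    p
  }
  base <- toy_base_population(20000)
  cfg <- simulation_config(2000, 2015, store_states = "none")
  ref <- simulate_population(p1, base, cfg)$pop_year_res
  for (variant in c("v2", "v3")) {
    got <- simulate_population(neutral(variant), base, cfg)$pop_year_res
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("extract_outcomes answers each target class correctly", {
  # single-stratum constant-hazard construction with known answers
  p <- toy_params("v3")
  p$fertility$table$F <- 1e-12
  p$fertility$table$trend_F <- 0   # keep a trickle of births at every age
  p$migration$table$base_rate <- 0
  # flat hazard 0.02 at every age: set both slopes to 0
  p$lc$table$c <- log(0.02)
  p$lc$table$beta_year <- 0
  p$lc$table$beta_age <- 0
  p$rr <- unit_rr()
  lv <- stratum_levels()
  arr <- array(0, dim = c(111, 2, 4, nrow(lv$mig)))
  arr[, 2, 3, 1] <- 100   # all rural, E2
  st <- population_state(arr, 2000)
  cfg <- simulation_config(2000, 2005, store_states = "all")
  traj <- simulate_population(p, st, cfg)
  tg <- target_set(data.frame(
    class = c("mortality", "education", "education", "population_size",
              "life_expectancy_validation"),
    year = c(2002, 2002, 2002, 2000, 2002),
    age_low = c(30, 20, 20, NA, NA), age_high = c(44, 24, 24, NA, NA),
    residence = c("rural", "rural", "rural", "rural", "all"),
    education = c(NA, "E2", "E0", NA, NA),
    window = NA, estimate = c(0.02, 1, 0, 100 * 111, 50),
    ci_low = c(0.01, 0.9, 0, 1, 45), ci_high = c(0.03, 1, 0.1, 1e9, 55),
    calibration = TRUE))
  out <- extract_outcomes(traj, tg)
  expect_equal(out$model[1], 1 - exp(-0.02), tolerance = 1e-9)
  expect_equal(out$model[2], 1)   # all mass in E2
  expect_equal(out$model[3], 0)
  expect_equal(out$model[4], total_population(st, "rural"))
  expect_equal(out$model[5], life_expectancy(build_life_table(rep(0.02, 111))),
               tolerance = 1e-9)
  expect_error(extract_outcomes(traj, target_set(data.frame(
    class = "population_size", year = 2050, age_low = NA, age_high = NA,
    residence = "rural", education = NA, window = NA,
    estimate = 1, ci_low = 0.5, ci_high = 2, calibration = TRUE))),
    "outside trajectory")
})

test_that("the fast calibration likelihood equals the reference path", {
  g <- fixture_generated()
  cfg <- simulation_config(1992, 2008, store_states = c(1993, 1999, 2006))
  set.seed(31)
  for (variant in c("v1", "v2", "v3")) {
    tmpl <- demogsim:::build_template(variant, g$targets, 1992)
    spec <- demogsim:::param_spec(variant)
    fast <- demogsim:::make_loglik(tmpl, g$targets, g$base_population, cfg)
    ref <- demogsim:::reference_loglik(tmpl, g$targets, g$base_population, cfg)
    for (i in 1:3) {
      v <- demogsim:::init_from_targets(tmpl, g$targets, spec) +
        0.01 * (spec$upper - spec$lower) * rnorm(nrow(spec))
      v <- pmin(pmax(v, spec$lower), spec$upper)
      names(v) <- spec$name
      expect_equal(fast(v), ref(v), tolerance = 1e-9)
    }
  }
})
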