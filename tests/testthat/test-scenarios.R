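# Static comparator, education intervention, and difference-in-differences.

test_that("make_static freezes trends at start-year levels and is idempotent", {
  p <- toy_params("v3")
  p$migration$table$trend <- ifelse(
    p$migration$table$direction == "rural_to_urban", 2e-4, 0)
  s <- make_static(p, 2005)
  expect_equal(s$fertility$table$trend_F, rep(0, 8))
  expect_true(all(s$lc$table$beta_year == 0))
  expect_true(all(s$migration$table$trend == 0))
  expect_equal(s$edu$urban$trend, rep(0, 4))
  # effective levels at the freeze year match the dynamic model
  for (res in c("urban", "rural")) {
    expect_equal(total_fertility_rate(s$fertility, 2005, res, "E1"),
                 total_fertility_rate(p$fertility, 2005, res, "E1"),
                 tolerance = 1e-9)
    expect_equal(lee_carter_rate(s$lc, 30, 2005, res),
                 lee_carter_rate(p$lc, 30, 2005, res), tolerance = 1e-12)
  }
  expect_equal(migration_hazard(s$migration, "rural_to_urban", "E2", 2005),
               migration_hazard(p$migration, "rural_to_urban", "E2", 2005))
  expect_equal(newborn_education_distribution(s$edu, 2005, "rural"),
               newborn_education_distribution(p$edu, 2005, "rural"),
               tolerance = 1e-12)
  # idempotent
  expect_equal(make_static(s, 2005), s)
  # a zero-length simulation cannot see the trends: states identical
  base <- toy_base_population(3000)
  cfg0 <- simulation_config(2005, 2005)
  init <- expand_initial_population(base, p, 2005)
  t_dyn <- simulate_population(p, init, cfg0)
  t_st <- simulate_population(s, init, cfg0)
  expect_equal(t_st$pop_year_res, t_dyn$pop_year_res, tolerance = 1e-12)
})

test_that("the static comparator overestimates population and underestimates life expectancy under declining trends", {
  scen <- make_truth("full_effects", seed = 3)
  base <- synth_base_population(scen)
  cfg <- simulation_config(1992, 2012, store_states = "none")
  res <- run_four_arms(scen$params, base, cfg, intervention_year = 2050)
  dyn <- res$trajectories$dynamic_base
  st <- res$trajectories$static_base
  n <- length(dyn$years)
  # declining fertility: the frozen model projects more people at the horizon
  expect_gt(sum(st$pop_year_res[n, ]), sum(dyn$pop_year_res[n, ]))
  # declining mortality: the frozen model projects lower life expectancy
  le_dyn <- res$le$dynamic_base
  le_st <- res$le$static_base
  expect_true(all(le_st[-1] <= le_dyn[-1]))
})

test_that("the primary-education intervention moves rural E0 mass to E1 at birth", {
  p <- toy_params("v3")
  p$edu$rural$baseline <- c(0.4, 0.2, 0.3, 0.1)
  p$edu$rural$trend <- rep(0, 4)
  pi <- apply_primary_education_intervention(p, 2000)
  d <- demogsim:::newborn_distribution_with_intervention(pi, 2003, "rural")
  expect_equal(d, c(0, 0.6, 0.3, 0.1))
  # urban distributions unchanged
  expect_equal(demogsim:::newborn_distribution_with_intervention(pi, 2003, "urban"),
               newborn_education_distribution(p$edu, 2003, "urban"))
  # cohorts born before the intervention unchanged
  expect_equal(demogsim:::newborn_distribution_with_intervention(pi, 1999, "rural"),
               newborn_education_distribution(p$edu, 1999, "rural"))
})

test_that("a beneficial intervention yields non-negative incremental life expectancy in both arms", {
  scen <- make_truth("full_effects", seed = 4)
  base <- synth_base_population(scen)
  cfg <- simulation_config(1992, 2015, store_states = "none")
  res <- run_four_arms(scen$params, base, cfg, intervention_year = 2000)
  inc_dyn <- res$le$dynamic_intervention - res$le$dynamic_base
  inc_st <- res$le$static_intervention - res$le$static_base
  expect_true(all(inc_dyn >= -1e-9))
  expect_true(all(inc_st >= -1e-9))
  # the effect only begins with cohorts born in the intervention year
  expect_equal(inc_dyn[as.character(1992:1999)],
               setNames(rep(0, 8), 1992:1999), tolerance = 1e-12)
  expect_gt(inc_dyn[length(inc_dyn)], 0)
})

test_that("difference-in-differences is exactly zero for null contrasts", {
  yrs <- 2000:2010
  le <- matrix(rnorm(11 * 20, 65), 20, 11, dimnames = list(NULL, yrs))
  # identical arms in all four slots
  dd <- diff_in_diff_life_expectancy(list(base = le, intervention = le),
                                     list(base = le, intervention = le))
  expect_true(all(dd$median == 0 & dd$ci_low == 0 & dd$ci_high == 0))
  # dynamic pair equal to static pair: differences cancel
  le2 <- le + 1
  dd2 <- diff_in_diff_life_expectancy(list(base = le, intervention = le2),
                                      list(base = le, intervention = le2))
  expect_true(all(abs(dd2$median) < 1e-12))
  expect_error(diff_in_diff_life_expectancy(
    list(base = le, intervention = le),
    list(base = le[, 1:5], intervention = le[, 1:5])), "mismatch")
})

test_that("common random numbers give a zero-effect intervention exactly zero difference", {
  p <- toy_params("v3")
  base <- toy_base_population(4000)
  base$count <- round(base$count)
  cfg <- simulation_config(2000, 2010, mode = "stochastic", seed = 17,
                          store_states = "none")
  # an intervention after the horizon can change nothing
  res <- run_four_arms(p, base, cfg, intervention_year = 2100)
  expect_identical(res$trajectories$dynamic_base$pop_year_res,
                   res$trajectories$dynamic_intervention$pop_year_res)
  expect_identical(res$le$dynamic_base, res$le$dynamic_intervention)
  expect_identical(res$le$static_base, res$le$static_intervention)
})
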