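# Truth scenarios, target generation, and the recovery report.

test_that("scenarios encode their qualitative structure", {
  full <- make_truth("full_effects")
  # relative risk of death declines monotonically with education
  for (res in c("urban", "rural"))
    expect_true(all(diff(full$params$rr[res, ]) < 0))
  expect_lt(full$params$fertility$table$trend_F[1], 0)
  expect_true(all(full$params$lc$table$beta_year < 0))
  r2u <- full$params$migration$table
  r2u <- r2u[r2u$direction == "rural_to_urban", ]
  expect_true(all(diff(r2u$base_rate[match(c("E0", "E1", "E2", "E3"),
                                           r2u$education)]) > 0))

  noedu <- make_truth("no_education_effects")
  expect_true(all(noedu$params$rr == 1))
  for (res in c("urban", "rural")) {
    expect_equal(length(unique(noedu$params$fertility$table$F[
      noedu$params$fertility$table$residence == res])), 1L)
    expect_equal(noedu$params$edu[[res]]$trend, rep(0, 4))
  }

  nomig <- make_truth("no_migration")
  expect_true(all(nomig$params$migration$table$base_rate == 0))

  static <- make_truth("static")
  expect_equal(static$params$fertility$table$trend_F, rep(0, 8))
  expect_true(all(static$params$lc$table$beta_year == 0))
  expect_true(all(static$params$migration$table$trend == 0))
  expect_equal(static$params$edu$urban$trend, rep(0, 4))

  expect_error(make_truth("bogus"))
})

test_that("generation is reproducible bit-for-bit from (scenario, seed)", {
  g1 <- suppressWarnings(generate_targets(make_truth("full_effects", seed = 9)))
  g2 <- suppressWarnings(generate_targets(make_truth("full_effects", seed = 9)))
  expect_identical(g1$targets$estimate, g2$targets$estimate)
  g3 <- suppressWarnings(generate_targets(make_truth("full_effects", seed = 10)))
  expect_false(identical(g1$targets$estimate, g3$targets$estimate))
})

test_that("zero-noise targets equal the truth outcomes exactly", {
  g0 <- fixture_generated(noise = 0)
  expect_equal(g0$targets$estimate[g0$targets$calibration],
               g0$truth_outcomes$truth[g0$targets$calibration],
               tolerance = 1e-12)
  # and pass validation cleanly when rewritten and reloaded
  dir <- tempfile()
  write_targets(g0$targets, dir)
  expect_no_warning(load_targets(dir))
  unlink(dir, recursive = TRUE)
})

test_that("generated confidence intervals cover the truth at their nominal rate", {
  # mortality + population rows across several seeds give >1000 draws
  hits <- c(); n <- 0
  for (seed in 1:4) {
    g <- suppressWarnings(
      generate_targets(make_truth("full_effects", seed = seed)))
    tr <- g$truth_outcomes$truth
    keep <- g$targets$calibration
    hits <- c(hits, tr[keep] >= g$targets$ci_low[keep] &
                tr[keep] <= g$targets$ci_high[keep])
  }
  # truncation at zero slightly inflates coverage for near-zero rows
  expect_gt(length(hits), 1000)
  expect_equal(mean(hits), 0.95, tolerance = 0.025)
})

test_that("migration lookback windows nest for every stratum", {
  g <- fixture_generated()
  mg <- g$targets[g$targets$class == "migration", ]
  key <- paste(mg$year, mg$residence, mg$education)
  tr <- g$truth_outcomes
  trm <- tr[tr$class == "migration", ]
  for (u in unique(key)) {
    sub <- trm[paste(trm$year, trm$residence, trm$education) == u, ]
    p <- sub$truth[match(c("6y", "12y", "ever"), sub$window)]
    expect_true(p[1] <= p[2] + 1e-12 && p[2] <= p[3] + 1e-12)
  }
})

test_that("recovery_report scores coverage against the truth", {
  scen <- make_truth("full_effects", seed = 1)
  spec <- demogsim:::param_spec("v3")
  truth_v <- params_to_vector(scen$params)[spec$name]
  # a point-mass chain at the truth: full coverage, zero error
  mk_chain <- function(center, sd) {
    draws <- matrix(rep(center, each = 50), 50, length(center),
                    dimnames = list(NULL, names(center)))
    if (sd > 0) draws <- draws + rnorm(length(draws), 0, sd)
    structure(list(draws = draws, deviance = rep(1, 50)),
              class = "mcmc_chain")
  }
  set.seed(8)
  rep0 <- recovery_report(list(mk_chain(truth_v, 1e-9)), scen)
  expect_equal(rep0$coverage, 1)
  expect_true(all(abs(rep0$table$rel_error) < 1e-6, na.rm = TRUE))
  # a chain shifted far from the truth misses it
  shifted <- truth_v + 10
  rep1 <- recovery_report(list(mk_chain(shifted, 0.001)), scen)
  expect_equal(rep1$coverage, 0)
  # wrong parameter names are rejected
  bad <- mk_chain(c(nonsense_param = 1), 0.001)
  expect_error(recovery_report(list(bad), scen), "mismatch")
})
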