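# Target schema, CSV round trip, and the Gaussian calibration likelihood.

test_that("log-likelihood matches the Normal density formula", {
  tg <- target_set(data.frame(
    class = "population_size", year = 2000, age_low = NA, age_high = NA,
    residence = "urban", education = NA, window = NA,
    estimate = 100, ci_low = 100 - 1.96 * 10, ci_high = 100 + 1.96 * 10,
    calibration = TRUE))
  # sigma = (ci width)/3.92 = 10; exact hit gives -ln(10 sqrt(2 pi))
  expect_equal(log_likelihood(tg, model = 100), -log(10 * sqrt(2 * pi)),
               tolerance = 1e-5)
  expect_equal(log_likelihood(tg, model = 100), -3.22154, tolerance = 1e-5)
  # one sigma off costs exactly half a squared unit
  expect_equal(log_likelihood(tg, model = 110),
               log_likelihood(tg, model = 100) - 0.5, tolerance = 1e-9)
  expect_equal(log_likelihood(tg, model = 110), -3.72154, tolerance = 1e-5)
  # additivity: doubling the rows doubles the contribution
  tg2 <- target_set(rbind(tg, tg))
  expect_equal(log_likelihood(tg2, model = c(110, 110)),
               2 * log_likelihood(tg, model = 110), tolerance = 1e-9)
  expect_error(log_likelihood(tg, model = c(1, 2)), "misaligned")
})

test_that("likelihood is invariant to row order and maximized at zero residual", {
  g <- fixture_generated()
  out <- extract_outcomes(
    simulate_population(g$truth, g$base_population,
                        simulation_config(1992, 2008,
                                          store_states = c(1993, 1999, 2006))),
    g$targets)
  ll <- log_likelihood(out)
  perm <- sample(nrow(out))
  expect_equal(log_likelihood(out[perm, ]), ll, tolerance = 1e-9)
  # on zero-noise targets the truth is the global optimum: any perturbation
  # of the model values lowers the likelihood
  g0 <- fixture_generated(noise = 0)
  out0 <- extract_outcomes(
    simulate_population(g0$truth, g0$base_population,
                        simulation_config(1992, 2008,
                                          store_states = c(1993, 1999, 2006))),
    g0$targets)
  expect_equal(out0$model[out0$calibration], out0$estimate[out0$calibration],
               tolerance = 1e-9)
  ll0 <- log_likelihood(out0)
  set.seed(2)
  for (i in 1:5) {
    pert <- out0
    pert$model <- pert$model * (1 + rnorm(nrow(pert), 0, 0.01))
    expect_lt(log_likelihood(pert), ll0)
  }
})

test_that("deviance is minus twice the log-likelihood", {
  expect_equal(deviance_from_loglik(-3.22154), 6.44308)
  expect_equal(deviance_from_loglik(0), 0)
  # additive over independent blocks
  expect_equal(deviance_from_loglik(-1.5 + -2.5),
               deviance_from_loglik(-1.5) + deviance_from_loglik(-2.5))
  expect_error(deviance_from_loglik(-Inf), "finite")
})

test_that("targets round-trip through the manifest + CSV dialects", {
  g <- fixture_generated()
  dir <- tempfile()
  write_targets(g$targets, dir)
  # loading reports no warnings and preserves every row
  expect_no_warning(tg2 <- load_targets(dir))
  expect_equal(nrow(tg2), nrow(g$targets))
  for (cl in unique(g$targets$class)) {
    a <- g$targets[g$targets$class == cl, ]
    b <- tg2[tg2$class == cl, ]
    expect_equal(nrow(b), nrow(a))
    expect_equal(sort(b$estimate), sort(a$estimate), tolerance = 1e-9)
  }
  # validation rows keep their non-calibration flag
  expect_true(all(!tg2$calibration[tg2$class == "life_expectancy_validation"]))
  unlink(dir, recursive = TRUE)
})

test_that("malformed target files are rejected with located diagnostics", {
  dir <- tempfile(); dir.create(dir)
  write.csv(data.frame(year = 2000, residence = "urban",
                       population = 50, ci_low = 60, ci_high = 70),
            file.path(dir, "population_size.csv"), row.names = FALSE)
  yaml::write_yaml(list(targets = list(list(class = "population_size",
                                            file = "population_size.csv"))),
                   file.path(dir, "manifest.yaml"))
  expect_error(load_targets(dir), "CI inversion.*2")
  yaml::write_yaml(list(targets = list(list(class = "bogus",
                                            file = "population_size.csv"))),
                   file.path(dir, "manifest.yaml"))
  expect_error(load_targets(dir), "unknown target class")
  # empty manifest gives an empty, valid target set
  yaml::write_yaml(list(targets = list()), file.path(dir, "manifest.yaml"))
  expect_equal(nrow(load_targets(dir)), 0L)
  unlink(dir, recursive = TRUE)
  expect_error(target_set(data.frame(
    class = "education", year = c(2000, 2000, 2000, 2000),
    age_low = 20, age_high = 24, residence = "urban",
    education = c("E0", "E1", "E2", "E3"), window = NA,
    estimate = c(0.5, 0.5, 0.5, 0.5), ci_low = 0.4, ci_high = 0.6,
    calibration = TRUE)), "simplex")
})
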