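# Sampler correctness on conjugate toys, convergence diagnostics, DIC, and
# model selection.

test_that("the sampler recovers a conjugate-normal posterior", {
  # data y ~ N(theta, s^2), flat prior on a wide interval: posterior is
  # N(ybar, s^2/n)
  set.seed(14)
  n <- 25; s <- 2
  y <- rnorm(n, 3, s)
  loglik <- function(theta) sum(dnorm(y, theta, s, log = TRUE))
  ch <- mcmc_sample(loglik, init = c(theta = 0), lower = -50, upper = 50,
                    n_iter = 60000, burn_in = 10000, seed = 5)
  post_mean <- mean(ch$draws[, 1])
  post_sd_true <- s / sqrt(n)
  # Monte Carlo error allowing for autocorrelation of the walk
  ess <- nrow(ch$draws) / (2 * 30)
  mcse <- post_sd_true / sqrt(ess)
  expect_lt(abs(post_mean - mean(y)), 3 * mcse)
  expect_equal(sd(ch$draws[, 1]), post_sd_true, tolerance = 0.15)
  expect_gt(ch$acceptance[1], 0.1)
  expect_lt(ch$acceptance[1], 0.6)
})

test_that("sampler contracts: bounds, reproducibility, validation", {
  loglik <- function(theta) -0.5 * sum(theta^2)
  expect_error(mcmc_sample(loglik, c(a = 0), -1, 1, n_iter = 100,
                           burn_in = 100), "exceed")
  ch1 <- mcmc_sample(loglik, c(a = 0, b = 0), -3, 3, n_iter = 2000,
                     burn_in = 500, seed = 11)
  ch2 <- mcmc_sample(loglik, c(a = 0, b = 0), -3, 3, n_iter = 2000,
                     burn_in = 500, seed = 11)
  expect_identical(ch1$draws, ch2$draws)
  expect_true(all(ch1$draws >= -3 & ch1$draws <= 3))
  expect_error(mcmc_sample(loglik, c(a = 5), -1, 1, 100, 10), "bounds")
  expect_error(mcmc_sample(function(v) -Inf, c(a = 0), -1, 1, 100, 10),
               "non-finite")
})

test_that("gelman_rubin separates diverged chains and passes matched ones", {
  set.seed(21)
  make_chain <- function(center) {
    structure(list(draws = matrix(rnorm(4000, center), ncol = 1,
                                  dimnames = list(NULL, "x"))),
              class = "mcmc_chain")
  }
  same <- gelman_rubin(list(make_chain(0), make_chain(0), make_chain(0)))
  expect_lt(same["x"], 1.05)
  apart <- gelman_rubin(list(make_chain(0), make_chain(100)))
  expect_gt(apart["x"], 10)
  expect_error(gelman_rubin(list(make_chain(0))), "two chains")
  short <- structure(list(draws = matrix(1, 1, 1)), class = "mcmc_chain")
  expect_error(gelman_rubin(list(short, short)), "length")
})

test_that("DIC decomposition follows the Spiegelhalter formulas", {
  d <- dic_from_deviances(c(10, 12, 14), 9)
  expect_equal(d$mean_deviance, 12)
  expect_equal(d$p_d, 3)
  expect_equal(d$dic, 15)
  # a point-mass posterior has no effective parameters
  d0 <- dic_from_deviances(rep(7.5, 100), 7.5)
  expect_equal(d0$p_d, 0)
  expect_equal(d0$dic, 7.5)
  expect_error(dic_from_deviances(numeric(0), 1), "empty")
})

test_that("p_D approximates the free parameter count on a Gaussian toy", {
  # k independent mean parameters with diffuse priors: p_D ~ k
  set.seed(33)
  k <- 5; n <- 20; s <- 1
  y <- matrix(rnorm(k * n, rep(1:k, each = n), s), n, k)
  ybar <- colMeans(y)
  loglik <- function(theta) sum(dnorm(y, rep(theta, each = n), s, log = TRUE))
  init <- ybar
  names(init) <- paste0("m", 1:k)
  ch <- mcmc_sample(loglik, init, lower = -50, upper = 50,
                    n_iter = 110000, burn_in = 10000,
                    blocks = as.list(1:k), seed = 3)
  theta_bar <- colMeans(ch$draws)
  dic <- dic_from_deviances(ch$deviance, -2 * loglik(theta_bar))
  expect_equal(dic$p_d, k, tolerance = 0.5 / k)
})

test_that("select_model reproduces the nested-comparison table logic", {
  D <- 1000
  mk <- function(d) structure(list(mean_deviance = d, p_d = 0,
                                   deviance_at_posterior_mean = d, dic = d),
                              class = "dic_result")
  sel <- select_model(list(v1 = mk(D), v2 = mk(D + 5.2),
                           v3 = mk(D + 5.2 - 259.1)))
  expect_equal(sel$table$delta_vs_previous, c(NA, 5.2, -259.1))
  expect_equal(sel$selected, "v3")
  expect_true(sel$meaningful)
  # exact ties go to the simplest variant and are not meaningful
  tie <- select_model(list(v1 = mk(D), v2 = mk(D)))
  expect_equal(tie$selected, "v1")
  expect_false(tie$meaningful)
  # a 4-point winner is selected but not a meaningful margin
  close <- select_model(list(v1 = mk(D), v2 = mk(D - 4)))
  expect_equal(close$selected, "v2")
  expect_false(close$meaningful)
  expect_error(select_model(list(mk(D))), "at least two")
})
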