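# Population container, migration-state bookkeeping, and life-table utilities.

test_that("life table matches the constant-hazard closed form and a fine-step oracle", {
  lt <- build_life_table(rep(0.02, 111))
  # constant hazard mu: e0 = 1/mu in continuous time; discretization stays close
  expect_equal(life_expectancy(lt), 50.0, tolerance = 0.1 / 50)

  # fine-step numeric oracle: survival integrated on a daily grid
  oracle_e0 <- function(h) {
    dt <- 1 / 365
    tgrid <- seq(0, length(h), by = dt)
    hz <- h[pmin(floor(tgrid[-length(tgrid)]) + 1L, length(h))]
    surv <- c(1, exp(-cumsum(hz * dt)))
    sum((surv[-1] + surv[-length(surv)]) / 2 * dt)
  }
  set.seed(7)
  for (i in 1:5) {
    h <- runif(111, 0, 0.15)
    expect_equal(life_expectancy(build_life_table(h)), oracle_e0(h),
                 tolerance = 0.2 / oracle_e0(h))
  }
})

test_that("life table closure handles degenerate hazards", {
  # no mortality until a huge terminal hazard: everyone lives to the cap
  h <- c(rep(0, 110), 1e6)
  e0 <- life_expectancy(build_life_table(h))
  expect_equal(e0, 110, tolerance = 0.01)
  # terminal hazard zero: closed with one extra person-year
  h0 <- rep(0, 111)
  expect_equal(life_expectancy(build_life_table(h0)), 110 + 1)
  # immediate near-certain death: e0 collapses toward the half-year floor
  hbig <- rep(1e9, 111)
  expect_lt(life_expectancy(build_life_table(hbig)), 0.6)
  expect_error(build_life_table(c(-0.1, rep(0.1, 110))), "non-negative")
})

test_that("life table survivorship is a non-increasing probability", {
  set.seed(11)
  h <- runif(111, 0, 0.5)
  lt <- build_life_table(h)
  expect_true(all(diff(lt$lx) <= 0))
  expect_true(all(lt$lx >= 0 & lt$lx <= 1))
  expect_true(all(lt$ex >= 0))
})

test_that("total_population filters and is additive over disjoint partitions", {
  lv <- stratum_levels()
  arr <- array(0, dim = c(111, 2, 4, nrow(lv$mig)))
  st_empty <- population_state(arr, 2000)
  expect_equal(total_population(st_empty), 0)

  arr[31, 1, 2, 1] <- 10   # urban
  arr[41, 2, 3, 1] <- 20   # rural
  st <- population_state(arr, 2000)
  expect_equal(total_population(st), 30)
  expect_equal(total_population(st, "urban"), 10)
  expect_equal(total_population(st, "rural"), 20)
  expect_equal(total_population(st, "urban") + total_population(st, "rural"),
               total_population(st))
  expect_error(total_population(st, "suburban"), "unknown residence")
})

test_that("state validation rejects bad counts", {
  lv <- stratum_levels()
  arr <- array(0, dim = c(111, 2, 4, nrow(lv$mig)))
  arr[1, 1, 1, 1] <- -1
  expect_error(population_state(arr, 2000), "non-negative")
  arr[1, 1, 1, 1] <- 2.5
  expect_error(population_state(arr, 2000, mode = "stochastic"), "integer")
  expect_silent(population_state(round(arr), 2000, mode = "stochastic"))
})

test_that("migration states advance like an explicit per-year history", {
  tab <- mig_states()
  never <- 1L
  # never + no move stays never
  expect_equal(advance_migration_state(never, FALSE), never)
  # a move resets the clock with the new direction
  moved <- advance_migration_state(never, TRUE, "rural_to_urban")
  expect_equal(tab$direction[moved], "rural_to_urban")
  expect_equal(tab$ysm[moved], 0L)
  expect_equal(migration_bin(moved), "moved_0_5")

  # oracle: explicit year-by-year history for one individual
  history_bin <- function(moves) {
    # moves: logical per year; returns the bin after the last year
    ysm <- NA
    for (m in moves) {
      if (m) ysm <- 0 else if (!is.na(ysm)) ysm <- ysm + 1
    }
    if (is.na(ysm)) "never"
    else if (ysm <= 5) "moved_0_5"
    else if (ysm <= 11) "moved_6_11"
    else "moved_12_plus"
  }
  set.seed(3)
  for (rep in 1:20) {
    moves <- runif(15) < 0.15
    s <- never
    for (m in moves)
      s <- advance_migration_state(s, m, "rural_to_urban")
    expect_equal(migration_bin(s), history_bin(moves))
  }
  # the 5->6 year boundary crosses bins exactly
  s <- advance_migration_state(never, TRUE, "urban_to_rural")
  for (i in 1:5) s <- advance_migration_state(s, FALSE)
  expect_equal(migration_bin(s), "moved_0_5")   # 5 years since move
  s <- advance_migration_state(s, FALSE)
  expect_equal(migration_bin(s), "moved_6_11")  # 6 years since move
})

test_that("population state round-trips through the long CSV dialect", {
  p <- toy_params()
  st <- expand_initial_population(toy_base_population(1000), p, 2000)
  f <- tempfile(fileext = ".csv")
  write_population_csv(st, f)
  st2 <- read_population_csv(f)
  expect_equal(st2$year, 2000L)
  expect_equal(total_population(st2), total_population(st), tolerance = 1e-12)
  # everyone starts with no migration history, so the bin mapping is lossless
  expect_equal(st2$counts, st$counts, tolerance = 1e-12)
  unlink(f)
})
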