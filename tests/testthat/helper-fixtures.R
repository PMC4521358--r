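# Shared fixtures built in code. The generated scenario is cached per test run
# because several files exercise the same synthetic target set.

fixture_env <- new.env()

fixture_generated <- function(name = "full_effects", seed = 1L, noise = NULL) {
  key <- paste(name, seed, paste(noise, collapse = "_"), sep = "|")
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- suppressWarnings(
      generate_targets(make_truth(name, seed = seed), noise = noise))
  }
  fixture_env[[key]]
}

# a small, fast parameter set and base population for simulator-level tests
toy_params <- function(variant = "v3") {
  fert <- if (variant == "v1") {
    data.frame(residence = c("urban", "rural"), education = NA_character_,
               F = c(2.5, 3.5), a = c(24, 22), b = c(9, 10), trend_F = -0.03)
  } else {
    fe <- expand.grid(residence = c("urban", "rural"),
                      education = c("E0", "E1", "E2", "E3"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    fe$F <- c(4, 4.5, 3.5, 4, 3, 3.5, 2.2, 2.7)
    fe$a <- 22 + (fe$education == "E3") * 3
    fe$b <- 10
    fe$trend_F <- -0.03
    fe
  }
  lc <- expand.grid(residence = c("urban", "rural"),
                    cluster = c("infant", "child", "adult"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lc$c <- c(-2.8, -2.5, -6.2, -5.9, -3.9, -3.6)
  lc$beta_year <- -0.02
  lc$beta_age <- c(0, 0, -0.15, -0.15, 0.085, 0.085)
  lc$reference_year <- 2000L
  lc$reference_age <- c(0, 0, 5, 5, 60, 60)
  rr <- rbind(urban = c(1, 0.85, 0.65, 0.45), rural = c(1, 0.9, 0.75, 0.6))
  colnames(rr) <- c("E0", "E1", "E2", "E3")
  if (variant == "v1") rr <- unit_rr()
  mig <- expand.grid(direction = c("rural_to_urban", "urban_to_rural"),
                     education = c("E0", "E1", "E2", "E3"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mig$base_rate <- ifelse(mig$direction == "rural_to_urban" & variant == "v3",
                          0.008, 0)
  mig$trend <- 0
  edu <- education_trend_params(
    urban = list(baseline = c(0.3, 0.3, 0.3, 0.1),
                 trend = if (variant == "v1") rep(0, 4)
                         else c(-0.006, 0, 0.004, 0.002)),
    rural = list(baseline = c(0.5, 0.3, 0.18, 0.02),
                 trend = if (variant == "v1") rep(0, 4)
                         else c(-0.008, 0.004, 0.003, 0.001)),
    reference_year = 1978L)
  parameter_set(variant,
                fertility = fertility_params(fert, 2000L),
                lc = lee_carter_params(lc),
                rr = rr,
                migration = migration_params(mig, 2000L),
                edu = edu)
}

toy_base_population <- function(size = 2e4, urban_share = 0.3, age_cap = 110L) {
  ages <- 0:age_cap
  w <- exp(-0.03 * ages)
  w <- w / sum(w)
  rbind(data.frame(age = ages, residence = "urban",
                   count = size * urban_share * w),
        data.frame(age = ages, residence = "rural",
                   count = size * (1 - urban_share) * w))
}
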