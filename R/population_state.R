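#' demogsim: stratified demographic microsimulation with Bayesian calibration
#'
#' Simulates a female population stratified by single year of age, urban/rural
#' residence, educational attainment (0, 1-5, 6-12, >12 years of schooling) and
#' migration history, under annual competing risks of death and migration and a
#' Gompertz-Pasupuleti fertility process, all with linear secular trends.
#' Three nested model variants of increasing complexity can be calibrated to
#' survey-style targets by MCMC and compared with the deviance information
#' criterion.
#'
#' @useDynLib demogsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm rnorm runif median quantile sd var complete.cases setNames
#' @importFrom utils read.csv write.csv head
#' @keywords internal
"_PACKAGE"

# ---- stratum grids ----------------------------------------------------------

#' Stratum level sets
#'
#' Canonical level vectors for the four stratification axes. Ages are single
#' years from 0 to `age_cap`; education categories E0-E3 correspond to 0, 1-5,
#' 6-12 and >12 years of schooling.
#'
#' @param age_cap Maximum (open-ended) single-year age; must be >= 100.
#' @return A list with components `ages`, `residences`, `educations` and the
#'   migration-state table from [mig_states()].
#' @export
stratum_levels <- function(age_cap = 110L) {
  age_cap <- as.integer(age_cap)
  if (is.na(age_cap) || age_cap < 100L)
    stop("age_cap must be an integer >= 100")
  list(
    ages       = 0:age_cap,
    residences = c("urban", "rural"),
    educations = c("E0", "E1", "E2", "E3"),
    mig        = mig_states()
  )
}

#' Migration-history states
#'
#' Internal single-year years-since-move bookkeeping. State 1 is "never moved";
#' the remaining states track the direction of the last move (rural_to_urban or
#' urban_to_rural) and the number of completed years since that move, capped at
#' 12 (meaning 12 or more). The coarse lookback bins used by survey targets
#' (moved within the last 6 years, within 12 years, ever) are derived from the
#' year counter, aligning exactly with the 6- and 12-year lookback windows.
#'
#' @return A data.frame with columns `index`, `direction`
#'   (`none`/`rural_to_urban`/`urban_to_rural`), `ysm` (years since move, NA
#'   for never) and `bin` (`never`, `moved_0_5`, `moved_6_11`, `moved_12_plus`).
#' @export
mig_states <- function() {
  ysm <- 0:12
  bin_of <- function(y) ifelse(y <= 5, "moved_0_5",
                        ifelse(y <= 11, "moved_6_11", "moved_12_plus"))
  data.frame(
    index     = seq_len(1L + 2L * length(ysm)),
    direction = c("none", rep("rural_to_urban", 13), rep("urban_to_rural", 13)),
    ysm       = c(NA_integer_, ysm, ysm),
    bin       = c("never", bin_of(ysm), bin_of(ysm)),
    stringsAsFactors = FALSE
  )
}

#' @rdname mig_states
#' @param index Vector of migration-state indices.
#' @return `migration_bin()`: the lookback bin label for each state index.
#' @export
migration_bin <- function(index) {
  tab <- mig_states()
  if (any(is.na(index)) || any(index < 1L) || any(index > nrow(tab)))
    stop("invalid migration-state index")
  tab$bin[index]
}

#' Advance migration-history states by one year
#'
#' On a move the state resets to years-since-move 0 with the new direction;
#' otherwise "never" stays "never" and the year counter advances (capped at
#' 12+), preserving the direction of the last move.
#'
#' @param index Current migration-state indices (see [mig_states()]).
#' @param moved Logical vector: did a move occur this year?
#' @param direction Direction of this year's move (`rural_to_urban` or
#'   `urban_to_rural`); recycled, ignored where `moved` is FALSE.
#' @return New state indices.
#' @export
advance_migration_state <- function(index, moved = FALSE, direction = NULL) {
  tab <- mig_states()
  if (any(index < 1L) || any(index > nrow(tab)))
    stop("invalid migration-state index")
  n <- length(index)
  moved <- rep_len(moved, n)
  out <- integer(n)
  # no move: never -> never; otherwise ysm+1 capped at 12
  stay <- !moved
  out[stay] <- ifelse(tab$direction[index[stay]] == "none",
                      1L,
                      mig_index(tab$direction[index[stay]],
                                pmin(tab$ysm[index[stay]] + 1L, 12L)))
  if (any(moved)) {
    if (is.null(direction)) stop("direction required when moved is TRUE")
    direction <- rep_len(direction, n)
    if (!all(direction[moved] %in% c("rural_to_urban", "urban_to_rural")))
      stop("direction must be rural_to_urban or urban_to_rural")
    out[moved] <- mig_index(direction[moved], 0L)
  }
  out
}

# index of the (direction, ysm) state; direction "none" + NA -> 1
mig_index <- function(direction, ysm) {
  base <- ifelse(direction == "rural_to_urban", 1L,
          ifelse(direction == "urban_to_rural", 14L, NA_integer_))
  ifelse(direction == "none", 1L, 1L + base + as.integer(ysm))
}

# ---- population state -------------------------------------------------------

#' Construct a population state
#'
#' A population state holds person counts for one calendar year on the full
#' stratum grid: age x residence x education x migration state. Counts are
#' real-valued in expected-value mode and integer in stochastic mode.
#'
#' @param counts 4-d array `[age, residence, education, migration state]`, or a
#'   long data.frame with columns `age`, `residence`, `education`,
#'   `migration_bin` (or `mig_index`), `direction`, `count`.
#' @param year Calendar year the counts refer to.
#' @param mode `"expected_value"` or `"stochastic"`.
#' @param age_cap Maximum age (default 110).
#' @return An object of class `population_state`.
#' @export
population_state <- function(counts, year, mode = c("expected_value", "stochastic"),
                             age_cap = 110L) {
  mode <- match.arg(mode)
  lv <- stratum_levels(age_cap)
  A <- length(lv$ages); R <- 2L; E <- 4L; M <- nrow(lv$mig)
  if (is.data.frame(counts)) {
    counts <- state_array_from_long(counts, lv)
  }
  if (!is.array(counts) || length(dim(counts)) != 4L ||
      !all(dim(counts) == c(A, R, E, M)))
    stop(sprintf("counts must be an array of dim [%d, %d, %d, %d]", A, R, E, M))
  dimnames(counts) <- list(NULL, lv$residences, lv$educations, NULL)
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (mode == "stochastic" && any(abs(counts - round(counts)) > 1e-9))
    stop("stochastic mode requires integer counts")
  structure(
    list(counts = counts, year = as.integer(year), mode = mode,
         age_cap = as.integer(age_cap)),
    class = "population_state"
  )
}

state_array_from_long <- function(df, lv) {
  need <- c("age", "residence", "education", "count")
  if (!all(need %in% names(df)))
    stop("long-format state needs columns: ", paste(need, collapse = ", "))
  A <- length(lv$ages); M <- nrow(lv$mig)
  arr <- array(0, dim = c(A, 2L, 4L, M))
  ri <- match(df$residence, lv$residences)
  ei <- match(df$education, lv$educations)
  if (anyNA(ri) || anyNA(ei)) stop("unknown residence or education level")
  if ("mig_index" %in% names(df)) {
    mi <- as.integer(df$mig_index)
  } else if ("migration_bin" %in% names(df)) {
    # bins map to a representative years-since-move (start of the bin)
    dir <- if ("direction" %in% names(df)) df$direction else "none"
    dir <- rep_len(dir, nrow(df))
    ysm <- c(never = NA, moved_0_5 = 0, moved_6_11 = 6, moved_12_plus = 12)[df$migration_bin]
    mi <- mig_index(ifelse(df$migration_bin == "never", "none", dir), ysm)
  } else {
    mi <- rep(1L, nrow(df))
  }
  if (anyNA(mi) || any(mi < 1L | mi > M)) stop("invalid migration state")
  ai <- as.integer(df$age) + 1L
  if (any(ai < 1L | ai > A)) stop("age outside [0, age_cap]")
  idx <- cbind(ai, ri, ei, mi)
  for (k in seq_len(nrow(df))) arr[idx[k, , drop = FALSE]] <-
      arr[idx[k, , drop = FALSE]] + df$count[k]
  arr
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> year %d, mode %s, total %.1f persons\n",
              x$year, x$mode, sum(x$counts)))
  byres <- apply(x$counts, 2, sum)
  cat(sprintf("  urban %.1f | rural %.1f | age cap %d\n",
              byres["urban"], byres["rural"], x$age_cap))
  invisible(x)
}

#' @export
as.data.frame.population_state <- function(x, row.names = NULL, optional = FALSE,
                                           drop_zero = TRUE, ...) {
  lv <- stratum_levels(x$age_cap)
  mig <- lv$mig
  grid <- expand.grid(age = lv$ages, residence = lv$residences,
                      education = lv$educations, mig_index = mig$index,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$migration_bin <- mig$bin[grid$mig_index]
  grid$direction <- mig$direction[grid$mig_index]
  grid$count <- as.vector(x$counts)
  grid$year <- x$year
  out <- grid[, c("year", "age", "residence", "education",
                  "migration_bin", "direction", "count")]
  if (drop_zero) out <- out[out$count > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read or write a population state as long-format CSV
#'
#' The serialized dialect has columns
#' `year, age, residence, education, migration_bin, direction, count`.
#'
#' @param state A `population_state`.
#' @param path File path.
#' @param mode,age_cap Passed to [population_state()] when reading.
#' @return `read_population_csv()` returns a `population_state`.
#' @export
write_population_csv <- function(state, path) {
  write.csv(as.data.frame(state), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path, mode = "expected_value", age_cap = 110L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty population file: ", path)
  population_state(df, year = df$year[1], mode = mode, age_cap = age_cap)
}

#' Total population, optionally filtered by residence
#'
#' @param state A `population_state`.
#' @param residence `NULL` (all), `"urban"` or `"rural"`.
#' @return Number of persons in the filtered strata.
#' @export
total_population <- function(state, residence = NULL) {
  stopifnot(inherits(state, "population_state"))
  if (is.null(residence)) return(sum(state$counts))
  if (!residence %in% c("urban", "rural")) stop("unknown residence filter")
  sum(state$counts[, residence, , ])
}

# counts collapsed to [age, residence, education]
state_counts_are <- function(state) {
  apply(state$counts, c(1, 2, 3), sum)
}

# ---- life table -------------------------------------------------------------

#' Build a period life table from age-specific mortality hazards
#'
#' Survivorship follows `l(x+1) = l(x) exp(-h(x))` with `l(0) = 1`;
#' person-years are `L(x) = (l(x) + l(x+1)) / 2` for ages below the cap. The
#' table is closed at the terminal age with `L = l / h` when the terminal
#' hazard is positive, and `L = l` (one further person-year) when it is zero.
#' Life expectancy at birth is the sum of the `L(x)` column.
#'
#' @param hazards Non-negative mortality rates (per person-year) indexed by
#'   single year of age from 0 to the age cap.
#' @return An object of class `life_table`: a data.frame with columns `age`,
#'   `hazard`, `lx`, `Lx`, `ex`.
#' @export
build_life_table <- function(hazards) {
  hazards <- as.numeric(hazards)
  if (length(hazards) < 2L) stop("need hazards for at least two ages")
  if (anyNA(hazards)) stop("hazards must be numeric and non-missing")
  if (any(hazards < 0)) stop("hazards must be non-negative")
  n <- length(hazards)
  lx <- c(1, cumprod(exp(-hazards)))  # length n + 1; lx[n+1] = survival past cap
  Lx <- (lx[1:(n - 1)] + lx[2:n]) / 2
  term <- if (hazards[n] > 0) lx[n] / hazards[n] else lx[n]
  Lx <- c(Lx, term)
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx[1:n] > 0, Tx / lx[1:n], 0)
  structure(
    data.frame(age = seq_len(n) - 1L, hazard = hazards,
               lx = lx[1:n], Lx = Lx, ex = ex),
    class = c("life_table", "data.frame")
  )
}

#' Life expectancy at a given age from a life table
#'
#' @param lt A `life_table`.
#' @param age Age at which to evaluate the expectation (default 0).
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(lt, age = 0L) {
  stopifnot(inherits(lt, "life_table"))
  i <- match(age, lt$age)
  if (is.na(i)) stop("age outside the life table")
  lt$ex[i]
}
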