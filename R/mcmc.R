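# Generic MCMC machinery: adaptive block random-walk Metropolis over a
# bounded parameter space with flat (vague uniform) priors, the potential
# scale reduction convergence diagnostic, and Spiegelhalter-style DIC.

#' Adaptive block random-walk Metropolis sampler
#'
#' Samples from the posterior implied by `log_lik` and independent uniform
#' priors on `[lower, upper]`. Each iteration updates one block of parameters
#' (cyclic scan) with a Gaussian random-walk proposal; per-block proposal
#' scales adapt during burn-in toward the target acceptance rate and are then
#' frozen. Deterministic given `seed`.
#'
#' @param log_lik Function of the named parameter vector returning a scalar
#'   log-likelihood (may be `-Inf`).
#' @param init Named numeric starting vector (must have finite likelihood).
#' @param lower,upper Bounds, recycled to `length(init)`.
#' @param n_iter Total iterations (block updates).
#' @param burn_in Iterations discarded (and used for adaptation);
#'   `n_iter > burn_in` required.
#' @param blocks List of integer index vectors partitioning the parameters;
#'   default one block per parameter-name prefix is NOT inferred — a single
#'   all-parameter block is used.
#' @param scale Initial per-parameter proposal standard deviations; default
#'   2% of the prior range.
#' @param seed RNG seed.
#' @param target_accept Acceptance rate targeted by the adaptation.
#' @return An object of class `mcmc_chain`: retained `draws` (matrix), their
#'   `deviance` (`-2 log_lik`), per-block `acceptance`, the frozen scales, and
#'   the settings.
#' @export
mcmc_sample <- function(log_lik, init, lower, upper, n_iter, burn_in,
                        blocks = NULL, scale = NULL, seed = 1L,
                        target_accept = 0.28) {
  d <- length(init)
  if (is.null(names(init))) names(init) <- paste0("par", seq_len(d))
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  if (any(init < lower | init > upper)) stop("init outside the prior bounds")
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (is.null(blocks)) blocks <- list(seq_len(d))
  if (is.null(scale)) scale <- 0.02 * (upper - lower)
  set.seed(seed)
  theta <- init
  ll <- log_lik(theta)
  if (!is.finite(ll)) stop("non-finite log-likelihood at the starting point")
  B <- length(blocks)
  log_s <- numeric(B)          # per-block adaptive log scale factor
  n_prop <- numeric(B); n_acc <- numeric(B); n_adapt <- numeric(B)
  keep <- n_iter - burn_in
  draws <- matrix(NA_real_, keep, d, dimnames = list(NULL, names(init)))
  devs <- numeric(keep)
  for (it in seq_len(n_iter)) {
    bi <- (it - 1L) %% B + 1L
    idx <- blocks[[bi]]
    prop <- theta
    prop[idx] <- theta[idx] + exp(log_s[bi]) * scale[idx] * rnorm(length(idx))
    n_prop[bi] <- n_prop[bi] + 1
    acc <- FALSE
    if (all(prop[idx] >= lower[idx] & prop[idx] <= upper[idx])) {
      ll_prop <- log_lik(prop)
      if (is.finite(ll_prop) && log(runif(1)) < ll_prop - ll) {
        theta <- prop; ll <- ll_prop; acc <- TRUE
      }
    }
    if (acc) n_acc[bi] <- n_acc[bi] + 1
    if (it <= burn_in) {
      n_adapt[bi] <- n_adapt[bi] + 1
      step <- min(0.5, 1 / sqrt(n_adapt[bi]))
      log_s[bi] <- log_s[bi] + step * ((if (acc) 1 else 0) - target_accept)
    }
    if (it > burn_in) {
      k <- it - burn_in
      draws[k, ] <- theta
      devs[k] <- -2 * ll
    }
  }
  structure(list(draws = draws, deviance = devs,
                 acceptance = ifelse(n_prop > 0, n_acc / n_prop, NA),
                 scales = exp(log_s), blocks = blocks, seed = seed,
                 n_iter = n_iter, burn_in = burn_in),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf("<mcmc_chain> %d retained draws of %d parameters; acceptance %.2f\n",
              nrow(x$draws), ncol(x$draws), mean(x$acceptance, na.rm = TRUE)))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction
#'
#' The classic between/within-chain variance ratio; values near 1 indicate
#' convergence, values well above 1.1 indicate disagreement between chains.
#'
#' @param chains List of at least two `mcmc_chain` objects (or draw matrices)
#'   with equal retained lengths.
#' @return Named vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(chains) {
  mats <- lapply(chains, function(ch)
    if (inherits(ch, "mcmc_chain")) ch$draws else as.matrix(ch))
  if (length(mats) < 2L) stop("need at least two chains")
  n <- unique(vapply(mats, nrow, integer(1)))
  if (length(n) != 1L) stop("chains must have equal retained lengths")
  if (n < 2L) stop("chains must have length >= 2")
  m <- length(mats)
  d <- ncol(mats[[1]])
  rhat <- numeric(d)
  for (j in seq_len(d)) {
    xs <- vapply(mats, function(M) M[, j], numeric(n))
    means <- colMeans(xs)
    W <- mean(apply(xs, 2, var))
    Bn <- var(means)               # B/n
    if (W == 0) {
      rhat[j] <- if (Bn == 0) 1 else Inf
    } else {
      rhat[j] <- sqrt(((n - 1) / n * W + Bn) / W)
    }
  }
  names(rhat) <- colnames(mats[[1]])
  rhat
}

#' DIC from posterior deviances
#'
#' Spiegelhalter decomposition: `p_D = mean(D) - D(posterior mean)` and
#' `DIC = mean(D) + p_D`.
#'
#' @param deviances Deviance of each retained posterior draw.
#' @param deviance_at_mean Deviance re-evaluated at the posterior mean
#'   parameter vector.
#' @return An object of class `dic_result` with components `mean_deviance`,
#'   `deviance_at_posterior_mean`, `p_d`, `dic`.
#' @export
dic_from_deviances <- function(deviances, deviance_at_mean) {
  if (!length(deviances)) stop("empty deviance vector")
  md <- mean(deviances)
  p_d <- md - deviance_at_mean
  structure(list(mean_deviance = md,
                 deviance_at_posterior_mean = deviance_at_mean,
                 p_d = p_d, dic = md + p_d),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("<dic_result> DIC %.2f (mean deviance %.2f, p_D %.2f)\n",
              x$dic, x$mean_deviance, x$p_d))
  invisible(x)
}
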