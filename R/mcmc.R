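# Adaptive random-walk Metropolis.  Rate constants and scaling factors are
# sampled in log10 space (with the Jacobian added to the target so the box
# prior stays uniform on the original scale); sigma is sampled linearly.
# The proposal covariance is re-estimated during a dedicated adaptation
# phase as (2.38^2/d) * Chat + jitter and frozen for production, so the
# production draws form a valid fixed-kernel Markov chain.

#' MCMC settings
#'
#' @param burn Burn-in iterations (default 25000).
#' @param adapt Adaptation iterations used to tune the proposal covariance
#'   (default 25000).
#' @param production Production iterations retained for inference
#'   (default 250000).
#' @param chains Number of independent chains (default 5).
#' @param seed Integer seed (chain i uses `seed + i - 1`); `NULL` leaves the
#'   RNG stream untouched.
#' @param init_scale Initial proposal standard deviation as a fraction of
#'   each box width in the sampling space (default 0.1).
#' @param accept_band Target acceptance band used by the scalar step-size
#'   tuner during burn-in (default `c(0.15, 0.4)`).
#' @return list of settings (class `mcmc_config`).
#' @export
mcmc_config <- function(burn = 25000, adapt = 25000, production = 250000,
                        chains = 5, seed = NULL, init_scale = 0.1,
                        accept_band = c(0.15, 0.4)) {
  stopifnot(burn >= 0, adapt >= 0, production >= 1, chains >= 1)
  structure(list(burn = burn, adapt = adapt, production = production,
                 chains = chains, seed = seed, init_scale = init_scale,
                 accept_band = accept_band), class = "mcmc_config")
}

prior_transform <- function(prior) {
  lg <- if ("log" %in% names(prior)) prior$log
        else prior$lower > 0 & prior$name != "sigma"
  list(log = lg,
       lo = ifelse(lg, log10(prior$lower), prior$lower),
       hi = ifelse(lg, log10(prior$upper), prior$upper))
}

#' Run one adaptive Metropolis chain
#'
#' @param log_post Function of a named parameter vector (original scale)
#'   returning the log-posterior (`-Inf` outside the support).
#' @param prior data.frame (`name`, `lower`, `upper`, optional logical `log`
#'   marking coordinates sampled in log10 space; default: all but `sigma`).
#' @param config An `mcmc_config`.
#' @param seed Integer seed for this chain (overrides `config$seed`).
#' @return list with `draws` (production iterations x parameters, original
#'   scale), `lp` (log-posterior trace), `accept` (per-phase acceptance
#'   rates), and the frozen proposal covariance.
#' @export
run_chain <- function(log_post, prior, config = mcmc_config(),
                      seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  d <- nrow(prior)
  tr <- prior_transform(prior)
  width <- tr$hi - tr$lo
  ln10 <- log(10)

  # log target in sampling coordinates (Jacobian keeps the prior uniform on
  # the original scale)
  target <- function(xt) {
    x <- ifelse(tr$log, 10^xt, xt)
    lp <- log_post(stats::setNames(x, prior$name))
    if (!is.finite(lp)) return(-Inf)
    lp + sum(log(ln10) + ln10 * xt[tr$log])
  }

  xt <- NULL
  for (try in 1:200) {
    cand <- tr$lo + stats::runif(d) * width
    if (is.finite(target(cand))) { xt <- cand; break }
  }
  if (is.null(xt)) stop("could not find a starting point with finite posterior")
  lp <- target(xt)

  n_tot <- config$burn + config$adapt + config$production
  hist_t <- matrix(NA_real_, n_tot, d)
  lp_tr <- numeric(n_tot)
  acc <- c(burn = 0L, adapt = 0L, production = 0L)
  phase_len <- c(burn = config$burn, adapt = config$adapt,
                 production = config$production)

  step <- config$init_scale
  sigma_prop <- diag((step * width)^2, d)
  chol_prop <- chol(sigma_prop)
  jitter <- diag(1e-10 * width^2, d)
  acc_win <- 0L

  for (i in seq_len(n_tot)) {
    phase <- if (i <= config$burn) "burn"
             else if (i <= config$burn + config$adapt) "adapt"
             else "production"
    prop <- xt + drop(stats::rnorm(d) %*% chol_prop)
    lp_prop <- target(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      xt <- prop; lp <- lp_prop
      acc[phase] <- acc[phase] + 1L
      acc_win <- acc_win + 1L
    }
    hist_t[i, ] <- xt
    lp_tr[i] <- lp

    if (phase == "burn" && i %% 50L == 0L) {
      rate <- acc_win / 50; acc_win <- 0L
      if (rate < config$accept_band[1]) step <- step * 0.7
      if (rate > config$accept_band[2]) step <- step * 1.3
      chol_prop <- chol(diag((step * width)^2, d))
    }
    if (phase == "adapt" && (i %% 100L == 0L ||
                             i == config$burn + config$adapt)) {
      ch <- hist_t[max(1, config$burn) : i, , drop = FALSE]
      if (nrow(ch) > 2 * d) {
        sigma_prop <- 2.38^2 / d * stats::cov(ch) + jitter
        chol_prop <- chol(sigma_prop)
      }
    }
  }

  prod_idx <- (config$burn + config$adapt + 1L):n_tot
  draws_t <- hist_t[prod_idx, , drop = FALSE]
  draws <- draws_t
  for (j in seq_len(d)) if (tr$log[j]) draws[, j] <- 10^draws_t[, j]
  colnames(draws) <- prior$name
  list(draws = draws, lp = lp_tr[prod_idx],
       accept = acc / pmax(phase_len, 1L),
       proposal_cov = sigma_prop, seed = seed)
}

#' Run several independent chains
#'
#' @inheritParams run_chain
#' @return A `posterior_sample`: `draws` (list of production matrices, one
#'   per chain, original scale), `lp`, `accept`, `prior`, `config`.
#' @export
run_mcmc <- function(log_post, prior, config = mcmc_config()) {
  seeds <- if (is.null(config$seed)) rep(list(NULL), config$chains)
           else as.list(config$seed + seq_len(config$chains) - 1L)
  chains <- lapply(seeds, function(s) run_chain(log_post, prior, config, s))
  structure(list(draws = lapply(chains, `[[`, "draws"),
                 lp = lapply(chains, `[[`, "lp"),
                 accept = lapply(chains, `[[`, "accept"),
                 prior = prior, config = config),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("posterior_sample: %d chain(s) x %d draws of %d parameter(s)\n",
              length(x$draws), nrow(x$draws[[1]]), ncol(x$draws[[1]])))
  invisible(x)
}

# iterations x chains matrix for one parameter
param_matrix <- function(sample, param) {
  sapply(sample$draws, function(m) m[, param])
}

#' Pooled production draws of a posterior sample
#'
#' @param sample A `posterior_sample`.
#' @param max_draws Thin (every k-th draw) so at most this many pooled draws
#'   remain; `Inf` disables thinning.
#' @return Matrix draws x parameters.
#' @export
pooled_draws <- function(sample, max_draws = Inf) {
  pooled <- do.call(rbind, sample$draws)
  if (nrow(pooled) > max_draws) {
    k <- ceiling(nrow(pooled) / max_draws)
    pooled <- pooled[seq(1, nrow(pooled), by = k), , drop = FALSE]
  }
  pooled
}
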