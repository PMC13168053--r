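# Convergence diagnostics: rank-normalized split-Rhat and bulk/tail
# effective sample size (Geyer initial monotone sequence on per-chain
# autocorrelations, combined across split chains).

split_chains <- function(x) {
  x <- as.matrix(x)
  n <- floor(nrow(x) / 2)
  cbind(x[seq_len(n), , drop = FALSE],
        x[(nrow(x) - n + 1):nrow(x), , drop = FALSE])
}

rank_normalize <- function(x) {
  d <- dim(x)
  z <- stats::qnorm((rank(as.vector(x), ties.method = "average") - 3 / 8) /
                    (length(x) + 1 / 4))
  dim(z) <- d
  z
}

rhat_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 2 || m < 2) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (!is.finite(w) || w <= 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Rank-normalized split-Rhat
#'
#' Potential-scale-reduction diagnostic computed on rank-normalized split
#' chains; the reported value is the maximum of the bulk and the folded
#' (median-absolute-deviation sensitive) versions.  Values near 1 indicate
#' convergence; degenerate (constant) chains give `NA` with a warning.
#'
#' @param x Matrix of draws, iterations x chains (at least 2 chains,
#'   4 draws each).
#' @return Scalar Rhat.
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2 || nrow(x) < 4)
    stop("rhat needs at least 2 chains with at least 4 draws")
  if (stats::sd(x) == 0) {
    warning("constant chains: Rhat undefined")
    return(NA_real_)
  }
  bulk <- rhat_basic(rank_normalize(split_chains(x)))
  folded <- rhat_basic(rank_normalize(split_chains(abs(x - stats::median(x)))))
  max(bulk, folded)
}

# per-chain autocovariance by FFT (biased, as used by the ESS estimator)
autocovariance <- function(y) {
  n <- length(y)
  y <- y - mean(y)
  m <- stats::nextn(2 * n)
  f <- stats::fft(c(y, rep(0, m - n)))
  # biased autocovariance with 1/n normalization
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (m * n)
}

# effective sample size of the mean of split chains (Vehtari et al. style)
ess_mean <- function(x) {
  x <- split_chains(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4 || any(apply(x, 2, stats::sd) == 0) || stats::sd(x) == 0)
    return(NA_real_)
  acov <- apply(x, 2, autocovariance)
  chain_var <- acov[1, ] * n / (n - 1)
  w <- mean(chain_var)
  var_plus <- w * (n - 1) / n + stats::var(colMeans(x))
  rho <- 1 - (w - rowMeans(acov)) / var_plus
  # Geyer initial positive monotone sequence on paired sums (lags 0+1, 2+3, ...)
  tau <- -1
  prev_pair <- Inf
  t <- 1
  while (t + 1 <= n) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau <- tau + 2 * pair
    t <- t + 2
  }
  m * n / max(tau, 1 / (m * n))
}

#' Bulk effective sample size
#'
#' ESS of the rank-normalized split chains: a measure of the information the
#' draws carry about the bulk of the distribution.
#'
#' @inheritParams rhat
#' @return Scalar ESS.
#' @export
ess_bulk <- function(x) {
  x <- as.matrix(x)
  ess_mean(rank_normalize(split_chains(x)))
}

#' Tail effective sample size
#'
#' Minimum of the ESS of the 5% and 95% quantile indicator variables:
#' stability of tail estimates.
#'
#' @inheritParams rhat
#' @return Scalar ESS.
#' @export
ess_tail <- function(x) {
  x <- as.matrix(x)
  q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  min(ess_mean((x <= q[1]) * 1), ess_mean((x <= q[2]) * 1))
}

#' Convergence summary of a posterior sample
#'
#' @param sample A `posterior_sample` from [run_mcmc()].
#' @return data.frame with one row per parameter: `rhat`, `ess_bulk`,
#'   `ess_tail`, posterior `median`, and central 95% credible bounds.
#' @export
mcmc_diagnostics <- function(sample) {
  params <- colnames(sample$draws[[1]])
  pooled <- pooled_draws(sample)
  out <- do.call(rbind, lapply(params, function(p) {
    m <- param_matrix(sample, p)
    data.frame(parameter = p,
               rhat = if (length(sample$draws) >= 2) rhat(m) else NA_real_,
               ess_bulk = ess_bulk(m), ess_tail = ess_tail(m),
               median = stats::median(pooled[, p]),
               q2.5 = stats::quantile(pooled[, p], 0.025, names = FALSE),
               q97.5 = stats::quantile(pooled[, p], 0.975, names = FALSE))
  }))
  rownames(out) <- NULL
  out
}
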