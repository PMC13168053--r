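# The hybrid likelihood: Gaussian (homoscedastic) for quantitative
# relative-intensity records, Bernoulli with a logistic link on the
# model-output difference for binary comparison statements, and the
# hinge-penalty objective that the logistic negative log-likelihood
# approaches when |delta/s| >> 1.

#' Quantitative sum-of-squares
#'
#' `sum((y - f)^2)` over non-missing records; missing values contribute 0.
#'
#' @param y Observed values (may contain `NA`).
#' @param f Model predictions, same length.
#' @return Non-negative scalar.
#' @export
f_quant <- function(y, f) {
  stopifnot(length(y) == length(f))
  sum((y - f)^2, na.rm = TRUE)
}

#' Gaussian negative log-likelihood of the quantitative data
#'
#' `(n/2) log(2 pi sigma^2) + sum((y-f)^2) / (2 sigma^2)` with `n` the
#' non-missing count (homoscedastic noise).
#'
#' @inheritParams f_quant
#' @param sigma Noise scale (> 0).
#' @return Scalar; 0 when no non-missing records.
#' @export
gaussian_nll <- function(y, f, sigma) {
  if (sigma <= 0) stop("sigma must be > 0")
  n <- sum(!is.na(y) & !is.na(f))
  if (n == 0) return(0)
  n / 2 * log(2 * pi * sigma^2) + f_quant(y, f) / (2 * sigma^2)
}

#' Logistic outcome probability
#'
#' `p = 1 / (1 + exp(-delta/s))`, computed stably for large `|delta/s|`.
#'
#' @param delta Model-output differences.
#' @param s Logistic scale(s) (> 0).
#' @return Probabilities in \[0, 1\].
#' @export
logistic_prob <- function(delta, s) {
  if (any(s <= 0)) stop("scale s must be > 0")
  stats::plogis(delta / s)
}

#' Negative log-likelihood of the qualitative data
#'
#' `sum_i [ log(1 + exp(-delta_i/s_i)) + (1 - z_i) * delta_i/s_i ]`,
#' evaluated with the log1p-exp trick so saturated statements neither
#' overflow nor lose the linear tail.
#'
#' @param delta Model-output differences g(a) - g(b).
#' @param s Logistic scales (> 0), recycled.
#' @param z Observed binary outcomes (0/1), recycled.
#' @return Scalar (use `terms = TRUE` for the per-statement vector).
#' @param terms Return the per-statement terms instead of their sum?
#' @export
qual_nll <- function(delta, s, z, terms = FALSE) {
  if (any(s <= 0)) stop("scale s must be > 0")
  d <- delta / s
  tt <- pmax(-d, 0) + log1p(exp(-abs(d))) + (1 - z) * d
  if (terms) tt else sum(tt)
}

#' Hinge penalty for the qualitative data
#'
#' `sum_i w_i * [ max(0, -delta_i) + (1 - z_i) * delta_i ]`: the penalty is
#' `w_i |delta_i|` when the sign of `delta_i` contradicts the observation and
#' 0 otherwise.  With `w = 1/s` it brackets the logistic negative
#' log-likelihood term from below within `log(2)`.
#'
#' @param delta Model-output differences.
#' @param z Observed binary outcomes (0/1).
#' @param w Weights (default 1), recycled.
#' @param terms Return per-statement penalties instead of their sum?
#' @return Scalar or vector of non-negative penalties.
#' @export
qual_penalty <- function(delta, z, w = 1, terms = FALSE) {
  tt <- w * (pmax(0, -delta) + (1 - z) * delta)
  if (terms) tt else sum(tt)
}
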