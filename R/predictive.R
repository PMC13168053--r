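# Posterior predictive distributions: parametric uncertainty propagated
# through simulations (no measurement-noise injection), summarized as nested
# central credible bands, plus per-statement satisfaction fractions.

# simulate observable matrices for each retained draw
draw_obsmats <- function(draws, pinned, variants, times, rtol = 1e-6,
                         atol = 1e-2) {
  networks <- lapply(variants, build_network)
  names(networks) <- variants
  n_failed <- 0L
  sims <- vector("list", nrow(draws))
  for (i in seq_len(nrow(draws))) {
    theta <- pinned
    theta[colnames(draws)] <- draws[i, ]
    one <- tryCatch(lapply(variants, function(v) {
      st <- sim_states(networks[[v]], theta, times[[v]], rtol = rtol,
                       atol = atol)
      st %*% networks[[v]]$obs_weights
    }), error = function(e) NULL)
    if (is.null(one)) { n_failed <- n_failed + 1L; next }
    names(one) <- variants
    sims[[i]] <- one
  }
  kept <- which(!vapply(sims, is.null, TRUE))
  list(sims = sims[kept], kept = kept, n_failed = n_failed)
}

#' Posterior predictive bands
#'
#' Simulates every retained posterior draw and summarizes, per variant and
#' observable, the per-time median and nested central credible bands.
#'
#' @param sample A `posterior_sample`.
#' @param times Time grid (s).
#' @param pinned Full parameter vector for non-sampled parameters.
#' @param variants Variants to simulate (default all five).
#' @param levels Central credible levels (default 10%..95%).
#' @param scaled Multiply the three scaled observables by the draw's scaling
#'   factors (arbitrary units) instead of reporting copy numbers?
#' @param max_draws Thinning cap on the number of simulated draws.
#' @param rtol,atol Integration tolerances.
#' @return A `posterior_bands`: for each variant and observable a list with
#'   `time`, `median`, and `bands` (named list per level with `lower`/`upper`
#'   matrices of one row per time).  `n_failed` counts dropped draws.
#' @export
posterior_predictive <- function(sample, times, pinned = make_theta(),
                                 variants = variant_ids(),
                                 levels = c(0.10, 0.25, 0.50, 0.75, 0.90, 0.95),
                                 scaled = FALSE, max_draws = 2000,
                                 rtol = 1e-6, atol = 1e-2) {
  draws <- pooled_draws(sample, max_draws)
  tl <- stats::setNames(rep(list(sort(unique(times))), length(variants)),
                        variants)
  sim <- draw_obsmats(draws, pinned, variants, tl, rtol, atol)
  if (length(sim$sims) == 0) stop("all posterior draws failed to simulate")
  obs <- observable_names()
  sm <- scale_map()
  out <- lapply(variants, function(v) {
    per_obs <- lapply(obs, function(o) {
      oc <- match(o, obs)
      vals <- vapply(sim$sims, function(s) s[[v]][, oc],
                     numeric(length(tl[[v]])))
      vals <- matrix(vals, nrow = length(tl[[v]]))
      if (scaled && !is.na(sm[o])) {
        sc <- if (sm[o] %in% colnames(draws)) draws[sim$kept, sm[o]]
              else rep(pinned[[sm[o]]], length(sim$kept))
        vals <- sweep(vals, 2, sc, "*")
      }
      bands <- lapply(levels, function(L) {
        lo <- apply(vals, 1, stats::quantile, probs = 0.5 - L / 2)
        hi <- apply(vals, 1, stats::quantile, probs = 0.5 + L / 2)
        list(lower = lo, upper = hi)
      })
      names(bands) <- paste0(levels * 100, "%")
      list(time = tl[[v]], median = apply(vals, 1, stats::median),
           bands = bands)
    })
    stats::setNames(per_obs, obs)
  })
  structure(list(bands = stats::setNames(out, variants), levels = levels,
                 n_draws = length(sim$sims), n_failed = sim$n_failed),
            class = "posterior_bands")
}

#' @export
print.posterior_bands <- function(x, ...) {
  cat(sprintf("posterior_bands: %d draws (%d failed), levels %s\n",
              x$n_draws, x$n_failed,
              paste(names(x$bands[[1]][[1]]$bands), collapse = " ")))
  invisible(x)
}

#' Per-statement posterior satisfaction fractions
#'
#' Fraction of retained posterior draws whose simulated trajectories satisfy
#' each comparison statement.
#'
#' @param sample A `posterior_sample`.
#' @param props A `property_set`.
#' @param pinned Full parameter vector for non-sampled parameters.
#' @param max_draws Thinning cap.
#' @param rtol,atol Integration tolerances.
#' @return data.frame: `statement`, `z`, `fraction` in \[0, 1\].
#' @export
constraint_satisfaction_fraction <- function(sample, props,
                                             pinned = make_theta(),
                                             max_draws = 500,
                                             rtol = 1e-6, atol = 1e-2) {
  draws <- pooled_draws(sample, max_draws)
  problem <- cascade_problem(data = NULL, props = props, rtol = rtol,
                             atol = atol)
  p <- problem$pidx
  sat <- matrix(NA, nrow(draws), length(p$z))
  kept <- 0L
  for (i in seq_len(nrow(draws))) {
    theta <- pinned
    theta[colnames(draws)] <- draws[i, ]
    pred <- problem_predict(problem, theta)
    if (is.null(pred)) next
    kept <- kept + 1L
    sat[kept, ] <- as.integer(pred$delta >= 0) == p$z
  }
  if (kept == 0) stop("all posterior draws failed to simulate")
  data.frame(statement = vapply(props$props, format, character(1)),
             z = p$z, fraction = colMeans(sat[seq_len(kept), , drop = FALSE]))
}
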