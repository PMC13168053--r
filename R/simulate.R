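#' Simulate a cascade network deterministically
#'
#' Integrates the mass-action ODEs with the stiff-capable `lsoda` solver
#' (compiled right-hand side and analytic Jacobian).  The pre-stimulus state
#' equals the initial copy numbers (ligand engagement is off before t = 0)
#' and the stimulus switches on at t = 0 with rate `c1L`.
#'
#' @param network A `cascade_network` from [build_network()].
#' @param params Parameter vector; the network's variant transformation is
#'   applied internally (idempotent), so the base set may be passed.
#' @param t_grid Sorted non-negative times (s) at which state is reported.
#' @param rtol,atol Relative and absolute integration tolerances
#'   (defaults 1e-8 and 1e-2 molecules).
#' @return A `cascade_trajectory`: `time`, `states` (time x species copy
#'   numbers), `observables` (data.frame with `time`, `MEK_pRDS`,
#'   `pERK1_2_wt`, `pEGFR`, `pSOS1`), and the variant label.
#' @export
simulate_cascade <- function(network, params, t_grid,
                             rtol = 1e-8, atol = 1e-2) {
  check_params(params)
  if (is.unsorted(t_grid) || any(t_grid < 0))
    stop("t_grid must be sorted and non-negative")
  st <- sim_states(network, params, t_grid, rtol = rtol, atol = atol)
  as_trajectory(network, t_grid, st)
}

as_trajectory <- function(network, t_grid, states) {
  obs <- states %*% network$obs_weights
  structure(list(
    variant = network$variant, time = t_grid, states = states,
    observables = data.frame(time = t_grid, obs, check.names = FALSE),
    obs_weights = network$obs_weights, moieties = network$moieties
  ), class = "cascade_trajectory")
}

# Lean integration core: returns the time x species state matrix only.
sim_states <- function(network, params, t_grid, rtol = 1e-8, atol = 1e-2) {
  p <- apply_variant(params, network$variant)
  cm <- network$compiled
  k <- if (identical(names(p)[cm$rate_idx], cm$rate))
    cm$mult * as.numeric(p[cm$rate_idx])
  else cm$mult * as.numeric(p[cm$rate])
  y0 <- initial_state(network, p)
  times <- t_grid
  if (length(times) == 0L || times[1] > 0) times <- c(0, times)
  .Call(C_set_network, cm$n_species, cm$re1, cm$re2, cm$sptr, cm$sidx,
        cm$sval, k)
  out <- deSolve::lsoda(
    y = unname(y0), times = times, func = "cascade_derivs", parms = NULL,
    jacfunc = "cascade_jac", jactype = "fullusr", dllname = "cascadefit",
    initfunc = NULL, rtol = rtol, atol = atol, maxsteps = 100000,
    ynames = FALSE)
  ok <- nrow(out) == length(times) && all(is.finite(out))
  if (!ok) {
    bad <- if (nrow(out) < length(times)) times[nrow(out) + 1L]
           else times[which(!apply(is.finite(out), 1, all))[1]]
    stop(sprintf("integration failed near t = %g s (variant %s)",
                 bad, network$variant))
  }
  st <- out[match(t_grid, times), -1, drop = FALSE]
  colnames(st) <- network$species
  st
}

#' Simulate with an independent fixed-step RK4 integrator
#'
#' A brute-force cross-check for the adaptive solver: classical Runge-Kutta 4
#' at a fixed step.  Report times must be multiples of `dt`.
#'
#' @inheritParams simulate_cascade
#' @param dt Fixed step size in seconds (default 1e-3).
#' @return A `cascade_trajectory`.
#' @export
simulate_rk4 <- function(network, params, t_grid, dt = 1e-3) {
  check_params(params)
  p <- apply_variant(params, network$variant)
  cm <- network$compiled
  k <- cm$mult * as.numeric(p[cm$rate])
  y0 <- unname(initial_state(network, p))
  st <- t(.Call(C_rk4, y0, cm$re1, cm$re2, cm$sptr, cm$sidx, cm$sval, k,
                as.numeric(dt), as.numeric(t_grid)))
  colnames(st) <- network$species
  as_trajectory(network, t_grid, st)
}

#' Observable time series of a trajectory
#'
#' `MEK_pRDS`: activation-site-phosphorylated MEK protomers of both isoforms,
#' monomeric or dimeric; `pERK1_2_wt`: doubly phosphorylated ERK; `pEGFR`:
#' phosphorylated receptor subunits (2 per phosphorylated dimer, with or
#' without SOS1); `pSOS1`: feedback-phosphorylated SOS1.
#'
#' @param traj A `cascade_trajectory`.
#' @return data.frame with `time` and the four observables.
#' @export
compute_observables <- function(traj) {
  data.frame(time = traj$time, traj$states %*% traj$obs_weights,
             check.names = FALSE)
}

#' Conserved-moiety totals along a trajectory
#'
#' @param traj A `cascade_trajectory`.
#' @return data.frame of per-time totals for the eight material moieties.
#'   All are conserved except EGFR, which is non-increasing (degradation).
#' @export
moiety_totals <- function(traj) {
  data.frame(time = traj$time, traj$states %*% traj$moieties,
             check.names = FALSE)
}

#' @export
print.cascade_trajectory <- function(x, ...) {
  cat(sprintf("cascade_trajectory [%s]: %d times in [%g, %g] s, %d species\n",
              x$variant, length(x$time), min(x$time), max(x$time),
              ncol(x$states)))
  invisible(x)
}
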