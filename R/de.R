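# Differential evolution (rand/1/bin) under box constraints.  Coordinates
# whose bounds are positive and span at least one decade are searched in
# log10 space; initialization is uniform in the search space (log-uniform on
# the original scale, plain uniform for narrow boxes).  Out-of-bounds mutant
# coordinates are reflected back inside, avoiding boundary pile-up.

#' Assemble a full parameter-plus-scaling vector
#'
#' @param params Model parameters, e.g. [default_params()].
#' @param ScalepEGFR,ScalepERK,ScalepSOS1 Scaling factors (AU per molecule).
#' @param sigma Quantitative noise scale.
#' @return Named numeric vector of length 50.
#' @export
make_theta <- function(params = default_params(), ScalepEGFR = 4.5e-5,
                       ScalepERK = 3.2e-6, ScalepSOS1 = 1.1e-4, sigma = 1) {
  c(unclass(params), ScalepEGFR = ScalepEGFR, ScalepERK = ScalepERK,
    ScalepSOS1 = ScalepSOS1, sigma = sigma)
}

#' Differential-evolution settings
#'
#' @param pop_size Population size (>= 4; default 50).
#' @param generations Generation budget (default 500).
#' @param f Mutation factor in (0, 2) (default 0.85).
#' @param cr Crossover rate in (0, 1] (default 0.7).
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @param tol Early-stopping objective value (stop once best <= tol);
#'   `NULL` disables.
#' @param n_runs Independent restarts for the multistart variant.
#' @return list of settings (class `de_config`).
#' @export
de_config <- function(pop_size = 50, generations = 500, f = 0.85, cr = 0.7,
                      seed = NULL, tol = NULL, n_runs = 1) {
  stopifnot(pop_size >= 4, f > 0, f < 2, cr > 0, cr <= 1, generations >= 0)
  structure(list(pop_size = pop_size, generations = generations, f = f,
                 cr = cr, seed = seed, tol = tol, n_runs = n_runs),
            class = "de_config")
}

# per-coordinate search-space transform
de_transform <- function(bounds) {
  lg <- bounds$lower > 0 & bounds$upper / bounds$lower >= 10
  list(log = lg,
       lo = ifelse(lg, log10(bounds$lower), bounds$lower),
       hi = ifelse(lg, log10(bounds$upper), bounds$upper))
}

de_from_t <- function(x, tr) ifelse(tr$log, 10^x, x)

reflect_into <- function(x, lo, hi) {
  for (i in 1:50) {
    below <- x < lo; above <- x > hi
    if (!any(below) && !any(above)) break
    x[below] <- 2 * lo[below] - x[below]
    x[above] <- 2 * hi[above] - x[above]
  }
  pmin(pmax(x, lo), hi)
}

#' Initialize a DE population
#'
#' Each individual is sampled independently and uniformly in the search
#' space: log-uniform between the bounds on the original scale, or plain
#' uniform for coordinates spanning less than one decade.
#'
#' @param bounds data.frame (`name`, `lower`, `upper`).
#' @param config A `de_config` (its `seed` is applied if non-`NULL`).
#' @return `pop_size` x d matrix on the original scale, columns named.
#' @export
init_population <- function(bounds, config = de_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  tr <- de_transform(bounds)
  d <- nrow(bounds)
  xt <- matrix(stats::runif(config$pop_size * d), config$pop_size, d)
  xt <- sweep(sweep(xt, 2, tr$hi - tr$lo, "*"), 2, tr$lo, "+")
  x <- xt
  for (j in seq_len(d)) if (tr$log[j]) x[, j] <- 10^xt[, j]
  colnames(x) <- bounds$name
  x
}

#' One DE generation (rand/1/bin, greedy selection)
#'
#' @param pop Population matrix on the original scale (rows: individuals).
#' @param fit Objective values of `pop`.
#' @param objective Function of a named parameter vector.
#' @param bounds data.frame (`name`, `lower`, `upper`) matching `pop` columns.
#' @param config A `de_config` (`f`, `cr` used).
#' @return list with updated `pop`, `fit`, and `n_eval` (new evaluations).
#' @export
de_generation <- function(pop, fit, objective, bounds, config = de_config()) {
  np <- nrow(pop)
  if (np < 4) stop("population must have at least 4 members")
  tr <- de_transform(bounds)
  d <- ncol(pop)
  xt <- pop
  for (j in seq_len(d)) if (tr$log[j]) xt[, j] <- log10(pop[, j])
  new_xt <- xt; new_fit <- fit
  for (i in seq_len(np)) {
    r <- sample(setdiff(seq_len(np), i), 3)
    mutant <- xt[r[1], ] + config$f * (xt[r[2], ] - xt[r[3], ])
    mutant <- reflect_into(mutant, tr$lo, tr$hi)
    cross <- stats::runif(d) < config$cr
    cross[sample.int(d, 1)] <- TRUE
    trial <- xt[i, ]
    trial[cross] <- mutant[cross]
    cand <- de_from_t(trial, tr)
    names(cand) <- bounds$name
    fc <- objective(cand)
    if (fc <= fit[i]) { new_xt[i, ] <- trial; new_fit[i] <- fc }
  }
  new_pop <- new_xt
  for (j in seq_len(d)) if (tr$log[j]) new_pop[, j] <- 10^new_xt[, j]
  colnames(new_pop) <- bounds$name
  list(pop = new_pop, fit = new_fit, n_eval = np)
}

#' Minimize an objective by differential evolution
#'
#' @param objective Function of a named parameter vector (original scale).
#' @param bounds data.frame (`name`, `lower`, `upper`).
#' @param config A `de_config`.
#' @param init Optional starting population (matrix, original scale); rows
#'   beyond `pop_size` are ignored, missing rows are drawn as in
#'   [init_population()].
#' @return A `cascade_fit`: `theta` (best point), `value`, non-increasing
#'   per-generation `history`, `n_eval`, `seed`.
#' @export
de_optim <- function(objective, bounds, config = de_config(), init = NULL) {
  if (any(bounds$lower >= bounds$upper))
    stop("infeasible bounds for: ",
         paste(bounds$name[bounds$lower >= bounds$upper], collapse = ", "))
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg0 <- config; cfg0$seed <- NULL
  pop <- init_population(bounds, cfg0)
  if (!is.null(init)) {
    k <- min(nrow(init), nrow(pop))
    pop[seq_len(k), ] <- init[seq_len(k), colnames(pop), drop = FALSE]
  }
  fit <- apply(pop, 1, function(x) objective(stats::setNames(x, bounds$name)))
  n_eval <- length(fit)
  history <- numeric(config$generations)
  best <- min(fit)
  for (g in seq_len(config$generations)) {
    step <- de_generation(pop, fit, objective, bounds, config)
    pop <- step$pop; fit <- step$fit; n_eval <- n_eval + step$n_eval
    best <- min(best, min(fit))
    history[g] <- best
    if (!is.null(config$tol) && best <= config$tol) {
      history <- history[seq_len(g)]
      break
    }
  }
  i <- which.min(fit)
  structure(list(theta = stats::setNames(pop[i, ], bounds$name),
                 value = fit[i], history = history, n_eval = n_eval,
                 seed = config$seed), class = "cascade_fit")
}

#' @export
print.cascade_fit <- function(x, ...) {
  cat(sprintf("cascade_fit: best objective %.6g after %d evaluations\n",
              x$value, x$n_eval))
  invisible(x)
}

#' Maximum-likelihood fit of a calibration problem
#'
#' Minimizes `F = Fquant + Fqual` over the free parameters by differential
#' evolution; all other parameters stay at `pinned`.
#'
#' @param problem A `cascade_problem`.
#' @param free Names of adjustable parameters (subset of `bounds$name`).
#' @param bounds Box constraints, default [optim_bounds()].
#' @param pinned Full parameter vector supplying fixed values,
#'   default `make_theta()`.
#' @param config A `de_config`.  With `n_runs > 1`, independent seeded runs
#'   are performed (seeds `seed`, `seed + 1`, ...).
#' @return A `cascade_fit`; for multistart, a `cascade_fit_multi` with all
#'   `runs`, the `best` run index, and the best run's fields promoted.
#' @export
fit_cascade <- function(problem, free = optim_bounds()$name,
                        bounds = optim_bounds(), pinned = make_theta(),
                        config = de_config()) {
  bad <- intersect(free, fixed_param_names())
  if (length(bad) > 0)
    stop("parameters fixed by design cannot be adjusted: ",
         paste(bad, collapse = ", "))
  b <- bounds[match(free, bounds$name), ]
  if (anyNA(b$lower)) stop("no bounds for: ",
                           paste(free[is.na(b$lower)], collapse = ", "))
  obj <- function(x) {
    theta <- pinned
    theta[names(x)] <- x
    total_objective(theta, problem)
  }
  if (config$n_runs <= 1) {
    res <- de_optim(obj, b, config)
    res$free <- free
    return(res)
  }
  seeds <- if (is.null(config$seed)) rep(list(NULL), config$n_runs)
           else as.list(config$seed + seq_len(config$n_runs) - 1L)
  runs <- lapply(seq_len(config$n_runs), function(i) {
    cfg <- config; cfg$seed <- seeds[[i]]; cfg$n_runs <- 1
    r <- de_optim(obj, b, cfg)
    r$label <- paste0("run", i)
    r
  })
  best <- which.min(vapply(runs, `[[`, numeric(1), "value"))
  out <- runs[[best]]
  out$runs <- runs
  out$best <- best
  out$free <- free
  class(out) <- c("cascade_fit_multi", "cascade_fit")
  out
}
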