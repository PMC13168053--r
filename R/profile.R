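# Profile likelihood: re-minimize the objective along a grid of fixed values
# for one parameter, sweeping outward from the MLE with warm starts, then
# classify practical identifiability from the sub-threshold region.

profile_grid <- function(lower, upper, n = 20) {
  if (lower > 0 && upper / lower >= 10) 10^seq(log10(lower), log10(upper),
                                               length.out = n)
  else seq(lower, upper, length.out = n)
}

#' Profile an arbitrary objective along one coordinate
#'
#' @param objective Function of a named parameter vector.
#' @param bounds data.frame (`name`, `lower`, `upper`) of all free parameters.
#' @param name Coordinate to profile.
#' @param grid Grid of fixed values; default 20 points log-spaced across the
#'   coordinate's bounds.
#' @param config `de_config` for the reduced optimizations.
#' @param center Named vector to warm-start from (e.g. an MLE); optional.
#' @return list with `grid`, minimized `value` per grid point, and the
#'   minimizing parameter vectors (`argmin`, rows matching `grid`).
#' @export
profile_objective <- function(objective, bounds, name, grid = NULL,
                              config = de_config(pop_size = 15,
                                                 generations = 40),
                              center = NULL) {
  i <- match(name, bounds$name)
  if (is.na(i)) stop("unknown parameter: ", name)
  if (is.null(grid)) grid <- profile_grid(bounds$lower[i], bounds$upper[i])
  if (length(grid) == 0) stop("empty profile grid")
  others <- bounds[-i, , drop = FALSE]
  grid <- sort(grid)

  solve_point <- function(v, warm) {
    obj_red <- function(x) objective(c(stats::setNames(v, name), x))
    if (nrow(others) == 0) {
      val <- obj_red(stats::setNames(numeric(0), character(0)))
      return(list(value = val, theta = stats::setNames(v, name)))
    }
    init <- NULL
    if (!is.null(warm))
      init <- matrix(warm[others$name], 1,
                     dimnames = list(NULL, others$name))
    res <- de_optim(obj_red, others, config, init = init)
    list(value = res$value,
         theta = c(stats::setNames(v, name), res$theta))
  }

  start <- if (is.null(center) || is.na(center[name])) which.min(grid)
           else which.min(abs(grid - center[name]))
  values <- numeric(length(grid))
  argmin <- vector("list", length(grid))
  warm0 <- if (is.null(center)) NULL else center
  # sweep up from the start, then down, warm-starting from the neighbor
  warm <- warm0
  for (g in start:length(grid)) {
    sol <- solve_point(grid[g], warm)
    values[g] <- sol$value; argmin[[g]] <- sol$theta; warm <- sol$theta
  }
  warm <- if (is.null(argmin[[start]])) warm0 else argmin[[start]]
  if (start > 1) for (g in (start - 1):1) {
    sol <- solve_point(grid[g], warm)
    values[g] <- sol$value; argmin[[g]] <- sol$theta; warm <- sol$theta
  }
  list(grid = grid, value = values, argmin = argmin)
}

#' Profile-likelihood curve of one model parameter
#'
#' Holds `name` fixed at each grid value and re-minimizes
#' `F = Fquant + Fqual` over the remaining free parameters (differential
#' evolution, warm-started outward from the MLE).
#'
#' @param name Parameter to profile.
#' @param problem A `cascade_problem`.
#' @param free All adjustable parameter names (including `name`).
#' @param bounds Box constraints, default [optim_bounds()].
#' @param pinned Full parameter vector for non-adjustable entries.
#' @param mle Optional `cascade_fit` (or named vector) used as warm start and
#'   as the global-minimum reference; if missing, the profile minimum serves.
#' @param grid,config Passed to [profile_objective()].
#' @return A `profile_curve`: `parameter`, `grid`, objective `value`,
#'   per-point `Fquant` and `qual_nll`, `n` (data count), `mle_value` and
#'   `mle_objective`.
#' @export
profile_parameter <- function(name, problem, free = c("d3", "u3"),
                              bounds = optim_bounds(), pinned = make_theta(),
                              mle = NULL, grid = NULL,
                              config = de_config(pop_size = 15,
                                                 generations = 40)) {
  if (!(name %in% free)) stop("profiled parameter must be in the free set")
  b <- bounds[match(free, bounds$name), ]
  obj <- function(x) {
    theta <- pinned; theta[names(x)] <- x
    total_objective(theta, problem)
  }
  center <- if (inherits(mle, "cascade_fit")) mle$theta else mle
  pr <- profile_objective(obj, b, name, grid = grid, config = config,
                          center = center)
  bd <- lapply(pr$argmin, function(th) {
    theta <- pinned; theta[names(th)] <- th
    objective_breakdown(theta, problem)
  })
  mle_value <- if (!is.null(center)) unname(center[name])
               else pr$grid[which.min(pr$value)]
  mle_objective <- if (inherits(mle, "cascade_fit")) mle$value
                   else min(pr$value)
  structure(list(parameter = name, grid = pr$grid, value = pr$value,
                 Fquant = vapply(bd, `[[`, numeric(1), "Fquant"),
                 qual_nll = vapply(bd, `[[`, numeric(1), "qual_nll"),
                 n = if (is.null(problem$qidx)) 0L else length(problem$qidx$y),
                 mle_value = mle_value, mle_objective = mle_objective,
                 argmin = pr$argmin),
            class = "profile_curve")
}

#' @export
print.profile_curve <- function(x, ...) {
  cat(sprintf("profile_curve[%s]: %d grid points, objective in [%.4g, %.4g]\n",
              x$parameter, length(x$grid), min(x$value), max(x$value)))
  invisible(x)
}

#' Classify practical identifiability from a profile curve
#'
#' Converts the objective to the negative log-likelihood scale using the
#' plug-in noise estimate `sigma2 = Fquant(MLE)/n` (Gaussian part) plus the
#' logistic qualitative term, then takes the sub-threshold region
#' `{grid : nll <= min(nll) + delta}` as the profile confidence set.  The
#' parameter is practically identifiable iff that region excludes both grid
#' endpoints (i.e. is bounded away from the box bounds).
#'
#' @param curve A `profile_curve`.
#' @param delta Threshold on the -log L scale; default 1.92
#'   (chi-square(1) 95% / 2).
#' @return list: `identifiable`, `ci` (range of the sub-threshold grid),
#'   `ci_log10_width`, `nll` values, `delta`.
#' @export
classify_identifiability <- function(curve, delta = 1.92) {
  if (length(curve$grid) < 3) stop("need at least 3 grid points")
  n <- curve$n
  if (n > 0) {
    i_min <- which.min(curve$value)
    sigma2 <- max(curve$Fquant[i_min] / n, .Machine$double.eps)
    nll <- n / 2 * log(2 * pi * sigma2) + curve$Fquant / (2 * sigma2) +
      curve$qual_nll
  } else {
    nll <- curve$qual_nll
  }
  inside <- which(nll <= min(nll) + delta)
  ci <- range(curve$grid[inside])
  identifiable <- !(1L %in% inside) && !(length(curve$grid) %in% inside)
  list(identifiable = identifiable, ci = ci,
       ci_log10_width = if (all(ci > 0)) diff(log10(ci)) else NA_real_,
       nll = nll, delta = delta)
}
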