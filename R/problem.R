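# A calibration problem bundles networks, quantitative records, and
# qualitative statements, with the index bookkeeping needed to evaluate the
# objective from one simulation per variant per parameter vector.

#' Assemble a calibration problem
#'
#' Precomputes, for each needed variant, the union time grid of all
#' quantitative records and property conditions (times must coincide with
#' grid points; no interpolation), so that one simulation per variant serves
#' every record and statement.
#'
#' @param data Long quantitative dataset from [quant_dataset()], or `NULL`.
#' @param props A `property_set`, or `NULL`.
#' @param rtol,atol Integration tolerances used for objective evaluations.
#' @return A `cascade_problem`.
#' @export
cascade_problem <- function(data = NULL, props = NULL,
                            rtol = 1e-6, atol = 1e-2) {
  times <- stats::setNames(vector("list", length(variant_ids())),
                           variant_ids())
  if (!is.null(data)) {
    for (v in unique(data$variant))
      times[[v]] <- c(times[[v]], data$time[data$variant == v])
  }
  if (!is.null(props) && length(props) > 0) {
    pt <- property_times(props)
    for (v in names(pt)) times[[v]] <- c(times[[v]], pt[[v]])
  }
  times <- Filter(length, lapply(times, function(tt) sort(unique(tt))))
  variants <- names(times)
  networks <- lapply(variants, build_network)
  names(networks) <- variants

  qidx <- NULL
  if (!is.null(data)) {
    ok <- !is.na(data$value)
    sm <- scale_map()
    qidx <- list(
      y = data$value[ok],
      variant = data$variant[ok],
      row = vapply(seq_len(sum(ok)), function(i)
        match(data$time[ok][i], times[[data$variant[ok][i]]]), 1L),
      col = match(data$observable[ok], observable_names()),
      scale = unname(sm[data$observable[ok]]))
    if (anyNA(qidx$scale))
      stop("no scaling factor defined for observable(s): ",
           paste(unique(data$observable[ok][is.na(qidx$scale)]), collapse = ", "))
  }

  pidx <- NULL
  if (!is.null(props) && length(props) > 0) {
    side <- function(getter) list(
      variant = vapply(props$props, function(p) getter(p)$variant, ""),
      row = vapply(props$props, function(p)
        match(getter(p)$time, times[[getter(p)$variant]]), 1L),
      col = vapply(props$props, function(p)
        match(getter(p)$observable, observable_names()), 1L))
    pidx <- list(
      left = side(function(p) p$left), right = side(function(p) p$right),
      z = vapply(props$props, `[[`, integer(1), "z"),
      s = vapply(props$props, `[[`, numeric(1), "s"),
      w = vapply(props$props, `[[`, numeric(1), "w"))
  }

  # per-variant linear gather indices for fast prediction assembly
  gather <- function(variant, row, col) {
    lapply(stats::setNames(variants, variants), function(v) {
      pos <- which(variant == v)
      list(pos = pos, lin = row[pos] + (col[pos] - 1L) * length(times[[v]]))
    })
  }
  qgather <- if (is.null(qidx)) NULL else gather(qidx$variant, qidx$row, qidx$col)
  lgather <- if (is.null(pidx)) NULL else
    gather(pidx$left$variant, pidx$left$row, pidx$left$col)
  rgather <- if (is.null(pidx)) NULL else
    gather(pidx$right$variant, pidx$right$row, pidx$right$col)

  structure(list(
    variants = variants, times = times, networks = networks,
    data = data, props = props, qidx = qidx, pidx = pidx,
    qgather = qgather, lgather = lgather, rgather = rgather,
    rtol = rtol, atol = atol,
    counter = local({ e <- new.env(); e$n_eval <- 0L; e$n_fail <- 0L; e })
  ), class = "cascade_problem")
}

#' @export
print.cascade_problem <- function(x, ...) {
  cat(sprintf(
    "cascade_problem: %d quantitative record(s), %d statement(s), variants: %s\n",
    if (is.null(x$qidx)) 0L else length(x$qidx$y),
    if (is.null(x$pidx)) 0L else length(x$pidx$z),
    paste(x$variants, collapse = ", ")))
  invisible(x)
}

# One simulation per variant; returns list of observable matrices, or NULL on
# integration failure (failure counter incremented, objective becomes +Inf).
problem_obsmats <- function(problem, theta) {
  problem$counter$n_eval <- problem$counter$n_eval + 1L
  out <- vector("list", length(problem$variants))
  names(out) <- problem$variants
  for (v in problem$variants) {
    st <- tryCatch(
      sim_states(problem$networks[[v]], theta, problem$times[[v]],
                 rtol = problem$rtol, atol = problem$atol),
      error = function(e) NULL)
    if (is.null(st)) {
      problem$counter$n_fail <- problem$counter$n_fail + 1L
      warning("simulation failed for variant ", v,
              "; objective set to +Inf", call. = FALSE)
      return(NULL)
    }
    out[[v]] <- st %*% problem$networks[[v]]$obs_weights
  }
  out
}

# Scaled quantitative predictions f(c_i, theta) and raw qualitative
# differences delta_i from one set of observable matrices.
problem_predict <- function(problem, theta, obsmats = NULL) {
  if (is.null(obsmats)) obsmats <- problem_obsmats(problem, theta)
  if (is.null(obsmats)) return(NULL)
  gather <- function(g, n) {
    out <- numeric(n)
    for (v in names(g)) {
      if (length(g[[v]]$pos))
        out[g[[v]]$pos] <- obsmats[[v]][g[[v]]$lin]
    }
    out
  }
  f <- NULL
  if (!is.null(problem$qidx)) {
    q <- problem$qidx
    f <- as.numeric(theta[q$scale]) * gather(problem$qgather, length(q$y))
  }
  delta <- NULL
  if (!is.null(problem$pidx)) {
    m <- length(problem$pidx$z)
    delta <- gather(problem$lgather, m) - gather(problem$rgather, m)
  }
  list(f = f, delta = delta)
}

#' Model output for a single measurement condition
#'
#' The observable's copy number multiplied by its scaling factor (qualitative
#' comparisons use raw copy numbers and do not go through this).
#'
#' @param theta Full named parameter vector including scaling factors.
#' @param condition list with `variant`, `observable`, `time`.
#' @param rtol,atol Integration tolerances.
#' @return Scalar prediction f(c, theta).
#' @export
model_output <- function(theta, condition, rtol = 1e-8, atol = 1e-2) {
  sname <- scale_map()[condition$observable]
  if (is.na(sname)) stop("no scaling factor for observable ",
                         condition$observable)
  net <- build_network(condition$variant)
  traj <- simulate_cascade(net, theta, condition$time, rtol = rtol, atol = atol)
  as.numeric(theta[sname]) * traj$observables[1, condition$observable]
}

#' Objective breakdown F = Fquant + Fqual at a parameter vector
#'
#' @param theta Full named parameter vector (model parameters plus scaling
#'   factors; `sigma` ignored here).
#' @param problem A `cascade_problem`.
#' @return list with `Fquant`, `Fqual`, `total`, per-record `residuals2`,
#'   per-statement `penalties` and `delta`, the logistic negative
#'   log-likelihood `qual_nll`, and the non-missing count `n`.  A failed
#'   simulation yields `total = Inf`.
#' @export
objective_breakdown <- function(theta, problem) {
  pred <- problem_predict(problem, theta)
  if (is.null(pred))
    return(list(Fquant = Inf, Fqual = Inf, total = Inf, residuals2 = NULL,
                penalties = NULL, delta = NULL, qual_nll = Inf, n = 0L))
  res2 <- pen <- numeric(0)
  qnll <- 0
  if (!is.null(pred$f)) res2 <- (problem$qidx$y - pred$f)^2
  if (!is.null(pred$delta)) {
    p <- problem$pidx
    pen <- qual_penalty(pred$delta, p$z, p$w, terms = TRUE)
    qnll <- qual_nll(pred$delta, p$s, p$z)
  }
  Fquant <- sum(res2); Fqual <- sum(pen)
  list(Fquant = Fquant, Fqual = Fqual, total = Fquant + Fqual,
       residuals2 = res2, penalties = pen, delta = pred$delta,
       qual_nll = qnll, n = length(res2))
}

#' Total objective F(theta)
#' @inheritParams objective_breakdown
#' @return Scalar `Fquant + Fqual` (`Inf` on simulation failure).
#' @export
total_objective <- function(theta, problem) {
  objective_breakdown(theta, problem)$total
}

#' Exact negative log-likelihood (Gaussian + logistic)
#'
#' @inheritParams objective_breakdown
#' @param sigma Quantitative noise scale; defaults to `theta["sigma"]`.
#' @return Scalar -log L(theta | y, z).
#' @export
neg_log_lik <- function(theta, problem, sigma = theta[["sigma"]]) {
  pred <- problem_predict(problem, theta)
  if (is.null(pred)) return(Inf)
  out <- 0
  if (!is.null(pred$f)) out <- out + gaussian_nll(problem$qidx$y, pred$f, sigma)
  if (!is.null(pred$delta))
    out <- out + qual_nll(pred$delta, problem$pidx$s, problem$pidx$z)
  out
}

#' Log-posterior over a sampled parameter subset
#'
#' Non-sampled parameters are held at `pinned`; the prior is uniform (flat)
#' inside the box and the log-posterior is `-Inf` outside.
#'
#' @param theta_sampled Named vector covering exactly `prior$name`.
#' @param problem A `cascade_problem`.
#' @param prior data.frame (`name`, `lower`, `upper`), e.g. [bayes_bounds()].
#' @param pinned Full named parameter vector supplying non-sampled values.
#' @return Scalar log-posterior (up to the normalizing constant of the data).
#' @export
log_posterior <- function(theta_sampled, problem, prior, pinned) {
  if (!setequal(names(theta_sampled), prior$name))
    stop("theta_sampled must cover exactly the prior parameters")
  x <- theta_sampled[prior$name]
  if (any(x < prior$lower) || any(x > prior$upper)) return(-Inf)
  theta <- pinned
  theta[prior$name] <- x
  lp_prior <- -sum(log(prior$upper - prior$lower))
  nll <- neg_log_lik(theta, problem, sigma = theta[["sigma"]])
  -nll + lp_prior
}

#' Simulate all problem variants at a parameter vector
#'
#' @inheritParams objective_breakdown
#' @param rtol,atol Tolerances (default: the problem's).
#' @return Named list of `cascade_trajectory` keyed by variant, suitable for
#'   [evaluate_property()] and [count_satisfied()].
#' @export
problem_trajectories <- function(theta, problem, rtol = problem$rtol,
                                 atol = problem$atol) {
  out <- lapply(problem$variants, function(v) {
    st <- sim_states(problem$networks[[v]], theta, problem$times[[v]],
                     rtol = rtol, atol = atol)
    as_trajectory(problem$networks[[v]], problem$times[[v]], st)
  })
  stats::setNames(out, problem$variants)
}
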