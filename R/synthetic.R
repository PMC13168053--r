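# Study-shaped synthetic data from known ground truth: 18 quantitative
# relative-intensity records (WT only; Gaussian noise on the scaled outputs,
# then max-normalization into (0,1]) and 90 binary comparison statements
# across the five variants at 300/1800/3600 s (deterministic sign of the
# true difference, or Bernoulli draws through the logistic link).

#' Ground-truth record for synthetic data
#'
#' @param theta Full parameter vector (model parameters + scaling factors),
#'   e.g. [make_theta()].
#' @param sigma True quantitative noise scale (AU), default 1.
#' @param s Logistic scale for qualitative statements, default 1.
#' @param check Verify that adjustable coordinates lie inside the
#'   optimization bounds (default TRUE).
#' @return list (class `ground_truth`) with `theta`, `sigma`, `s`.
#' @export
ground_truth <- function(theta = make_theta(), sigma = 1, s = 1,
                         check = TRUE) {
  if (check) {
    b <- optim_bounds()
    v <- theta[b$name]
    bad <- b$name[v < b$lower | v > b$upper]
    if (length(bad) > 0)
      stop("ground truth outside optimization bounds: ",
           paste(bad, collapse = ", "))
  }
  structure(list(theta = theta, sigma = sigma, s = s),
            class = "ground_truth")
}

#' Default measurement time grid for synthetic quantitative data
#'
#' Six times spanning the rise, peak, and relaxation of the stimulated
#' cascade over one hour.
#' @return Numeric vector (s).
#' @export
default_quant_times <- function() c(60, 300, 600, 1200, 1800, 3600)

#' Generate a quantitative dataset from ground truth
#'
#' Simulates WT at the true parameters, applies the true scaling factors,
#' adds N(0, sigma^2) noise, then rescales each observable series by its
#' maximum so values lie in (0, 1] (floored at 1e-6).  The per-observable
#' normalization constants are returned so that the effective ground truth
#' (scaling factors divided by the constants) reproduces the data exactly
#' when `sigma = 0`.
#'
#' @param truth A [ground_truth()].
#' @param times Measurement times, default [default_quant_times()].
#' @param observables Scaled observables to measure (default all three).
#' @param n_missing Number of records replaced by missing values (`nan`).
#' @param rtol,atol Integration tolerances.
#' @return list: `exp` (wide EXP-style table), `data` (long dataset from
#'   [quant_dataset()]), `norm` (per-observable maxima), `effective_theta`
#'   (truth with normalized scaling factors), `effective_sigma`
#'   (per-observable noise scale after normalization).
#' @export
gen_quant <- function(truth, times = default_quant_times(),
                      observables = c("pEGFR", "pSOS1", "pERK1_2_wt"),
                      n_missing = 0, rtol = 1e-8, atol = 1e-2) {
  sm <- scale_map()
  stopifnot(all(observables %in% names(sm)))
  net <- build_network("WT")
  traj <- simulate_cascade(net, truth$theta, times, rtol = rtol, atol = atol)
  exp_tab <- data.frame(time = times)
  norm <- stats::setNames(numeric(length(observables)), observables)
  for (o in observables) {
    raw <- truth$theta[[sm[o]]] * traj$observables[[o]]
    noisy <- raw + stats::rnorm(length(raw), 0, truth$sigma)
    m <- max(noisy)
    if (m <= 0) stop("noise overwhelms the signal for observable ", o)
    exp_tab[[o]] <- pmax(noisy / m, 1e-6)
    norm[o] <- m
  }
  if (n_missing > 0) {
    cells <- expand.grid(row = seq_along(times), obs = observables,
                         stringsAsFactors = FALSE)
    drop <- cells[sample.int(nrow(cells), n_missing), ]
    for (i in seq_len(nrow(drop)))
      exp_tab[drop$row[i], drop$obs[i]] <- NA
  }
  eff <- truth$theta
  eff[sm[observables]] <- eff[sm[observables]] / norm[observables]
  list(exp = exp_tab, data = quant_dataset(exp_tab, variant = "WT"),
       norm = norm, effective_theta = eff,
       effective_sigma = truth$sigma / norm)
}

#' Default comparison templates (90 statements)
#'
#' 60 cross-variant comparisons (all 10 variant pairs, at 300/1800/3600 s,
#' for `MEK_pRDS` and `pERK1_2_wt`) plus 30 within-variant time comparisons
#' (each variant and observable, the three time pairs).
#'
#' @return data.frame with columns `l_variant`, `l_obs`, `l_time`,
#'   `r_variant`, `r_obs`, `r_time`.
#' @export
default_templates <- function() {
  vs <- variant_ids()
  obs <- c("MEK_pRDS", "pERK1_2_wt")
  tps <- c(300, 1800, 3600)
  cross <- do.call(rbind, lapply(seq_len(length(vs) - 1), function(i) {
    do.call(rbind, lapply((i + 1):length(vs), function(j) {
      expand.grid(l_variant = vs[i], l_obs = obs, l_time = tps,
                  r_variant = vs[j], stringsAsFactors = FALSE)
    }))
  }))
  cross$r_obs <- cross$l_obs
  cross$r_time <- cross$l_time
  pairs <- rbind(c(300, 1800), c(300, 3600), c(1800, 3600))
  within <- do.call(rbind, lapply(vs, function(v) {
    do.call(rbind, lapply(obs, function(o) {
      data.frame(l_variant = v, l_obs = o, l_time = pairs[, 1],
                 r_variant = v, r_obs = o, r_time = pairs[, 2],
                 stringsAsFactors = FALSE)
    }))
  }))
  rbind(cross[, names(within)], within)
}

#' Generate a qualitative property set from ground truth
#'
#' Evaluates the true model-output difference for each template.  In
#' `deterministic` mode the observed outcome is the Heaviside sign of the
#' true difference (so the truth satisfies every statement); in `stochastic`
#' mode outcomes are Bernoulli draws with the logistic probability at scale
#' `truth$s`.
#'
#' @param truth A [ground_truth()].
#' @param templates Comparison templates, default [default_templates()].
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param rtol,atol Integration tolerances.
#' @return A `property_set`.
#' @export
gen_qual <- function(truth, templates = default_templates(),
                     mode = c("deterministic", "stochastic"),
                     rtol = 1e-8, atol = 1e-2) {
  mode <- match.arg(mode)
  stopifnot(all(c(templates$l_obs, templates$r_obs) %in% observable_names()))
  variants <- unique(c(templates$l_variant, templates$r_variant))
  trajs <- lapply(variants, function(v) {
    tt <- sort(unique(c(templates$l_time[templates$l_variant == v],
                        templates$r_time[templates$r_variant == v])))
    simulate_cascade(build_network(v), truth$theta, tt, rtol = rtol,
                     atol = atol)
  })
  names(trajs) <- variants
  val <- function(v, o, t) {
    tr <- trajs[[v]]
    tr$observables[match(t, tr$time), o]
  }
  lines <- character(nrow(templates))
  for (i in seq_len(nrow(templates))) {
    delta <- val(templates$l_variant[i], templates$l_obs[i], templates$l_time[i]) -
             val(templates$r_variant[i], templates$r_obs[i], templates$r_time[i])
    z <- if (mode == "deterministic") as.integer(delta >= 0)
         else stats::rbinom(1, 1, logistic_prob(delta, truth$s))
    op <- if (z == 1L) ">=" else "<"
    lines[i] <- sprintf("%s.%s at time=%s %s %s.%s at time=%s",
                        templates$l_variant[i], templates$l_obs[i],
                        format(templates$l_time[i], scientific = FALSE),
                        op,
                        templates$r_variant[i], templates$r_obs[i],
                        format(templates$r_time[i], scientific = FALSE))
  }
  property_set(lapply(lines, parse_property, scale = truth$s),
               provenance = paste0("synthetic-", mode))
}

#' Generate a full study-shaped synthetic bundle
#'
#' Five variant models, 18 quantitative WT measurements, 90 comparison
#' statements, and a manifest sufficient for exact regeneration.
#'
#' @param seed Integer seed driving all randomness.
#' @param truth A [ground_truth()]; its `sigma` and `s` set the noise models.
#' @param qual_mode `"deterministic"` or `"stochastic"` statement outcomes.
#' @param times Quantitative measurement times.
#' @param n_missing Missing quantitative records to inject.
#' @return A `cascade_bundle`: `exp`, `data`, `props`, `truth`,
#'   `truth_effective` (scaling factors on the normalized data scale),
#'   `manifest`.
#' @export
make_bundle <- function(seed = 1, truth = ground_truth(),
                        qual_mode = "deterministic",
                        times = default_quant_times(), n_missing = 0) {
  set.seed(seed)
  q <- gen_quant(truth, times = times, n_missing = n_missing)
  props <- gen_qual(truth, mode = qual_mode)
  manifest <- list(seed = seed, theta = as.list(truth$theta),
                   sigma = truth$sigma, s = truth$s, qual_mode = qual_mode,
                   times = times, n_missing = n_missing,
                   norm = as.list(q$norm),
                   effective_sigma = as.list(q$effective_sigma))
  structure(list(exp = q$exp, data = q$data, props = props, truth = truth,
                 truth_effective = ground_truth(q$effective_theta,
                                                sigma = truth$sigma,
                                                s = truth$s, check = FALSE),
                 manifest = manifest),
            class = "cascade_bundle")
}

#' @export
print.cascade_bundle <- function(x, ...) {
  cat(sprintf(
    "cascade_bundle: %d quantitative records (%d missing), %d statements (%s)\n",
    nrow(x$data), sum(is.na(x$data$value)), length(x$props),
    x$manifest$qual_mode))
  invisible(x)
}

#' Write a bundle as EXP/PROP/manifest files
#'
#' @param bundle A `cascade_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(exp = file.path(dir, "WT.exp"),
             prop = file.path(dir, "synthetic.prop"),
             manifest = file.path(dir, "manifest.json"))
  write_exp(bundle$exp, paths["exp"])
  write_prop(bundle$props, paths["prop"])
  jsonlite::write_json(bundle$manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Bayesian prior box matched to a synthetic bundle
#'
#' Max-normalization pins the effective scaling factor of each observable to
#' roughly 1/(peak copy number), which need not fall inside the absolute
#' scale boxes used with the published relative-intensity data.  For
#' posterior analyses of synthetic bundles this returns [bayes_bounds()] with
#' each scaling-factor box re-centered (geometrically) on the bundle's
#' effective scale, keeping the default box's multiplicative width; the
#' `d3`, `u3`, and `sigma` boxes are unchanged.
#'
#' @param bundle A `cascade_bundle`.
#' @return data.frame (`name`, `lower`, `upper`).
#' @export
bundle_bayes_bounds <- function(bundle) {
  b <- bayes_bounds()
  eff <- bundle$truth_effective$theta
  for (i in which(b$name %in% scale_map())) {
    r <- sqrt(b$upper[i] / b$lower[i])
    e <- eff[[b$name[i]]]
    b$lower[i] <- e / r
    b$upper[i] <- e * r
  }
  b
}

#' Regenerate a bundle from a written manifest
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `cascade_bundle` regenerated from the manifest's seed and truth.
#' @export
read_bundle <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  truth <- ground_truth(unlist(man$theta), sigma = man$sigma, s = man$s,
                        check = FALSE)
  make_bundle(seed = man$seed, truth = truth, qual_mode = man$qual_mode,
              times = man$times, n_missing = man$n_missing)
}
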