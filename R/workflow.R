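# Run configuration and stage dispatch: a flat key-value text format (one
# `key value...` line each, repeated keys for lists) mapping data files to
# model variants and selecting a pipeline stage.

.config_keys <- c("variant", "exp", "prop", "adjust", "algorithm", "seed",
                  "output_dir", "population", "generations", "mutation",
                  "crossover", "n_runs", "profile_parameter", "grid_points",
                  "burn", "adapt", "production", "chains", "theta", "scale",
                  "sigma", "qual_mode", "times", "n_missing", "study_shaped",
                  "rtol", "atol")

#' Load and validate a run configuration
#'
#' Format: one `key value [value...]` statement per line; `#` comments and
#' blank lines ignored; repeated keys accumulate (`exp`/`prop`/`adjust`/
#' `theta`).  Unknown keys are errors.  Referenced files must exist, adjusted
#' parameter names must be known, bounds must be ordered, and in study-shaped
#' mode (default) only the WT variant may carry an EXP file.
#'
#' @param path Config file path.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  cfg <- list(exp = list(), prop = list(), adjust = NULL, theta = c(),
              algorithm = NULL, seed = 1L, output_dir = ".",
              variants = character(0), study_shaped = TRUE,
              settings = list())
  known_params <- unique(c(names(make_theta()), "sigma"))
  for (i in keep) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tok[1]; args <- tok[-1]
    if (!(key %in% .config_keys))
      stop(sprintf("unknown config key '%s' (line %d)", key, i))
    switch(key,
      variant = { cfg$variants <- c(cfg$variants, match.arg(args[1], variant_ids())) },
      exp = {
        v <- match.arg(args[1], variant_ids())
        if (!file.exists(args[2])) stop("EXP file not found: ", args[2])
        cfg$exp[[v]] <- args[2]
      },
      prop = {
        v <- match.arg(args[1], variant_ids())
        if (!file.exists(args[2])) stop("PROP file not found: ", args[2])
        cfg$prop[[v]] <- c(cfg$prop[[v]], args[2])
      },
      adjust = {
        if (!(args[1] %in% known_params))
          stop(sprintf("unknown adjustable parameter '%s' (line %d)", args[1], i))
        lo <- as.numeric(args[2]); hi <- as.numeric(args[3])
        if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
          stop(sprintf("invalid bounds for '%s': lower must be < upper", args[1]))
        cfg$adjust <- rbind(cfg$adjust,
                            data.frame(name = args[1], lower = lo, upper = hi))
      },
      theta = {
        if (!(args[1] %in% known_params))
          stop(sprintf("unknown parameter '%s' (line %d)", args[1], i))
        cfg$theta[args[1]] <- as.numeric(args[2])
      },
      algorithm = {
        cfg$algorithm <- match.arg(args[1],
                                   c("fit", "profile", "sample", "check", "synth"))
      },
      seed = { cfg$seed <- as.integer(args[1]) },
      output_dir = { cfg$output_dir <- args[1] },
      study_shaped = { cfg$study_shaped <- as.logical(args[1]) },
      times = { cfg$settings$times <- as.numeric(args) },
      { cfg$settings[[key]] <- as.numeric(args[1]) })
  }
  if (is.null(cfg$algorithm)) stop("config must set 'algorithm'")
  if (length(cfg$variants) == 0) cfg$variants <- variant_ids()
  if (cfg$study_shaped && length(cfg$exp) > 0 &&
      !identical(names(cfg$exp), "WT"))
    stop("study-shaped configuration: only the WT variant may carry an EXP file")
  structure(cfg, class = "run_config")
}

config_problem <- function(config) {
  data <- NULL
  for (v in names(config$exp))
    data <- rbind(data, quant_dataset(read_exp(config$exp[[v]]), variant = v))
  props <- NULL
  sc <- if (!is.null(config$settings$scale)) config$settings$scale else 1
  all_props <- list()
  for (v in names(config$prop)) for (f in config$prop[[v]])
    all_props <- c(all_props, read_prop(f, scale = sc)$props)
  if (length(all_props) > 0) props <- property_set(all_props)
  rtol <- if (!is.null(config$settings$rtol)) config$settings$rtol else 1e-6
  atol <- if (!is.null(config$settings$atol)) config$settings$atol else 1e-2
  cascade_problem(data = data, props = props, rtol = rtol, atol = atol)
}

config_theta <- function(config) {
  theta <- make_theta()
  if (!is.null(config$settings$sigma)) theta["sigma"] <- config$settings$sigma
  if (length(config$theta) > 0) theta[names(config$theta)] <- config$theta
  theta
}

setting <- function(config, key, default) {
  v <- config$settings[[key]]
  if (is.null(v)) default else v
}

#' Execute a configured pipeline stage
#'
#' Dispatches to fit / profile / sample / check / synth and writes CSV/JSON
#' artifacts plus a reproducibility manifest (config hash, seed, package
#' version, objective-evaluation counts, wall time) into the configured
#' output directory.
#'
#' @param config A `run_config` from [load_config()], or a path to one.
#' @return Invisibly, a list with the stage `result` and the written `paths`.
#' @export
run_stage <- function(config) {
  if (is.character(config)) {
    cfg_path <- config
    config <- load_config(config)
  } else cfg_path <- NA_character_
  t0 <- Sys.time()
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(config$output_dir)
  theta <- config_theta(config)
  paths <- character(0)
  result <- NULL
  counters <- NULL

  if (config$algorithm == "synth") {
    truth <- ground_truth(theta = theta,
                          sigma = setting(config, "sigma", 1),
                          s = setting(config, "scale", 1), check = FALSE)
    bundle <- make_bundle(seed = config$seed, truth = truth,
                          qual_mode = if (!is.null(config$settings$qual_mode))
                            config$settings$qual_mode else "deterministic",
                          times = setting(config, "times",
                                          default_quant_times()),
                          n_missing = setting(config, "n_missing", 0))
    paths <- write_bundle(bundle, out)
    result <- bundle
  } else {
    problem <- config_problem(config)
    counters <- problem$counter
    if (config$algorithm == "check") {
      bd <- objective_breakdown(theta, problem)
      cs <- if (!is.null(problem$props))
        count_satisfied(problem$props, problem_trajectories(theta, problem))
      else list(n_satisfied = 0L, report = NULL)
      result <- list(breakdown = bd, satisfied = cs$n_satisfied,
                     n_statements = if (is.null(problem$pidx)) 0L
                                    else length(problem$pidx$z),
                     report = cs$report)
      p1 <- file.path(out, "check_summary.json")
      jsonlite::write_json(list(Fquant = bd$Fquant, Fqual = bd$Fqual,
                                total = bd$total,
                                satisfied = cs$n_satisfied,
                                n_statements = result$n_statements),
                           p1, auto_unbox = TRUE, digits = NA)
      paths <- p1
      if (!is.null(cs$report)) {
        p2 <- file.path(out, "check_report.csv")
        utils::write.csv(cs$report, p2, row.names = FALSE)
        paths <- c(paths, p2)
      }
    } else if (config$algorithm == "fit") {
      cfg <- de_config(pop_size = setting(config, "population", 50),
                       generations = setting(config, "generations", 500),
                       f = setting(config, "mutation", 0.85),
                       cr = setting(config, "crossover", 0.7),
                       seed = config$seed,
                       n_runs = setting(config, "n_runs", 1))
      bounds <- if (is.null(config$adjust)) optim_bounds() else config$adjust
      result <- fit_cascade(problem, free = bounds$name, bounds = bounds,
                            pinned = theta, config = cfg)
      runs <- if (inherits(result, "cascade_fit_multi")) result$runs
              else list(result)
      tab <- do.call(rbind, lapply(runs, function(r)
        as.data.frame(as.list(c(r$theta, objective = r$value)))))
      p1 <- file.path(out, "fit_runs.csv")
      utils::write.csv(tab, p1, row.names = FALSE)
      p2 <- file.path(out, "fit_summary.json")
      jsonlite::write_json(list(best_objective = result$value,
                                n_eval = result$n_eval, seed = config$seed,
                                theta = as.list(result$theta)),
                           p2, auto_unbox = TRUE, digits = NA)
      paths <- c(p1, p2)
    } else if (config$algorithm == "profile") {
      pname <- config$settings$profile_parameter
      if (is.null(pname)) stop("profile stage needs 'profile_parameter'")
      bounds <- if (is.null(config$adjust)) optim_bounds() else config$adjust
      cfg <- de_config(pop_size = setting(config, "population", 15),
                       generations = setting(config, "generations", 40),
                       seed = config$seed)
      i <- match(pname, bounds$name)
      if (is.na(i)) stop("profiled parameter not in adjustable set: ", pname)
      grid <- profile_grid(bounds$lower[i], bounds$upper[i],
                           setting(config, "grid_points", 20))
      result <- profile_parameter(pname, problem, free = bounds$name,
                                  bounds = bounds, pinned = theta,
                                  grid = grid, config = cfg)
      verdict <- classify_identifiability(result)
      p1 <- file.path(out, sprintf("profile_%s.csv", pname))
      utils::write.csv(data.frame(value = result$grid,
                                  objective = result$value,
                                  nll = verdict$nll),
                       p1, row.names = FALSE)
      p2 <- file.path(out, sprintf("profile_%s.json", pname))
      jsonlite::write_json(list(parameter = pname,
                                identifiable = verdict$identifiable,
                                ci_lower = verdict$ci[1],
                                ci_upper = verdict$ci[2]),
                           p2, auto_unbox = TRUE, digits = NA)
      paths <- c(p1, p2)
    } else if (config$algorithm == "sample") {
      bounds <- if (is.null(config$adjust)) bayes_bounds() else config$adjust
      cfg <- mcmc_config(burn = setting(config, "burn", 25000),
                         adapt = setting(config, "adapt", 25000),
                         production = setting(config, "production", 250000),
                         chains = setting(config, "chains", 5),
                         seed = config$seed)
      lp <- function(x) log_posterior(x, problem, bounds, pinned = theta)
      result <- run_mcmc(lp, bounds, cfg)
      for (ci in seq_along(result$draws)) {
        pc <- file.path(out, sprintf("chain%d.csv", ci))
        utils::write.csv(data.frame(iteration = seq_len(nrow(result$draws[[ci]])),
                                    result$draws[[ci]],
                                    log_posterior = result$lp[[ci]]),
                         pc, row.names = FALSE)
        paths <- c(paths, pc)
      }
      dg <- mcmc_diagnostics(result)
      p2 <- file.path(out, "diagnostics.json")
      jsonlite::write_json(list(diagnostics = dg,
                                accept = lapply(result$accept, as.list)),
                           p2, auto_unbox = TRUE, digits = NA)
      paths <- c(paths, p2)
      # posterior predictive band CSVs, one per variant
      bt <- setting(config, "times", c(300, 1800, 3600))
      pb <- posterior_predictive(result, times = bt, pinned = theta,
                                 max_draws = 200)
      for (v in names(pb$bands)) {
        tabs <- lapply(observable_names(), function(o) {
          bo <- pb$bands[[v]][[o]]
          lo <- sapply(bo$bands, `[[`, "lower")
          hi <- sapply(bo$bands, `[[`, "upper")
          colnames(lo) <- paste0("lower_", colnames(lo))
          colnames(hi) <- paste0("upper_", colnames(hi))
          data.frame(observable = o, time = bo$time, median = bo$median,
                     lo, hi, check.names = FALSE)
        })
        pv <- file.path(out, sprintf("bands_%s.csv", v))
        utils::write.csv(do.call(rbind, tabs), pv, row.names = FALSE)
        paths <- c(paths, pv)
      }
    }
  }

  manifest <- list(
    algorithm = config$algorithm, seed = config$seed,
    config_md5 = if (!is.na(cfg_path)) unname(tools::md5sum(cfg_path))
                 else NA,
    package_version = as.character(utils::packageVersion("cascadefit")),
    n_objective_evaluations = if (!is.null(counters)) counters$n_eval else 0L,
    n_failed_simulations = if (!is.null(counters)) counters$n_fail else 0L,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  pm <- file.path(out, "run_manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, pm)
  invisible(list(result = result, paths = paths))
}
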