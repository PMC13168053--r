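# Qualitative comparison statements: a small formal language for binary
# observations of the form
#   <variant>.<observable> at time=<t>  <op>  <variant>.<observable> at time=<t>
# with <op> in {<, >, <=, >=} and an optional trailing "weight=<w>".
# The observed outcome is z = 0 for "<"/"<=" and z = 1 for ">"/">=";
# the model prediction is H(delta) with delta = g(left) - g(right) and
# H(0) = 1 (ties satisfy ">=" and violate "<").

.prop_regex <- paste0(
  "^\\s*([A-Za-z0-9_]+)\\.([A-Za-z0-9_]+)\\s+at\\s+time=([0-9eE.+-]+)",
  "\\s*(<=|>=|<|>)\\s*",
  "([A-Za-z0-9_]+)\\.([A-Za-z0-9_]+)\\s+at\\s+time=([0-9eE.+-]+)",
  "(\\s+weight=([0-9eE.+-]+))?\\s*$")

#' Parse one comparison statement
#'
#' @param line Statement text (one line of a PROP file).
#' @param scale Logistic scale s (> 0) attached to the statement; the weight
#'   defaults to `1/scale` unless a `weight=` annotation overrides it.
#' @param line_no Optional line number used in error messages.
#' @return A `comparison_property`: left/right conditions (variant,
#'   observable, time), relation, outcome `z`, scale `s`, weight `w`, source.
#' @export
parse_property <- function(line, scale = 1, line_no = NA) {
  m <- regmatches(line, regexec(.prop_regex, line))[[1]]
  where <- if (is.na(line_no)) "" else sprintf(" (line %d)", line_no)
  if (length(m) == 0)
    stop(sprintf("malformed property%s: %s", where, trimws(line)))
  left  <- list(variant = m[2], observable = m[3], time = as.numeric(m[4]))
  op    <- m[5]
  right <- list(variant = m[6], observable = m[7], time = as.numeric(m[8]))
  for (cond in list(left, right)) {
    if (!(cond$variant %in% variant_ids()))
      stop(sprintf("unknown variant '%s'%s", cond$variant, where))
    if (!(cond$observable %in% observable_names()))
      stop(sprintf("unknown observable '%s'%s", cond$observable, where))
    if (!is.finite(cond$time) || cond$time < 0)
      stop(sprintf("invalid time '%s'%s", cond$time, where))
  }
  w <- if (!is.na(m[10]) && nzchar(m[10])) as.numeric(m[10]) else 1 / scale
  structure(list(left = left, right = right, op = op,
                 z = if (op %in% c(">", ">=")) 1L else 0L,
                 s = scale, w = w, source = trimws(line)),
            class = "comparison_property")
}

#' @export
format.comparison_property <- function(x, ...) {
  fmt_num <- function(t) format(t, scientific = FALSE, trim = TRUE)
  sprintf("%s.%s at time=%s %s %s.%s at time=%s",
          x$left$variant, x$left$observable, fmt_num(x$left$time), x$op,
          x$right$variant, x$right$observable, fmt_num(x$right$time))
}

#' @export
print.comparison_property <- function(x, ...) {
  cat(format(x), sprintf(" [z=%d, s=%g, w=%g]\n", x$z, x$s, x$w))
  invisible(x)
}

#' Construct a property set
#'
#' @param props List of `comparison_property` objects.
#' @param provenance Optional source label (e.g. file name).
#' @return A `property_set` (list with class attribute).
#' @export
property_set <- function(props, provenance = NA_character_) {
  stopifnot(all(vapply(props, inherits, TRUE, "comparison_property")))
  structure(list(props = props, provenance = provenance),
            class = "property_set")
}

#' @export
length.property_set <- function(x) length(x$props)

#' @export
print.property_set <- function(x, ...) {
  cat(sprintf("property_set: %d statements%s\n", length(x$props),
      if (is.na(x$provenance)) "" else paste0(" from ", x$provenance)))
  invisible(x)
}

#' Read a PROP file
#'
#' One statement per line; `#`-prefixed comments and blank lines ignored.
#'
#' @param path File path.
#' @param scale Default logistic scale for all statements.
#' @return A `property_set`.
#' @export
read_prop <- function(path, scale = 1) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  props <- lapply(keep, function(i) parse_property(lines[i], scale = scale,
                                                   line_no = i))
  property_set(props, provenance = basename(path))
}

#' Write a PROP file
#' @param props A `property_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_prop <- function(props, path) {
  writeLines(vapply(props$props, format, character(1)), path)
  invisible(path)
}

# Observable value at one (variant, observable, time) condition.
condition_value <- function(cond, trajectories) {
  traj <- trajectories[[cond$variant]]
  if (is.null(traj)) stop("no trajectory for variant ", cond$variant)
  i <- match(cond$time, traj$time)
  if (is.na(i)) stop(sprintf("time %g not on the %s grid", cond$time,
                             cond$variant))
  traj$observables[i, cond$observable]
}

#' Evaluate one property against simulated trajectories
#'
#' Uses raw (unscaled) copy numbers, the Heaviside convention H(0) = 1, and
#' delta = g(left) - g(right).
#'
#' @param prop A `comparison_property`.
#' @param trajectories Named list of `cascade_trajectory` keyed by variant.
#' @return list with `delta`, `predicted` (H(delta)), and `satisfied`.
#' @export
evaluate_property <- function(prop, trajectories) {
  delta <- condition_value(prop$left, trajectories) -
           condition_value(prop$right, trajectories)
  predicted <- as.integer(delta >= 0)
  list(delta = delta, predicted = predicted,
       satisfied = predicted == prop$z)
}

#' Count satisfied statements
#'
#' @param props A `property_set`.
#' @param trajectories Named list of trajectories keyed by variant.
#' @return list with `n_satisfied` and a per-statement `report` data.frame
#'   (statement, delta, z, predicted, satisfied).
#' @export
count_satisfied <- function(props, trajectories) {
  if (length(props) == 0)
    return(list(n_satisfied = 0L,
                report = data.frame(statement = character(0), delta = numeric(0),
                                    z = integer(0), predicted = integer(0),
                                    satisfied = logical(0))))
  ev <- lapply(props$props, evaluate_property, trajectories = trajectories)
  report <- data.frame(
    statement = vapply(props$props, format, character(1)),
    delta = vapply(ev, `[[`, numeric(1), "delta"),
    z = vapply(props$props, `[[`, integer(1), "z"),
    predicted = vapply(ev, `[[`, integer(1), "predicted"),
    satisfied = vapply(ev, `[[`, logical(1), "satisfied"))
  list(n_satisfied = sum(report$satisfied), report = report)
}

# Times each variant is interrogated at by a property set (for grid building).
property_times <- function(props) {
  out <- stats::setNames(vector("list", length(variant_ids())), variant_ids())
  for (p in props$props) {
    out[[p$left$variant]] <- c(out[[p$left$variant]], p$left$time)
    out[[p$right$variant]] <- c(out[[p$right$variant]], p$right$time)
  }
  lapply(out, function(v) sort(unique(v)))
}
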