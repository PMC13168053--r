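# EXP dialect: UTF-8 whitespace-delimited table, first header token `time`,
# remaining headers observable names, numeric rows, literal `nan` for a
# missing measurement.

#' Read an EXP time-series table
#'
#' @param path File path.
#' @return data.frame with a `time` column and one column per observable;
#'   missing measurements are `NA`.
#' @export
read_exp <- function(path) {
  df <- utils::read.table(path, header = TRUE, na.strings = "nan",
                          check.names = FALSE)
  if (names(df)[1] != "time")
    stop("EXP file must start with a 'time' column: ", path)
  if (any(!vapply(df, is.numeric, TRUE)))
    stop("EXP file has non-numeric entries: ", path)
  df
}

#' Write an EXP time-series table
#' @param df data.frame as returned by [read_exp()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_exp <- function(df, path) {
  txt <- as.matrix(format(df, digits = 15, trim = TRUE, scientific = FALSE))
  txt[is.na(df)] <- "nan"
  lines <- c(paste(colnames(df), collapse = "\t"),
             apply(txt, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Long-format quantitative dataset from an EXP table
#'
#' @param exp_table data.frame from [read_exp()].
#' @param variant Variant the measurements were made in (study shape: WT).
#' @return data.frame (`variant`, `observable`, `time`, `value`) with one row
#'   per table cell; `NA` rows are retained but contribute nothing to the
#'   objective.  Attribute `n` holds the non-missing count.
#' @export
quant_dataset <- function(exp_table, variant = "WT") {
  obs <- setdiff(names(exp_table), "time")
  unknown <- setdiff(obs, observable_names())
  if (length(unknown) > 0)
    stop("unknown observable(s) in EXP table: ", paste(unknown, collapse = ", "))
  long <- do.call(rbind, lapply(obs, function(o) {
    data.frame(variant = variant, observable = o, time = exp_table$time,
               value = exp_table[[o]], stringsAsFactors = FALSE)
  }))
  vals <- long$value[!is.na(long$value)]
  if (length(vals) > 0 && (any(vals <= 0) || any(vals > 1)))
    warning("non-missing quantitative values should lie in (0, 1]")
  attr(long, "n") <- sum(!is.na(long$value))
  long
}
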