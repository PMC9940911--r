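#' Write a trial table as delimited text
#'
#' Tab-separated, one row per trial, with the canonical column schema
#' (`subject`, `condition`, `session`, `trial`, `choice`, `outcome`,
#' `dt_s`, `omitted`).
#'
#' @param trials trial table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(.trial_columns %in% names(trials)))
  write.table(trials[, .trial_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Reads the delimited trial format and enforces the schema: 1-based trial
#' indices, decision times within the response window on responded trials,
#' and no outcome or decision time on omitted trials. Malformed rows are
#' rejected with their row numbers.
#'
#' @param path input path.
#' @param response_window upper bound for valid decision times (seconds,
#'   default 3).
#' @return validated trial data.frame (empty, with a warning, for an empty
#'   file).
#' @export
read_trials <- function(path, response_window = 3) {
  tr <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.trial_columns, names(tr))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(tr) == 0L) {
    warning("empty trial file: ", path, call. = FALSE)
    return(tr)
  }
  tr$choice[tr$choice %in% c("", "NA")] <- NA
  tr$omitted <- as.logical(tr$omitted)
  resp <- !tr$omitted
  bad <- which(resp & (!is.finite(tr$dt_s) | tr$dt_s <= 0 |
                         tr$dt_s > response_window))
  if (length(bad))
    stop("decision time outside (0, ", response_window, "] on row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  bad <- which(resp & (is.na(tr$choice) | !tr$choice %in% c("A", "B")))
  if (length(bad))
    stop("invalid choice on responded row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  bad <- which(resp & !tr$outcome %in% c(0, 1))
  if (length(bad))
    stop("invalid outcome on responded row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  bad <- which(!resp & (!is.na(tr$outcome) | !is.na(tr$dt_s)))
  if (length(bad))
    stop("omitted trials must carry no outcome or decision time; row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  bad <- which(tr$trial < 1 | tr$trial != round(tr$trial))
  if (length(bad))
    stop("trial indices must be positive integers; row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  tr
}

#' Write a run configuration as JSON
#'
#' @param config named list (seeds, MCMC budget, task-design overrides,
#'   file paths, ...).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' @param path input path.
#' @return named list; round-trips losslessly with [write_run_config()].
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
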