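# CSV round-trip for trial tables.  Fixed header: participant_id,
# experiment, block, stimulus_frequency, shape_association,
# matching_condition, trial_number, response, rt, correct.

TRIAL_COLUMNS <- c("participant_id", "experiment", "block",
                   "stimulus_frequency", "shape_association",
                   "matching_condition", "trial_number", "response", "rt",
                   "correct")

#' Read and write trial tables
#'
#' `write_trials()` writes a trial data frame as UTF-8 comma-separated
#' text with the fixed header; `read_trials()` reads it back, validating
#' required columns and flagging malformed rows by line number. Response
#' times are stored in seconds; `rt_unit = "ms"` converts milliseconds to
#' seconds on read. Unknown extra columns are preserved with a warning.
#' A `col_map` (`c(file_column = "trial_column")`) can adapt externally
#' deposited tables whose columns are named differently.
#'
#' @param path file path.
#' @param rt_unit `"s"` (default) or `"ms"`.
#' @param col_map optional named character vector renaming file columns to
#'   the package's trial columns.
#' @return `read_trials()`: a trial data frame; `write_trials()`: the
#'   path, invisibly.
#' @export
read_trials <- function(path, rt_unit = c("s", "ms"), col_map = NULL) {
  rt_unit <- match.arg(rt_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    hit <- names(df) %in% names(col_map)
    names(df)[hit] <- col_map[names(df)[hit]]
  }
  miss <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(miss))
    stop("trial file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(df), TRIAL_COLUMNS)
  if (length(extra))
    warning("unknown column(s) preserved: ", paste(extra, collapse = ", "),
            call. = FALSE)
  bad <- which(is.na(df$response) | !nzchar(as.character(df$response)))
  if (length(bad))
    stop("missing response in data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad_rt <- which(!is.finite(df$rt))
  if (length(bad_rt))
    stop("malformed rt in data row(s): ",
         paste(utils::head(bad_rt, 5), collapse = ", "), call. = FALSE)
  if (!all(df$response %in% c("matching", "nonmatching")))
    stop("response values must be 'matching' or 'nonmatching'",
         call. = FALSE)
  if (rt_unit == "ms") df$rt <- df$rt / 1000
  df$correct <- as.logical(df$correct)
  df[, c(TRIAL_COLUMNS, extra)]
}

#' @rdname read_trials
#' @param trials trial data frame with the standard columns.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss))
    stop("trials are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}
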