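# Trial CSV input/output. Fixed dialect: UTF-8, comma separated, header
# row, "." decimal point, missing values as empty fields.
#
# Columns: subject_id (chr), group (chr: sdi|control), task
# (chr: perceptual|memory), trial (int, 1-based within subject and task),
# stimulus (S1|S2), response (S1|S2), correct (TRUE|FALSE), confidence
# (int 1..6), rt_ms (int), ct_ms (int), contrast (oddball contrast in
# (0,1], perceptual only), imageability (high|low, memory only).

trial_columns <- c("subject_id", "group", "task", "trial", "stimulus",
                   "response", "correct", "confidence", "rt_ms", "ct_ms",
                   "contrast", "imageability")

#' Read and validate a trial CSV
#'
#' Hard validation: every schema violation is reported with the offending
#' row numbers (of the data rows, header excluded).
#'
#' @param path CSV path.
#' @param K number of confidence levels (default 6).
#' @return validated trial data frame.
#' @export
read_trials <- function(path, K = 6L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  miss <- setdiff(trial_columns, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, trial_columns]
  # coerce types; anything non-coercible becomes NA and fails validation
  suppressWarnings({
    df$trial <- as.integer(df$trial)
    df$confidence <- as.integer(df$confidence)
    df$rt_ms <- as.integer(df$rt_ms)
    df$ct_ms <- as.integer(df$ct_ms)
    df$contrast <- as.numeric(df$contrast)
  })
  df$imageability <- as.character(df$imageability)
  df$correct <- as.logical(df$correct)
  validate_trials(df, K)
  df
}

#' Validate a trial data frame against the schema
#'
#' @param trials data frame with the columns of the trial CSV schema.
#' @param K number of confidence levels.
#' @return the trials, invisibly, or an error listing rows and fields.
#' @export
validate_trials <- function(trials, K = 6L) {
  problems <- character(0)
  flag <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      problems <<- c(problems, sprintf(
        "%s in row(s) %s%s", what,
        paste(utils::head(rows, 5L), collapse = ", "),
        if (length(rows) > 5L) sprintf(" (+%d more)", length(rows) - 5L) else ""))
    }
  }
  flag(!(trials$task %in% c("perceptual", "memory")), "invalid task label")
  flag(!(trials$stimulus %in% c("S1", "S2")), "invalid stimulus class")
  flag(!(trials$response %in% c("S1", "S2")), "invalid response class")
  conf <- trials$confidence
  flag(is.na(conf) | conf != round(conf) | conf < 1 | conf > K,
       sprintf("confidence outside 1..%d", K))
  flag(is.na(trials$correct) |
         trials$correct != (trials$stimulus == trials$response),
       "correct flag inconsistent with stimulus/response")
  perc <- trials$task == "perceptual"
  flag(perc & (is.na(trials$contrast) | trials$contrast <= 0 |
                 trials$contrast > 1),
       "contrast missing or outside (0,1] on perceptual trial")
  flag(!perc & !is.na(trials$contrast), "contrast present on memory trial")
  flag(!perc & !(trials$imageability %in% c("high", "low")),
       "imageability missing or invalid on memory trial")
  flag(perc & !is.na(trials$imageability),
       "imageability present on perceptual trial")
  flag(is.na(trials$rt_ms) | trials$rt_ms <= 0, "non-positive rt_ms")
  flag(is.na(trials$ct_ms) | trials$ct_ms <= 0, "non-positive ct_ms")
  if (length(problems)) {
    stop("trial validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(trials)
}

#' Write trials to CSV
#'
#' Missing values are written as empty fields.
#'
#' @param trials trial data frame.
#' @param path output path.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(trial_columns, names(trials))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(trials[, trial_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a cohort's true-parameter manifest to JSON
#'
#' @param cohort a `cohort` from [simulate_cohort()].
#' @param path output path.
#' @export
write_manifest <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  jsonlite::write_json(list(seed = cohort$seed, manifest = cohort$manifest),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
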