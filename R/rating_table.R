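#' Build a rating-count table from trial records
#'
#' Tallies trials into the stimulus x response x confidence count cube that
#' is the sufficient statistic for all type-1 and type-2 SDT fits.
#' Stimulus and response classes are coded `"S1"`/`"S2"`; in the perceptual
#' task S1/S2 are target-in-interval-1/2, in the memory task S1 = new and
#' S2 = old (the old-item distribution is the "signal" of the
#' unequal-variance model, so the zROC slope `s` is the new-to-old
#' evidence-SD ratio, typically below 1).
#'
#' @param trials data frame with columns `stimulus`, `response` (each
#'   `"S1"` or `"S2"`) and `confidence` (integer 1..K). Extra columns are
#'   ignored. A `task` column, when present, must be constant (or filtered
#'   via `task`).
#' @param task optional task label; if given, `trials` is subset to rows
#'   with that label before tallying.
#' @param K number of confidence levels (default 6).
#' @return an object of class `rating_table`: a list with elements
#'   `counts` (2 x 2 x K integer array), `K`, `task`, `n_trials`,
#'   `padded`, `pad_scheme`.
#' @examples
#' tr <- data.frame(stimulus = c("S1", "S1", "S2", "S2"),
#'                  response = c("S1", "S2", "S2", "S2"),
#'                  confidence = c(6, 1, 6, 3))
#' counts_from_trials(tr)
#' @export
counts_from_trials <- function(trials, task = NULL, K = 6) {
  stopifnot(is.data.frame(trials), K >= 2)
  if (!is.null(task)) {
    if ("task" %in% names(trials)) {
      trials <- trials[trials$task == task, , drop = FALSE]
    }
  } else if ("task" %in% names(trials) && nrow(trials) > 0) {
    tl <- unique(trials$task)
    if (length(tl) > 1L) {
      stop("trials mix task labels (", paste(tl, collapse = ", "),
           "); pass `task` to select one")
    }
    task <- tl[1L]
  }
  need <- c("stimulus", "response", "confidence")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials lack column(s): ", paste(miss, collapse = ", "))

  counts <- array(0L, dim = c(2L, 2L, K),
                  dimnames = list(stimulus = c("S1", "S2"),
                                  response = c("S1", "S2"),
                                  confidence = as.character(seq_len(K))))
  if (nrow(trials) > 0) {
    bad_class <- !(trials$stimulus %in% c("S1", "S2")) |
      !(trials$response %in% c("S1", "S2"))
    if (any(bad_class)) {
      stop("invalid stimulus/response class in trial row(s): ",
           paste(utils::head(which(bad_class), 5L), collapse = ", "))
    }
    conf <- trials$confidence
    bad <- !is.finite(conf) | conf != round(conf) | conf < 1 | conf > K
    if (any(bad)) {
      stop("confidence outside 1..", K, " in trial row(s): ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    }
    tab <- table(factor(trials$stimulus, c("S1", "S2")),
                 factor(trials$response, c("S1", "S2")),
                 factor(conf, seq_len(K)))
    counts[] <- as.integer(tab)
  }
  structure(list(counts = counts, K = as.integer(K),
                 task = if (is.null(task)) NA_character_ else as.character(task),
                 n_trials = nrow(trials), padded = FALSE, pad_scheme = NULL),
            class = "rating_table")
}

#' Construct a rating table directly from a count array
#'
#' @param counts 2 x 2 x K non-negative array ordered
#'   (stimulus S1/S2, response S1/S2, confidence 1..K).
#' @param task optional task label.
#' @return a `rating_table`.
#' @export
rating_table <- function(counts, task = NA_character_) {
  stopifnot(is.array(counts), length(dim(counts)) == 3L,
            dim(counts)[1:2] == c(2L, 2L))
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  K <- dim(counts)[3L]
  if (K < 2) stop("need at least 2 confidence levels")
  dimnames(counts) <- list(stimulus = c("S1", "S2"), response = c("S1", "S2"),
                           confidence = as.character(seq_len(K)))
  structure(list(counts = counts, K = as.integer(K),
                 task = as.character(task), n_trials = sum(counts),
                 padded = FALSE, pad_scheme = NULL),
            class = "rating_table")
}

#' @export
print.rating_table <- function(x, ...) {
  cat("Rating table (", x$K, " confidence levels",
      if (!is.na(x$task)) paste0(", task: ", x$task), ")\n", sep = "")
  cat("  trials:", x$n_trials,
      if (x$padded) paste0(" [padded: ", x$pad_scheme, "]"), "\n")
  for (s in c("S1", "S2")) {
    cat("  stimulus ", s, ":\n", sep = "")
    print(x$counts[s, , ])
  }
  invisible(x)
}

# Internal: counts along the evidence-axis ordering used by the SDT fits.
# Column j = 1..2K runs (resp S1, conf K) ... (resp S1, conf 1),
# (resp S2, conf 1) ... (resp S2, conf K); one row per stimulus class.
evidence_counts <- function(table) {
  K <- table$K
  rbind(S1 = c(rev(table$counts["S1", "S1", ]), table$counts["S1", "S2", ]),
        S2 = c(rev(table$counts["S2", "S1", ]), table$counts["S2", "S2", ]))
}

# Internal: cumulative "above criterion j" proportions for the 2K-1 rating
# criteria; row per stimulus, so row S1 = false-alarm-style rates and row
# S2 = hit-style rates.
cumulative_rates <- function(table) {
  ev <- evidence_counts(table)
  tot <- rowSums(ev)
  n2K <- ncol(ev)
  above <- t(apply(ev[, n2K:1, drop = FALSE], 1L, cumsum))[, n2K:1, drop = FALSE]
  sweep(above[, -1L, drop = FALSE], 1L, tot, "/")
}

#' Pad a rating table against empty cumulative cells
#'
#' z-transforms of hit/false-alarm proportions diverge when a cumulative
#' rating count is 0 or equals the stimulus total. Following the common
#' meta-d' code convention, the default scheme adds 1/(2K) to every cell
#' whenever any of the 2(2K-1) cumulative cells is empty or full; the
#' `"always"` scheme pads unconditionally and `"none"` never does.
#'
#' @param table a `rating_table`.
#' @param scheme one of `"if-needed"` (default), `"always"`, `"none"`.
#' @return the (possibly) padded `rating_table`; `padded`/`pad_scheme`
#'   record what was done. `n_trials` keeps the raw trial count.
#' @export
pad_counts <- function(table, scheme = c("if-needed", "always", "none")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(table, "rating_table"))
  if (sum(table$counts) == 0) stop("no trials")
  ev <- evidence_counts(table)
  tot <- rowSums(ev)
  if (any(tot == 0)) stop("a stimulus class has no trials")
  cum <- cumulative_rates(table)
  needs <- any(cum <= 0 | cum >= 1)
  do_pad <- switch(scheme, "if-needed" = needs, "always" = TRUE, "none" = FALSE)
  if (do_pad) {
    table$unpadded_counts <- table$counts
    table$counts <- table$counts + 1 / (2 * table$K)
    table$padded <- TRUE
  }
  table$pad_scheme <- scheme
  table
}
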