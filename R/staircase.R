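# 1-up/2-down adaptive contrast staircase and the accuracy-based
# outlier-exclusion rule for the perceptual task.

#' Create a staircase state
#'
#' The oddball starts `start_delta` above the distractor baseline contrast
#' and moves in absolute steps: up one step after any error, down one step
#' after two consecutive correct responses. This rule converges to about
#' 70.7% correct. Contrast is floored just above the distractor level.
#'
#' @param start_delta initial oddball-minus-distractor contrast difference
#'   (default 0.20, i.e. oddball 20 percentage points above baseline).
#' @param step step size in absolute contrast (default 0.03).
#' @param baseline distractor contrast (default 0.20).
#' @param min_delta smallest allowed contrast difference (default 0.01).
#' @return object of class `staircase_state` with fields
#'   `oddball_contrast`, `delta`, `consecutive_correct`, `step`,
#'   `baseline`, `min_delta`.
#' @export
staircase_state <- function(start_delta = 0.20, step = 0.03,
                            baseline = 0.20, min_delta = 0.01) {
  stopifnot(start_delta >= min_delta, step > 0, min_delta > 0)
  structure(list(oddball_contrast = baseline + start_delta,
                 delta = start_delta, consecutive_correct = 0L,
                 step = step, baseline = baseline, min_delta = min_delta),
            class = "staircase_state")
}

#' Advance the staircase by one response
#'
#' After one incorrect response the oddball contrast increases by one
#' step; after two consecutive correct responses it decreases by one step
#' and the counter resets; after a first correct response only the counter
#' advances.
#'
#' @param state a `staircase_state`.
#' @param correct logical, whether the response was correct.
#' @return the updated `staircase_state`.
#' @examples
#' st <- staircase_state()  # oddball at 0.40
#' staircase_update(st, FALSE)$oddball_contrast  # 0.43
#' staircase_update(staircase_update(st, TRUE), TRUE)$oddball_contrast  # 0.37
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  if (!correct) {
    state$delta <- state$delta + state$step
    state$consecutive_correct <- 0L
  } else if (state$consecutive_correct >= 1L) {
    state$delta <- max(state$delta - state$step, state$min_delta)
    state$consecutive_correct <- 0L
  } else {
    state$consecutive_correct <- 1L
  }
  state$oddball_contrast <- state$baseline + state$delta
  state
}

#' Synthetic psychometric observer for the contrast-oddball task
#'
#' Detection probability is a cumulative Gaussian in the oddball contrast
#' difference, rising from 0.5 (guessing) to `1 - lapse`:
#' `p(delta) = 0.5 + (0.5 - lapse) * (2 * pnorm(delta / slope) - 1)`.
#' By default the slope is tied to the threshold so that
#' `p(threshold) = 1/sqrt(2)` (about 70.7%), the convergence point of the
#' 1-up/2-down rule, making the observer a one-parameter family in its
#' threshold (a Weber-like assumption).
#'
#' @param threshold contrast difference at ~70.7% correct.
#' @param slope Gaussian SD of the psychometric function; default ties it
#'   to `threshold` as described.
#' @param lapse asymptotic error probability (default 0.02).
#' @return object of class `psychometric_observer`.
#' @export
psychometric_observer <- function(threshold, slope = NULL, lapse = 0.02) {
  stopifnot(threshold > 0, lapse >= 0, lapse < 0.5)
  if (is.null(slope)) {
    target <- (sqrt(0.5) - 0.5) / (2 * (0.5 - lapse)) + 0.5
    slope <- threshold / stats::qnorm(target)
  }
  stopifnot(slope > 0)
  structure(list(threshold = threshold, slope = slope, lapse = lapse),
            class = "psychometric_observer")
}

#' Detection probability of a psychometric observer
#'
#' @param observer a `psychometric_observer`.
#' @param delta contrast difference(s), non-negative.
#' @return probability correct, in (0.5, 1 - lapse).
#' @export
detect_prob <- function(observer, delta) {
  stopifnot(inherits(observer, "psychometric_observer"))
  0.5 + (0.5 - observer$lapse) *
    (2 * stats::pnorm(delta / observer$slope) - 1)
}

#' Run a full 1-up/2-down staircase session
#'
#' Drives a psychometric observer through `n_trials` staircase trials,
#' drawing correctness Bernoulli from the observer's detection probability
#' at the current contrast difference.
#'
#' @param observer a `psychometric_observer`.
#' @param n_trials number of trials (default 180).
#' @param seed optional integer seed for reproducibility (the global RNG
#'   state is restored afterwards).
#' @param state starting `staircase_state`.
#' @return list with `history` (data frame: trial, delta,
#'   oddball_contrast, correct, reversal), `accuracy` (overall proportion
#'   correct over all trials), `threshold_estimate` (mean contrast
#'   difference at reversals after discarding the first 4; falls back to
#'   the mean delta over the final half of trials when fewer than 5
#'   reversals occurred) and `n_reversals`.
#' @export
run_staircase <- function(observer, n_trials = 180L, seed = NULL,
                          state = staircase_state()) {
  stopifnot(inherits(observer, "psychometric_observer"), n_trials >= 1)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  delta <- numeric(n_trials)
  correct <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    delta[t] <- state$delta
    correct[t] <- stats::runif(1) < detect_prob(observer, state$delta)
    state <- staircase_update(state, correct[t])
  }
  reversal <- find_reversals(c(delta, state$delta))
  hist <- data.frame(trial = seq_len(n_trials), delta = delta,
                     oddball_contrast = state$baseline + delta,
                     correct = correct, reversal = reversal)
  list(history = hist, accuracy = mean(correct),
       threshold_estimate = threshold_from_deltas(delta, reversal),
       n_reversals = sum(reversal), final_state = state)
}

# Internal: mark trials at which the contrast direction reversed. Takes
# the delta sequence extended by the post-session value so the final move
# is visible; returns a logical vector over the n_trials trials, TRUE at
# the trial where a direction change materialised.
find_reversals <- function(delta_ext) {
  n <- length(delta_ext) - 1L
  moves <- diff(delta_ext)
  reversal <- logical(n)
  last_dir <- 0
  for (t in seq_len(n)) {
    if (moves[t] != 0) {
      dir <- sign(moves[t])
      if (last_dir != 0 && dir != last_dir) reversal[t] <- TRUE
      last_dir <- dir
    }
  }
  reversal
}

# Internal: reversal-averaged threshold estimate (first 4 reversals
# discarded as burn-in).
threshold_from_deltas <- function(delta, reversal, discard = 4L) {
  idx <- which(reversal)
  if (length(idx) > discard) {
    mean(delta[idx[-seq_len(discard)]])
  } else {
    n <- length(delta)
    mean(delta[seq.int(floor(n / 2) + 1L, n)])
  }
}

#' Accuracy-based outlier exclusion
#'
#' Flags subjects whose accuracy falls below the sample mean minus 8
#' standard deviations. Mean and SD are computed leaving the candidate
#' out: with the candidate included, the sample SD is inflated by the
#' outlier itself and no point can ever lie 8 SDs below the mean in
#' samples of this size (the maximum possible z-score is
#' `(n-1)/sqrt(n)`), so the all-in version of the rule would be
#' vacuous. With zero variance among the other subjects nothing is
#' excluded unless the candidate lies strictly below their common value
#' minus zero spread (i.e. never). The rule is deterministic and
#' order-invariant.
#'
#' @param accuracies numeric vector of per-subject proportions correct.
#' @param n_sd number of SDs below the mean (default 8).
#' @return integer indices of excluded subjects (possibly empty).
#' @export
exclusion_filter <- function(accuracies, n_sd = 8) {
  stopifnot(is.numeric(accuracies), length(accuracies) >= 2,
            all(is.finite(accuracies)))
  flagged <- vapply(seq_along(accuracies), function(i) {
    rest <- accuracies[-i]
    sdv <- stats::sd(rest)
    if (!is.finite(sdv) || sdv == 0) return(FALSE)
    accuracies[i] < mean(rest) - n_sd * sdv
  }, logical(1))
  which(flagged)
}

# Internal RNG bookkeeping: remember/restore .Random.seed so seeded
# helpers do not disturb the caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
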