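# Synthetic SDT observers: trial-level choices, confidence ratings and
# timing for perceptual and recognition-memory sessions, and whole
# two-group cohorts.
#
# Generative model per trial: a decision variable x ~ N(+/- sep/2, sd)
# (sd 1 for S1, 1/s for S2). The choice compares x (plus optional choice
# noise) to the criterion. Confidence is based on y = x + metacognitive
# noise, binned by fixed criteria on the chosen response's side.
# Metacognitive noise degrades confidence only (M-ratio below 1); choice
# noise degrades the choice only, leaving confidence better informed than
# the decision (M-ratio above 1).

#' Generative parameters of one synthetic observer
#'
#' @param sensitivity generative type-1 sensitivity on the da scale
#'   (z-units). Ignored in the perceptual session, where the staircase
#'   induces trial-wise sensitivity through the psychometric function.
#' @param criterion decision criterion on the evidence axis (z-units).
#' @param s generative evidence-SD ratio, S1 to S2 (new to old for
#'   memory; values below 1 mean old items are noisier). Must be 1 when
#'   `choice_noise_sd > 0`.
#' @param meta_noise_sd SD of zero-mean Gaussian noise added to the
#'   confidence variable only; 0 = ideal metacognition.
#' @param choice_noise_sd SD of Gaussian noise added to the choice
#'   variable only; positive values model confidence that is better
#'   informed than the decision (M-ratio > 1).
#' @param confidence_offsets ascending vector of K-1 confidence-criterion
#'   offsets from the decision criterion, mirrored across the two
#'   response sides; negative leading offsets express overconfidence.
#' @param K number of confidence levels (default 6).
#' @param rt_model list with `rt_mean`, `ct_mean` (ms) and coefficients of
#'   variation `rt_cv`, `ct_cv`; response and confidence times are drawn
#'   lognormal.
#' @param group_label,subject_id optional labels carried into records.
#' @return object of class `observer_params`.
#' @export
observer_params <- function(sensitivity = 1.1, criterion = 0, s = 1,
                            meta_noise_sd = 0, choice_noise_sd = 0,
                            confidence_offsets = default_confidence_offsets(),
                            K = 6L,
                            rt_model = list(rt_mean = 1200, rt_cv = 0.35,
                                            ct_mean = 600, ct_cv = 0.35),
                            group_label = NA_character_,
                            subject_id = NA_character_) {
  stopifnot(s > 0, meta_noise_sd >= 0, choice_noise_sd >= 0, K >= 2,
            length(confidence_offsets) == K - 1,
            all(diff(confidence_offsets) > 0),
            rt_model$rt_mean > 0, rt_model$ct_mean > 0)
  if (choice_noise_sd > 0 && s != 1) {
    stop("choice noise is only supported for the equal-variance observer (s = 1)")
  }
  structure(list(sensitivity = sensitivity, criterion = criterion, s = s,
                 meta_noise_sd = meta_noise_sd,
                 choice_noise_sd = choice_noise_sd,
                 confidence_offsets = confidence_offsets, K = as.integer(K),
                 rt_model = rt_model, group_label = group_label,
                 subject_id = subject_id),
            class = "observer_params")
}

#' Default confidence-criterion offsets
#'
#' Offsets (relative to the decision criterion, in evidence-SD units) of
#' the five confidence criteria for a 6-point scale. The defaults were
#' calibrated once by simulation so that a typical observer (sensitivity
#' near 1.1, metacognitive noise near 0.8) reports a mean confidence of
#' about 4.7 on the 1-6 scale, matching the over-confident band commonly
#' seen in these tasks.
#'
#' @return numeric vector of length 5.
#' @export
default_confidence_offsets <- function() {
  c(-0.7, -0.25, 0.2, 0.65, 1.2)
}

# Internal: map confidence variable y to a 1..K rating, given the chosen
# response. For "S2" responses criteria sit at criterion + offsets and
# confidence counts how many y exceeds; "S1" responses mirror them.
confidence_from_evidence <- function(y, resp_s2, criterion, offsets) {
  up <- criterion + offsets
  dn <- criterion - offsets
  conf <- integer(length(y))
  if (any(resp_s2)) {
    conf[resp_s2] <- 1L + rowSums(outer(y[resp_s2], up, `>=`))
  }
  if (any(!resp_s2)) {
    conf[!resp_s2] <- 1L + rowSums(outer(y[!resp_s2], dn, `<=`))
  }
  conf
}

# Internal: draw n lognormal times (ms) with the given mean and CV.
draw_times <- function(n, mean_ms, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean_ms) - sdlog^2 / 2
  as.integer(round(stats::rlnorm(n, meanlog, sdlog)))
}

# Internal batch generator: one row per trial for given stimulus classes.
# `sep` may be a scalar or per-trial vector of evidence separations
# (already on the evidence axis, i.e. scaled for choice noise).
simulate_rating_batch <- function(params, stimulus, sep) {
  n <- length(stimulus)
  is_s2 <- stimulus == "S2"
  sdv <- ifelse(is_s2, 1 / params$s, 1)
  mu <- ifelse(is_s2, sep / 2, -sep / 2)
  x <- stats::rnorm(n, mu, sdv)
  xc <- if (params$choice_noise_sd > 0) {
    x + stats::rnorm(n, 0, params$choice_noise_sd)
  } else x
  resp_s2 <- xc > params$criterion
  y <- if (params$meta_noise_sd > 0) {
    x + stats::rnorm(n, 0, params$meta_noise_sd)
  } else x
  conf <- confidence_from_evidence(y, resp_s2, params$criterion,
                                   params$confidence_offsets)
  conf <- pmin(conf, params$K)
  data.frame(stimulus = stimulus,
             response = ifelse(resp_s2, "S2", "S1"),
             correct = resp_s2 == is_s2,
             confidence = conf,
             rt_ms = draw_times(n, params$rt_model$rt_mean, params$rt_model$rt_cv),
             ct_ms = draw_times(n, params$rt_model$ct_mean, params$rt_model$ct_cv),
             stringsAsFactors = FALSE)
}

#' Simulate a single trial
#'
#' @param params an `observer_params`.
#' @param stimulus_class `"S1"` or `"S2"`.
#' @return a one-row data frame with `stimulus`, `response`, `correct`,
#'   `confidence`, `rt_ms`, `ct_ms`.
#' @export
simulate_trial <- function(params, stimulus_class = c("S1", "S2")) {
  stimulus_class <- match.arg(stimulus_class)
  stopifnot(inherits(params, "observer_params"))
  sep <- params$sensitivity * sqrt((1 + 1 / params$s^2) / 2) *
    sqrt(1 + params$choice_noise_sd^2)
  simulate_rating_batch(params, stimulus_class, sep)
}

#' Simulate a recognition-memory session
#'
#' Emulates the study design: `n_learn` words studied, then a recognition
#' test over `n_test = 2 * n_learn` items (half old, half new), with the
#' imageability label crossed evenly over old/new (so each
#' old/new x high/low cell holds `n_learn / 2` trials). Old items (S2)
#' are drawn with evidence-SD ratio `s`; imageability has no generative
#' effect unless `imageability_da_shift` is nonzero, in which case high-
#' and low-imageable items get `sensitivity +/- shift/2`.
#'
#' @param params an `observer_params` (its `sensitivity` is the memory
#'   da).
#' @param n_learn number of studied words (default 100; must be even).
#' @param n_test number of test trials (default 200; must equal
#'   `2 * n_learn`).
#' @param imageability_da_shift optional generative imageability effect
#'   on da (default 0).
#' @return data frame of `n_test` trial records with columns `trial`,
#'   `task`, `stimulus`, `response`, `correct`, `confidence`, `rt_ms`,
#'   `ct_ms`, `contrast` (NA), `imageability`.
#' @export
simulate_memory_session <- function(params, n_learn = 100L, n_test = 200L,
                                    imageability_da_shift = 0) {
  stopifnot(inherits(params, "observer_params"))
  if (n_test != 2L * n_learn) stop("n_test must equal 2 * n_learn")
  if (n_learn %% 2L != 0L) stop("n_learn must be even for a 50/50 imageability split")
  half <- n_learn / 2L
  stimulus <- rep(c("S2", "S1"), each = n_learn)        # old then new
  imageability <- rep(rep(c("high", "low"), each = half), times = 2L)
  ord <- sample.int(n_test)
  stimulus <- stimulus[ord]
  imageability <- imageability[ord]
  da <- params$sensitivity +
    ifelse(imageability == "high", 1, -1) * imageability_da_shift / 2
  sep <- da * sqrt((1 + 1 / params$s^2) / 2)
  out <- simulate_rating_batch(params, stimulus, sep)
  data.frame(trial = seq_len(n_test), task = "memory", out,
             contrast = NA_real_, imageability = imageability,
             stringsAsFactors = FALSE)
}

#' Simulate a staircase-controlled perceptual session
#'
#' Runs the 1-up/2-down contrast staircase trial by trial. At the current
#' contrast difference the observer's detection probability p comes from
#' its psychometric function; the trial is realised through an SDT
#' decision variable with effective sensitivity `2 * qnorm(p)` (so choice
#' accuracy is exactly p and confidence can be computed from the same
#' evidence), scaled up when choice noise is present.
#'
#' @param params an `observer_params` (its `sensitivity` field is ignored
#'   here).
#' @param observer a `psychometric_observer`.
#' @param n_trials number of trials (default 180).
#' @param state starting `staircase_state`.
#' @return list with `trials` (trial records incl. the oddball `contrast`
#'   column), `accuracy`, `threshold_estimate`, `n_reversals`.
#' @export
simulate_perceptual_session <- function(params, observer, n_trials = 180L,
                                        state = staircase_state()) {
  stopifnot(inherits(params, "observer_params"),
            inherits(observer, "psychometric_observer"))
  scale_c <- sqrt(1 + params$choice_noise_sd^2)
  delta <- numeric(n_trials)
  stim <- sample(c("S1", "S2"), n_trials, replace = TRUE)
  resp <- character(n_trials)
  conf <- integer(n_trials)
  correct <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    delta[t] <- state$delta
    p <- detect_prob(observer, state$delta)
    sep <- 2 * stats::qnorm(p) * scale_c
    mu <- if (stim[t] == "S2") sep / 2 else -sep / 2
    x <- stats::rnorm(1, mu, 1)
    xc <- if (params$choice_noise_sd > 0) {
      x + stats::rnorm(1, 0, params$choice_noise_sd)
    } else x
    resp[t] <- if (xc > params$criterion) "S2" else "S1"
    correct[t] <- resp[t] == stim[t]
    y <- if (params$meta_noise_sd > 0) {
      x + stats::rnorm(1, 0, params$meta_noise_sd)
    } else x
    conf[t] <- min(confidence_from_evidence(y, resp[t] == "S2",
                                            params$criterion,
                                            params$confidence_offsets),
                   params$K)
    state <- staircase_update(state, correct[t])
  }
  reversal <- find_reversals(c(delta, state$delta))
  trials <- data.frame(
    trial = seq_len(n_trials), task = "perceptual", stimulus = stim,
    response = resp, correct = correct, confidence = conf,
    rt_ms = draw_times(n_trials, params$rt_model$rt_mean, params$rt_model$rt_cv),
    ct_ms = draw_times(n_trials, params$rt_model$ct_mean, params$rt_model$ct_cv),
    contrast = state$baseline + delta, imageability = NA_character_,
    stringsAsFactors = FALSE)
  list(trials = trials, accuracy = mean(correct),
       threshold_estimate = threshold_from_deltas(delta, reversal),
       n_reversals = sum(reversal))
}

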