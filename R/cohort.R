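# Two-group cohort simulation: per-subject generative parameters drawn
# from group-level distributions, full perceptual + memory sessions, and
# a true-parameter manifest for recovery testing.

#' Default cohort specification
#'
#' Generative group-level distributions for a two-group study
#' (substance-dependent individuals on maintenance treatment vs healthy
#' controls). Defaults mirror the published behavioral summary of the
#' study design this package models: group sizes 23/24; perceptual
#' contrast thresholds 0.19 (0.09) vs 0.16 (0.05); perceptual M-ratio
#' means 0.67 vs 1.01; memory da means 0.92 vs 1.19; memory (unequal
#' variance) M-ratio means 0.82 vs 0.93; response/confidence-time means
#' per task and group. Between-subject SDs of the true M-ratio and
#' memory da are generative choices (0.2 and 0.3): the observed
#' between-subject SDs also include estimation noise from the
#' finite-trial fits.
#'
#' @param n_sdi,n_control group sizes.
#' @return nested list of class `cohort_spec`; see the fields for the
#'   tunable quantities (all distributions are truncated normals given as
#'   `c(mean, sd)` plus bounds).
#' @export
cohort_spec <- function(n_sdi = 23L, n_control = 24L) {
  stopifnot(n_sdi >= 1, n_control >= 1)
  groups <- list(
    sdi = list(
      n = as.integer(n_sdi),
      contrast_threshold = c(mean = 0.19, sd = 0.09),
      perc_m_ratio = c(mean = 0.67, sd = 0.20),
      mem_da = c(mean = 0.92, sd = 0.30),
      mem_m_ratio = c(mean = 0.82, sd = 0.20),
      perc_rt = c(mean = 1358, sd = 573), perc_ct = c(mean = 831, sd = 613),
      mem_rt = c(mean = 2146, sd = 518), mem_ct = c(mean = 683, sd = 226)),
    control = list(
      n = as.integer(n_control),
      contrast_threshold = c(mean = 0.16, sd = 0.05),
      perc_m_ratio = c(mean = 1.01, sd = 0.20),
      mem_da = c(mean = 1.19, sd = 0.30),
      mem_m_ratio = c(mean = 0.93, sd = 0.20),
      perc_rt = c(mean = 1099, sd = 283), perc_ct = c(mean = 510, sd = 143),
      mem_rt = c(mean = 1964, sd = 425), mem_ct = c(mean = 577, sd = 262)))
  structure(list(
    groups = groups,
    K = 6L,
    n_perc_trials = 180L,
    n_learn = 100L, n_test = 200L,
    staircase = list(start_delta = 0.20, step = 0.03, baseline = 0.20,
                     min_delta = 0.01),
    lapse = 0.02,
    memory_s = 0.8,
    memory_criterion = 0,
    confidence_offsets = default_confidence_offsets(),
    threshold_bounds = c(0.04, 0.50),
    m_ratio_bounds = c(0.10, 2.00),
    mem_da_bounds = c(0.10, 2.50),
    rt_bounds = c(150, 6000),
    rt_cv = 0.35, ct_cv = 0.35,
    imageability_da_shift = 0),
    class = "cohort_spec")
}

# Internal: exact inverse-CDF truncated-normal draws.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a full two-group cohort
#'
#' Draws every subject's true parameters from the group distributions in
#' `spec`, runs the staircase-controlled perceptual session and the
#' recognition-memory session for each subject, and returns the trial
#' dataset together with a manifest of the true generative parameters.
#' Output is fully reproducible: the same seed yields identical data.
#'
#' @param spec a `cohort_spec`.
#' @param seed integer seed (required, for the determinism contract).
#' @return object of class `cohort`: list with `trials` (one row per
#'   trial, all subjects), `manifest` (one row per subject: true
#'   parameters and session summaries), `spec`, `seed`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"), is.numeric(seed),
            length(seed) == 1L, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  all_trials <- list()
  manifest <- list()
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    if (g$n < 1) stop("non-positive group size for ", gname)
    for (i in seq_len(g$n)) {
      sid <- sprintf("%s_%02d", gname, i)
      thr <- rtruncnorm(1, g$contrast_threshold["mean"],
                        g$contrast_threshold["sd"],
                        spec$threshold_bounds[1], spec$threshold_bounds[2])
      perc_m <- rtruncnorm(1, g$perc_m_ratio["mean"], g$perc_m_ratio["sd"],
                           spec$m_ratio_bounds[1], spec$m_ratio_bounds[2])
      mem_da <- rtruncnorm(1, g$mem_da["mean"], g$mem_da["sd"],
                           spec$mem_da_bounds[1], spec$mem_da_bounds[2])
      mem_m <- rtruncnorm(1, g$mem_m_ratio["mean"], g$mem_m_ratio["sd"],
                          spec$m_ratio_bounds[1], spec$m_ratio_bounds[2])
      rt_means <- vapply(c("perc_rt", "perc_ct", "mem_rt", "mem_ct"),
                         function(f) rtruncnorm(1, g[[f]]["mean"], g[[f]]["sd"],
                                                spec$rt_bounds[1],
                                                spec$rt_bounds[2]),
                         numeric(1))

      perc_noise <- noise_for_m_ratio(perc_m)
      perc_params <- observer_params(
        sensitivity = NA_real_, criterion = 0, s = 1,
        meta_noise_sd = perc_noise$meta_noise_sd,
        choice_noise_sd = perc_noise$choice_noise_sd,
        confidence_offsets = spec$confidence_offsets, K = spec$K,
        rt_model = list(rt_mean = rt_means[["perc_rt"]], rt_cv = spec$rt_cv,
                        ct_mean = rt_means[["perc_ct"]], ct_cv = spec$ct_cv),
        group_label = gname, subject_id = sid)
      pobs <- psychometric_observer(thr, lapse = spec$lapse)
      st <- staircase_state(spec$staircase$start_delta, spec$staircase$step,
                            spec$staircase$baseline, spec$staircase$min_delta)
      perc <- simulate_perceptual_session(perc_params, pobs,
                                          spec$n_perc_trials, st)

      mem_noise <- noise_for_m_ratio(min(mem_m, 1))
      mem_params <- observer_params(
        sensitivity = mem_da, criterion = spec$memory_criterion,
        s = spec$memory_s,
        meta_noise_sd = mem_noise$meta_noise_sd,
        choice_noise_sd = 0,
        confidence_offsets = spec$confidence_offsets, K = spec$K,
        rt_model = list(rt_mean = rt_means[["mem_rt"]], rt_cv = spec$rt_cv,
                        ct_mean = rt_means[["mem_ct"]], ct_cv = spec$ct_cv),
        group_label = gname, subject_id = sid)
      mem <- simulate_memory_session(mem_params, spec$n_learn, spec$n_test,
                                     spec$imageability_da_shift)

      subj_trials <- rbind(perc$trials, mem)
      subj_trials <- data.frame(subject_id = sid, group = gname, subj_trials,
                                stringsAsFactors = FALSE)
      all_trials[[sid]] <- subj_trials
      manifest[[sid]] <- data.frame(
        subject_id = sid, group = gname,
        true_threshold = thr, true_perc_m_ratio = perc_m,
        true_mem_da = mem_da, true_mem_m_ratio = min(mem_m, 1),
        perc_meta_noise_sd = perc_noise$meta_noise_sd,
        perc_choice_noise_sd = perc_noise$choice_noise_sd,
        mem_meta_noise_sd = mem_noise$meta_noise_sd,
        memory_s = spec$memory_s,
        rt_perc = rt_means[["perc_rt"]], ct_perc = rt_means[["perc_ct"]],
        rt_mem = rt_means[["mem_rt"]], ct_mem = rt_means[["mem_ct"]],
        perc_accuracy = perc$accuracy,
        perc_threshold_estimate = perc$threshold_estimate,
        stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, c(all_trials, make.row.names = FALSE))
  trials <- trials[, trial_columns]
  structure(list(trials = trials,
                 manifest = do.call(rbind, c(manifest, make.row.names = FALSE)),
                 spec = spec, seed = as.integer(seed)),
            class = "cohort")
}

#' Staircase accuracy study over a cohort of psychometric observers
#'
#' Draws observer contrast thresholds from the cohort spec's group
#' distributions (half the observers per group profile) and runs each
#' through the full 1-up/2-down staircase session, recording overall
#' accuracy and the reversal-averaged threshold estimate. This is the
#' design-level diagnostic of staircase convergence: the rule should hold
#' mean accuracy near 70.7% with only about a percentage point of spread
#' between observers.
#'
#' @param n_observers total number of simulated observers (default 120).
#' @param seed integer seed.
#' @param spec a `cohort_spec` (for the threshold distributions and
#'   staircase constants).
#' @param n_trials staircase trials per observer (default from spec).
#' @return data frame with one row per observer: `group`, `threshold`,
#'   `accuracy`, `threshold_estimate`.
#' @export
run_staircase_cohort <- function(n_observers = 120L, seed = 1L,
                                 spec = cohort_spec(),
                                 n_trials = spec$n_perc_trials) {
  stopifnot(n_observers >= 2)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  gnames <- rep(names(spec$groups), length.out = n_observers)
  rows <- lapply(seq_len(n_observers), function(i) {
    g <- spec$groups[[gnames[i]]]
    thr <- rtruncnorm(1, g$contrast_threshold["mean"],
                      g$contrast_threshold["sd"],
                      spec$threshold_bounds[1], spec$threshold_bounds[2])
    obs <- psychometric_observer(thr, lapse = spec$lapse)
    st <- staircase_state(spec$staircase$start_delta, spec$staircase$step,
                          spec$staircase$baseline, spec$staircase$min_delta)
    res <- run_staircase(obs, n_trials = n_trials, state = st)
    data.frame(group = gnames[i], threshold = thr, accuracy = res$accuracy,
               threshold_estimate = res$threshold_estimate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' @export
print.cohort <- function(x, ...) {
  ns <- table(x$manifest$group)
  cat("Synthetic cohort (seed ", x$seed, "): ",
      paste(sprintf("%s n=%d", names(ns), as.integer(ns)), collapse = ", "),
      "; ", nrow(x$trials), " trials\n", sep = "")
  invisible(x)
}
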