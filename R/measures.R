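# Per-subject measure extraction: all SDT fits are delegated to the
# rating-table / type-1 / type-2 modules; this layer only assembles them.

#' Extract per-subject behavioral measures
#'
#' For each subject: perceptual accuracy, contrast threshold (reversal
#' average of the staircase trace recovered from the contrast column),
#' equal-variance d' and M-ratio, mean confidence and mean response /
#' confidence times; for the memory task the unequal-variance da, zROC
#' slope s, equal-variance d', M-ratio under both variance models, and
#' the unequal-variance M-ratio computed separately for high- and
#' low-imageable words (each such fit uses exactly half the test trials).
#' Fits that fail on degenerate data (e.g. an all-correct subject) are
#' carried as NA and the subject is flagged.
#'
#' @param trials trial data frame in the package CSV schema (see
#'   [read_trials()]); row order is irrelevant.
#' @param K number of confidence levels (default 6).
#' @param pad_scheme padding scheme passed to [pad_counts()].
#' @param baseline_contrast distractor contrast used to convert the
#'   oddball contrast column back to contrast differences (default 0.20).
#' @param equal_variance_memory also fit the equal-variance memory
#'   variant (default TRUE).
#' @param imageability_split also fit the per-imageability memory
#'   M-ratios (default TRUE).
#' @return data frame, one row per subject, with measure columns prefixed
#'   `perc_` / `mem_` and a `complete` flag.
#' @export
extract_measures <- function(trials, K = 6L, pad_scheme = "if-needed",
                             baseline_contrast = 0.20,
                             equal_variance_memory = TRUE,
                             imageability_split = TRUE) {
  stopifnot(is.data.frame(trials))
  need <- c("subject_id", "group", "task", "trial", "stimulus", "response",
            "correct", "confidence")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials lack column(s): ", paste(miss, collapse = ", "))
  trials <- trials[order(trials$subject_id, trials$task, trials$trial), ,
                   drop = FALSE]
  subjects <- unique(trials$subject_id)
  rows <- lapply(subjects, function(sid) {
    tr <- trials[trials$subject_id == sid, , drop = FALSE]
    subject_measures(tr, sid, K, pad_scheme, baseline_contrast,
                     equal_variance_memory, imageability_split)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# Internal: measures for one subject.
subject_measures <- function(tr, sid, K, pad_scheme, baseline_contrast,
                             equal_variance_memory = TRUE,
                             imageability_split = TRUE) {
  grab <- function(expr) tryCatch(expr, error = function(e) NULL)
  fin <- function(x) if (is.null(x) || !is.finite(x)) NA_real_ else x

  perc <- tr[tr$task == "perceptual", , drop = FALSE]
  mem <- tr[tr$task == "memory", , drop = FALSE]
  out <- list(subject_id = sid, group = tr$group[1L])

  # --- perceptual ---
  p_d <- p_c <- p_m <- p_thr <- p_acc <- p_conf <- p_rt <- p_ct <- NA_real_
  if (nrow(perc) > 0) {
    p_acc <- mean(perc$correct)
    p_conf <- mean(perc$confidence)
    p_rt <- mean(perc$rt_ms)
    p_ct <- mean(perc$ct_ms)
    if (all(is.finite(perc$contrast))) {
      delta <- perc$contrast - baseline_contrast
      rev_ <- find_reversals(c(delta, delta[length(delta)]))
      p_thr <- threshold_from_deltas(delta, rev_)
    }
    tab <- grab(pad_counts(counts_from_trials(perc, K = K), pad_scheme))
    if (!is.null(tab)) {
      t1 <- grab(fit_type1_equal(tab))
      if (!is.null(t1)) {
        p_d <- t1$d_prime
        p_c <- t1$criterion_c
        t2 <- grab(fit_meta_d(tab, t1, "equal"))
        if (!is.null(t2)) p_m <- grab(m_ratio(t1, t2)$m_ratio)
      }
    }
  }

  # --- memory ---
  m_da <- m_s <- m_d <- m_uv <- m_ev <- m_hi <- m_lo <- NA_real_
  m_acc <- m_conf <- m_rt <- m_ct <- NA_real_
  if (nrow(mem) > 0) {
    m_acc <- mean(mem$correct)
    m_conf <- mean(mem$confidence)
    m_rt <- mean(mem$rt_ms)
    m_ct <- mean(mem$ct_ms)
    tab <- grab(pad_counts(counts_from_trials(mem, K = K), pad_scheme))
    if (!is.null(tab)) {
      t1u <- grab(fit_type1_unequal(tab))
      if (!is.null(t1u)) {
        m_da <- t1u$da
        m_s <- t1u$s
        t2u <- grab(fit_meta_d(tab, t1u, "unequal"))
        if (!is.null(t2u)) m_uv <- grab(m_ratio(t1u, t2u)$m_ratio)
      }
      t1e <- if (equal_variance_memory) grab(fit_type1_equal(tab)) else NULL
      if (!is.null(t1e)) {
        m_d <- t1e$d_prime
        t2e <- grab(fit_meta_d(tab, t1e, "equal"))
        if (!is.null(t2e)) m_ev <- grab(m_ratio(t1e, t2e)$m_ratio)
      }
    }
    if (imageability_split && "imageability" %in% names(mem)) {
      for (img in c("high", "low")) {
        sub <- mem[!is.na(mem$imageability) & mem$imageability == img, ,
                   drop = FALSE]
        if (nrow(sub) > 0) {
          val <- grab({
            tb <- pad_counts(counts_from_trials(sub, K = K), pad_scheme)
            t1s <- fit_type1_unequal(tb)
            m_ratio(t1s, fit_meta_d(tb, t1s, "unequal"))$m_ratio
          })
          if (img == "high") m_hi <- fin(val) else m_lo <- fin(val)
        }
      }
    }
  }

  res <- data.frame(
    subject_id = sid, group = tr$group[1L],
    perc_accuracy = fin(p_acc), perc_threshold = fin(p_thr),
    perc_d_prime = fin(p_d), perc_criterion = fin(p_c),
    perc_mean_conf = fin(p_conf), perc_m_ratio = fin(p_m),
    perc_mean_rt = fin(p_rt), perc_mean_ct = fin(p_ct),
    mem_accuracy = fin(m_acc), mem_da = fin(m_da), mem_s = fin(m_s),
    mem_d_prime = fin(m_d), mem_mean_conf = fin(m_conf),
    mem_m_ratio_uv = fin(m_uv), mem_m_ratio_ev = fin(m_ev),
    mem_m_ratio_high = fin(m_hi), mem_m_ratio_low = fin(m_lo),
    mem_mean_rt = fin(m_rt), mem_mean_ct = fin(m_ct),
    stringsAsFactors = FALSE)
  res$complete <- nrow(perc) > 0 && nrow(mem) > 0 &&
    is.finite(res$perc_m_ratio) && is.finite(res$mem_m_ratio_uv)
  res
}
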