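# Calibrated mapping between generative noise and M-ratio.
#
# The additive-noise observer does not admit an exact closed form for the
# fitted M-ratio: conditioning on the response makes fitted meta-d'
# fall faster with metacognitive noise than the naive evidence-SD
# rescaling suggests. The mapping is therefore calibrated once by
# simulation (400k-trial sessions, two fixed seeds per grid point,
# sensitivity 1.1, the default confidence criteria) and stored as a
# monotone lookup curve; `calibrate_noise_map()` reproduces the
# procedure.

# Fitted M-ratio as a function of meta_noise_sd (choice noise 0).
meta_noise_curve <- data.frame(
  sigma = c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2, 2.25, 2.5, 2.75, 3,
            3.5, 4, 4.5, 5),
  m_ratio = c(1, 0.9285, 0.7772, 0.6336, 0.5239, 0.4430, 0.3825, 0.3351,
              0.2969, 0.2671, 0.2429, 0.2222, 0.2046, 0.1758, 0.1552,
              0.1390, 0.1251))

# Fitted M-ratio as a function of choice_noise_sd (meta noise 0).
choice_noise_curve <- data.frame(
  sigma = c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75),
  m_ratio = c(1, 1.0923, 1.3118, 1.6087, 1.9428, 2.2878, 2.6457, 3.0063))

#' Map a target M-ratio to generative noise parameters
#'
#' Inverts the simulation-calibrated noise-to-M-ratio curves: targets
#' below 1 are produced with metacognitive noise (Gaussian noise on the
#' confidence variable only), targets above 1 with choice noise
#' (noise on the decision variable only, leaving confidence better
#' informed than the choice). Targets outside the calibrated range
#' (about 0.125 to 3) are clamped to its edge.
#'
#' @param m target M-ratio (> 0).
#' @return list with `meta_noise_sd` and `choice_noise_sd` (one of them
#'   0).
#' @export
noise_for_m_ratio <- function(m) {
  stopifnot(is.numeric(m), length(m) == 1L, is.finite(m), m > 0)
  if (m >= 1) {
    sc <- stats::approx(choice_noise_curve$m_ratio, choice_noise_curve$sigma,
                        xout = m, rule = 2)$y
    list(meta_noise_sd = 0, choice_noise_sd = sc)
  } else {
    sm <- stats::approx(rev(meta_noise_curve$m_ratio),
                        rev(meta_noise_curve$sigma), xout = m, rule = 2)$y
    list(meta_noise_sd = sm, choice_noise_sd = 0)
  }
}

#' Rebuild a noise-to-M-ratio calibration curve by simulation
#'
#' For each noise level, simulates rating sessions from the generative
#' observer, fits type-1 and type-2 models and records the mean fitted
#' M-ratio. This is the procedure behind the package's stored calibration
#' curves.
#'
#' @param sigmas noise levels to calibrate.
#' @param kind `"meta"` (noise on the confidence variable) or `"choice"`
#'   (noise on the decision variable).
#' @param n trials per session.
#' @param seeds integer seeds; sessions are averaged across them.
#' @param sensitivity generative type-1 sensitivity of the calibration
#'   observer.
#' @return data frame with columns `sigma`, `m_ratio`.
#' @export
calibrate_noise_map <- function(sigmas, kind = c("meta", "choice"),
                                n = 4e5, seeds = c(11L, 12L),
                                sensitivity = 1.1) {
  kind <- match.arg(kind)
  m_of <- function(sig, seed) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    op <- observer_params(
      sensitivity = NA_real_,
      meta_noise_sd = if (kind == "meta") sig else 0,
      choice_noise_sd = if (kind == "choice") sig else 0)
    stim <- sample(c("S1", "S2"), n, replace = TRUE)
    sep <- sensitivity * sqrt(1 + op$choice_noise_sd^2)
    tr <- simulate_rating_batch(op, stim, sep)
    tab <- pad_counts(counts_from_trials(tr, K = op$K))
    t1 <- fit_type1_equal(tab)
    fit_meta_d(tab, t1, "equal")$meta_d / t1$d_prime
  }
  m <- vapply(sigmas, function(sig) {
    mean(vapply(seeds, function(sd_) m_of(sig, sd_), numeric(1)))
  }, numeric(1))
  data.frame(sigma = sigmas, m_ratio = m)
}
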