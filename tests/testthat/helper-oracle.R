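# Independent brute-force oracle for the meta-d fit: dense grid over
# meta_d with the confidence criteria profiled out by direct Nelder-Mead
# optimisation of the response-conditional multinomial likelihood.
# Written independently of the package's fitting path: log-increment
# (not softplus) criterion parameterisation, per-response-side profiling
# (the likelihood separates across sides once meta_d is fixed), and no
# analytic gradients.

# Negative log-likelihood of one response side for candidate meta_d m.
# side = "S2": criteria tc + cumsum(exp(eps)) above tc, cells ordered
# conf 1..K; side = "S1": mirrored below tc.
oracle_side_nll <- function(eps, m, tc, s, K, counts_side, side) {
  mu <- c(-1, 1) * m * sqrt((1 + 1 / s^2) / 2) / 2
  sdv <- c(1, 1 / s)
  crit <- if (side == "S2") tc + cumsum(exp(eps)) else tc - cumsum(exp(eps))
  nll <- 0
  for (i in 1:2) {
    if (side == "S2") {
      bounds <- c(tc, crit, Inf)
      upper_tail <- 1 - stats::pnorm((bounds - mu[i]) / sdv[i])
      p <- upper_tail[1:K] - upper_tail[2:(K + 1)]
      denom <- upper_tail[1L]
    } else {
      bounds <- c(tc, crit, -Inf)
      lower_tail <- stats::pnorm((bounds - mu[i]) / sdv[i])
      p <- lower_tail[1:K] - lower_tail[2:(K + 1)]
      denom <- lower_tail[1L]
    }
    nll <- nll - sum(counts_side[i, ] * log(pmax(p / max(denom, 1e-300),
                                                 1e-300)))
  }
  nll
}

# Profiled negative log-likelihood at a fixed meta_d (criteria optimised
# per response side), with warm starting.
oracle_profile_nll <- function(m, tc_of_m, s, K, n_s1side, n_s2side,
                               warm = NULL) {
  tc <- tc_of_m(m)
  start1 <- if (is.null(warm)) rep(log(0.4), K - 1) else warm$s1
  start2 <- if (is.null(warm)) rep(log(0.4), K - 1) else warm$s2
  o1 <- stats::optim(start1, oracle_side_nll, m = m, tc = tc, s = s, K = K,
                     counts_side = n_s1side, side = "S1",
                     method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10))
  o2 <- stats::optim(start2, oracle_side_nll, m = m, tc = tc, s = s, K = K,
                     counts_side = n_s2side, side = "S2",
                     method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-10))
  list(nll = o1$value + o2$value, warm = list(s1 = o1$par, s2 = o2$par))
}

# Grid-search oracle: coarse pass over [-3, 3] then a fine 0.005-step
# pass around the coarse optimum. Returns the meta_d grid argmin.
oracle_meta_d <- function(table, type1, variance_model = "equal",
                          coarse_step = 0.05, fine_step = 0.005,
                          span = 3) {
  K <- table$K
  s <- if (variance_model == "unequal") type1$s else 1
  sens <- if (variance_model == "unequal") type1$da else type1$d_prime
  crit <- if (variance_model == "unequal") type1$c_a else type1$criterion_c
  c_rel <- if (abs(sens) > 1e-3) crit / sens else 0
  c_rel <- max(min(c_rel, 5), -5)
  b <- sqrt((1 + s^2) / 2) / s
  tc_of_m <- function(m) m * c_rel * b

  # response-side count matrices [stimulus, confidence 1..K]
  n_s1side <- cbind(table$counts[, "S1", ])  # 2 x K
  n_s2side <- cbind(table$counts[, "S2", ])

  eval_grid <- function(grid) {
    warm <- NULL
    vals <- numeric(length(grid))
    warms <- vector("list", length(grid))
    for (i in seq_along(grid)) {
      r <- oracle_profile_nll(grid[i], tc_of_m, s, K, n_s1side, n_s2side,
                              warm = warm)
      vals[i] <- r$nll
      warm <- r$warm
      warms[[i]] <- r$warm
    }
    list(vals = vals, warms = warms)
  }

  coarse <- seq(-span, span, by = coarse_step)
  rc <- eval_grid(coarse)
  i0 <- which.min(rc$vals)
  fine <- seq(max(-span, coarse[i0] - coarse_step),
              min(span, coarse[i0] + coarse_step), by = fine_step)
  rf <- eval_grid(fine)
  fine[which.min(rf$vals)]
}

# Random rating table with n trials: random sensitivity, criterion and
# confidence behavior, sampled through the package's generative observer.
random_rating_table <- function(n, K = 6) {
  d <- stats::runif(1, 0.3, 2)
  off <- sort(stats::runif(K - 1, -1.2, 1.4))
  while (min(diff(off)) < 0.05) off <- sort(stats::runif(K - 1, -1.2, 1.4))
  op <- observer_params(sensitivity = d,
                        criterion = stats::runif(1, -0.3, 0.3),
                        meta_noise_sd = stats::runif(1, 0, 1.2),
                        confidence_offsets = off, K = K)
  stim <- sample(c("S1", "S2"), n, replace = TRUE)
  tr <- do.call(rbind, lapply(seq_len(n), function(i) {
    simulate_trial(op, stim[i])
  }))
  pad_counts(counts_from_trials(tr, K = K))
}
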