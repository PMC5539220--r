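# Exact joint type-2 model counts (expected counts, possibly scaled) for
# a meta-level observer; used as noise-free input for recovery checks.
exact_t2_table <- function(meta_d, c_rel = 0, s = 1,
                           offsets = c(-0.7, -0.25, 0.2, 0.65, 1.2),
                           n = 1e5) {
  K <- length(offsets) + 1
  b <- sqrt((1 + s^2) / 2) / s
  tc <- meta_d * c_rel * b
  cvec <- c(tc - rev(offsets + 1.5), tc, tc + offsets + 1.5)
  sep <- meta_d * sqrt((1 + 1 / s^2) / 2)
  cnt <- array(0, dim = c(2, 2, K))
  for (i in 1:2) {
    mu <- c(-sep / 2, sep / 2)[i]
    sdv <- c(1, 1 / s)[i]
    p <- diff(c(0, pnorm((cvec - mu) / sdv), 1))
    cnt[i, 1, ] <- rev(p[1:K]) * n
    cnt[i, 2, ] <- p[(K + 1):(2 * K)] * n
  }
  pad_counts(rating_table(cnt), "none")
}

test_that("predicted rating probabilities normalise and lose stimulus
           dependence at zero meta sensitivity", {
  cs1 <- seq(-2, -0.4, length.out = 5)
  cs2 <- seq(0.4, 2, length.out = 5)
  p0 <- type2_predicted_probs(0, 0, cs1, cs2)
  expect_equal(unname(p0["S1", "S1", ]), unname(p0["S2", "S1", ]),
               tolerance = 1e-12)
  expect_equal(unname(p0["S1", "S2", ]), unname(p0["S2", "S2", ]),
               tolerance = 1e-12)

  p <- type2_predicted_probs(1.5, 0.2, cs1, cs2, s = 0.8)
  expect_true(all(p >= 0))
  expect_equal(unname(apply(p, c(1, 2), sum)), matrix(1, 2, 2),
               tolerance = 1e-10)
})

test_that("predicted probabilities equal direct Gaussian-CDF arithmetic", {
  cs1 <- c(-1.5, -1, -0.5, -0.25, -0.1)
  cs2 <- c(0.1, 0.25, 0.5, 1, 1.5)
  m <- 1.5
  p <- type2_predicted_probs(m, 0, cs1, cs2)
  # independent arithmetic: S2 stimulus sits at +m/2, S1 at -m/2
  for (stim_mu in c(-m / 2, m / 2)) {
    i <- if (stim_mu < 0) "S1" else "S2"
    P <- pnorm(c(cs1, 0, cs2), mean = stim_mu)
    cells <- diff(c(0, P, 1))
    expect_equal(unname(p[i, "S1", ]), rev(cells[1:6]) / P[6],
                 tolerance = 1e-12)
    expect_equal(unname(p[i, "S2", ]), cells[7:12] / (1 - P[6]),
                 tolerance = 1e-12)
  }
})

test_that("non-monotone criteria are rejected", {
  expect_error(type2_predicted_probs(1, 0, c(-1, -2, -0.5, -0.4, -0.3),
                                     seq(0.5, 2, length.out = 5)),
               "not monotone")
  expect_error(type2_predicted_probs(1, 0, seq(-2, -0.5, length.out = 5),
                                     seq(0.5, 2, length.out = 5) - 3),
               "not monotone")
})

test_that("meta_d is recovered from exact model counts", {
  for (m_true in c(0.6, 1.0, 1.8)) {
    tab <- exact_t2_table(m_true, c_rel = 0.1)
    t1 <- fit_type1_equal(tab)
    t2 <- fit_meta_d(tab, t1, "equal")
    expect_true(t2$converged)
    expect_lt(abs(t2$meta_d - m_true), 0.005)
    expect_lte(t2$log_likelihood, 0)
  }
  # unequal-variance version
  tab <- exact_t2_table(1.2, c_rel = 0.15, s = 0.8)
  t1 <- fit_type1_unequal(tab)
  t2 <- fit_meta_d(tab, t1, "unequal")
  expect_lt(abs(t2$meta_d - 1.2), 0.01)
  expect_equal(t2$s, t1$s)
})

test_that("sampled ideal observers show meta_d near d' (M-ratio near 1)", {
  set.seed(11)
  op <- observer_params(sensitivity = 1.2, meta_noise_sd = 0)
  stim <- sample(c("S1", "S2"), 1e5, replace = TRUE)
  tr <- metacogsdt:::simulate_rating_batch(op, stim, 1.2)
  tab <- pad_counts(counts_from_trials(tr))
  t1 <- fit_type1_equal(tab)
  t2 <- fit_meta_d(tab, t1, "equal")
  expect_lt(abs(t2$meta_d - t1$d_prime), 0.05)
  expect_lt(abs(m_ratio(t1, t2)$m_ratio - 1), 0.05)
})

# Joint cell probabilities of the full meta-d data-generating model:
# type-1 choices from the d' model, response-conditional confidence from
# the meta_d model with the criterion carried at c' = c_rel.
metad_joint_probs <- function(d, m, c_rel,
                              offsets = c(-0.7, -0.25, 0.2, 0.65, 1.2)) {
  tc1 <- d * c_rel
  tcm <- m * c_rel
  cvec <- c(tcm - rev(offsets + 1.5), tcm, tcm + offsets + 1.5)
  joint <- array(0, dim = c(2, 2, 6))
  for (i in 1:2) {
    mu1 <- c(-d / 2, d / 2)[i]
    mum <- c(-m / 2, m / 2)[i]
    r1 <- pnorm(tc1 - mu1)                      # P(resp S1 | stim) from d'
    P <- pnorm(cvec - mum)
    cells <- diff(c(0, P, 1))
    joint[i, 1, ] <- r1 * rev(cells[1:6]) / P[6]
    joint[i, 2, ] <- (1 - r1) * cells[7:12] / (1 - P[6])
  }
  joint
}

test_that("multinomial sampling recovers meta_d across the d' x meta_d grid", {
  set.seed(22)
  for (d in c(1, 1.5)) {
    for (m_true in c(0, 0.5, 1.0, 1.5)) {
      joint <- metad_joint_probs(d, m_true, c_rel = 0.1)
      rec <- vapply(1:3, function(r) {
        cnt <- array(0, dim = c(2, 2, 6))
        for (i in 1:2) {
          draw <- rmultinom(1, 5000, c(joint[i, 1, ], joint[i, 2, ]))[, 1]
          cnt[i, 1, ] <- draw[1:6]
          cnt[i, 2, ] <- draw[7:12]
        }
        tab <- pad_counts(rating_table(cnt))
        t1 <- fit_type1_equal(tab)
        fit_meta_d(tab, t1, "equal")$meta_d
      }, numeric(1))
      expect_lt(abs(mean(rec) - m_true), 0.1)
    }
  }
})

test_that("fitted meta_d matches the independent grid-search oracle", {
  set.seed(33)
  for (i in 1:5) {
    tab <- random_rating_table(n = sample(50:500, 1))
    t1 <- fit_type1_equal(tab)
    t2 <- fit_meta_d(tab, t1, "equal")
    oracle <- oracle_meta_d(tab, t1, "equal")
    expect_lt(abs(t2$meta_d - oracle), 0.01)
  }
})

test_that("equal-variance fit is the s = 1 special case of the unequal fit", {
  set.seed(44)
  tab <- random_rating_table(400)
  t1u <- fit_type1_unequal(tab)
  t1u$s <- 1
  t1u$da <- t1u$d_prime
  t1u$c_a <- t1u$criterion_c
  pinned <- fit_meta_d(tab, t1u, "unequal")
  equal <- fit_meta_d(tab, fit_type1_equal(tab), "equal")
  expect_lt(abs(pinned$meta_d - equal$meta_d), 1e-4)
})

test_that("degenerate confidence data are refused", {
  tr <- data.frame(stimulus = rep(c("S1", "S2"), each = 40),
                   response = rep(c("S1", "S2", "S1", "S2"), each = 20),
                   confidence = 4)
  tab <- pad_counts(counts_from_trials(tr))
  t1 <- fit_type1_equal(tab)
  expect_error(fit_meta_d(tab, t1, "equal"), "degenerate")
})

test_that("M-ratio is the exact sensitivity ratio and keeps its sign", {
  tab <- exact_t2_table(0.5)
  t1 <- fit_type1_equal(tab)      # d' = 0.5 by construction
  t2 <- fit_meta_d(tab, t1, "equal")
  mm <- m_ratio(t1, t2)
  expect_equal(mm$m_ratio, t2$meta_d / t1$d_prime)
  expect_equal(mm$variant, "equal")

  # negative meta_d yields a negative, preserved M-ratio
  t2neg <- t2
  t2neg$meta_d <- -0.3
  expect_equal(m_ratio(t1, t2neg)$m_ratio, -0.3 / t1$d_prime)
  expect_lt(m_ratio(t1, t2neg)$m_ratio, 0)

  # zero type-1 sensitivity is undefined efficiency
  t1zero <- t1
  t1zero$d_prime <- 0
  expect_error(m_ratio(t1zero, t2), "undefined efficiency")

  # mismatched variance models are refused
  t1u <- fit_type1_unequal(tab)
  expect_error(m_ratio(t1u, t2), "do not match")
})

test_that("analytic likelihood gradient matches finite differences", {
  set.seed(55)
  ev <- matrix(rpois(24, 15) + 0.5, nrow = 2)
  th <- c(0.9, rnorm(5, -0.6, 0.3), rnorm(5, -0.6, 0.3))
  an <- metacogsdt:::metad_eval(th, ev, 6, 0.85, 0.2)$grad
  num <- vapply(seq_along(th), function(j) {
    h <- 1e-6
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (metacogsdt:::metad_eval(tp, ev, 6, 0.85, 0.2, grad = FALSE)$nll -
       metacogsdt:::metad_eval(tm, ev, 6, 0.85, 0.2, grad = FALSE)$nll) / (2 * h)
  }, numeric(1))
  expect_equal(an, num, tolerance = 1e-4)
})
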