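# Helper: rating table with exact collapsed rates, counts spread over two
# middle confidence levels so no padding is needed for the collapse.
table_from_rates <- function(H, F_, n = 10000) {
  cnt <- array(0, dim = c(2, 2, 6))
  cnt[1, 2, 3:4] <- F_ * n / 2         # S1 -> S2
  cnt[1, 1, 3:4] <- (1 - F_) * n / 2
  cnt[2, 2, 3:4] <- H * n / 2
  cnt[2, 1, 3:4] <- (1 - H) * n / 2
  pad_counts(rating_table(cnt), "none")
}

test_that("d' and c match the z-transform closed form to machine precision", {
  fit <- fit_type1_equal(table_from_rates(0.71, 0.29))
  expect_equal(fit$d_prime, qnorm(0.71) - qnorm(0.29), tolerance = 1e-12)
  expect_equal(fit$d_prime, 1.1068, tolerance = 1e-4)
  expect_equal(fit$criterion_c, 0, tolerance = 1e-12)
  expect_equal(fit$s, 1)
  expect_equal(fit$da, fit$d_prime)

  # random rates agree with the closed form exactly
  set.seed(1)
  for (i in 1:10) {
    H <- runif(1, 0.05, 0.95)
    F_ <- runif(1, 0.05, 0.95)
    f <- fit_type1_equal(table_from_rates(H, F_))
    expect_equal(f$d_prime, qnorm(H) - qnorm(F_), tolerance = 1e-12)
    expect_equal(f$criterion_c, -(qnorm(H) + qnorm(F_)) / 2, tolerance = 1e-12)
  }
})

test_that("no sensitivity and unbiased cases behave as expected", {
  expect_equal(fit_type1_equal(table_from_rates(0.6, 0.6))$d_prime, 0,
               tolerance = 1e-12)
  f <- fit_type1_equal(table_from_rates(0.5, 0.5))
  expect_equal(f$criterion_c, 0, tolerance = 1e-12)
  expect_equal(f$d_prime, 0, tolerance = 1e-12)
})

test_that("rates at 0/1 are reported as a broken padding contract", {
  cnt <- array(0, dim = c(2, 2, 6))
  cnt[1, 1, 3] <- 50
  cnt[2, 2, 3] <- 50  # H = 1, F = 0
  tab <- rating_table(cnt)
  tab$pad_scheme <- "none"
  expect_error(fit_type1_equal(tab), "padding contract")
})

# Exact rating table from a closed-form unequal-variance Gaussian model.
exact_uv_table <- function(mu2, s, cvec, n = 1e6) {
  K <- (length(cvec) + 1) / 2
  cnt <- array(0, dim = c(2, 2, K))
  for (i in 1:2) {
    mu <- if (i == 1) 0 else mu2
    sdv <- if (i == 1) 1 else 1 / s
    p <- diff(c(0, pnorm((cvec - mu) / sdv), 1))
    cnt[i, 1, ] <- rev(p[1:K]) * n
    cnt[i, 2, ] <- p[(K + 1):(2 * K)] * n
  }
  pad_counts(rating_table(cnt), "none")
}

test_that("zROC slope is recovered exactly from a closed-form model", {
  cvec <- seq(-1.2, 2.2, length.out = 11)
  tab <- exact_uv_table(mu2 = 1.4, s = 0.9, cvec = cvec)
  fit <- fit_type1_unequal(tab)
  expect_equal(fit$s, 0.9, tolerance = 1e-8)
  # da against its defining formula at the collapsed operating point
  zH <- qnorm(fit$hit_rate)
  zF <- qnorm(fit$fa_rate)
  expect_equal(fit$da, sqrt(2 / (1 + 0.9^2)) * (zH - 0.9 * zF),
               tolerance = 1e-8)
  # and against the generative separation: da = mu2 * sqrt(2/(1 + 1/s^2))
  expect_equal(fit$da, 1.4 * sqrt(2 / (1 + 1 / 0.9^2)), tolerance = 1e-8)

  # equal-variance limit: s = 1 gives da = d'
  tab1 <- exact_uv_table(mu2 = 1.2, s = 1, cvec = cvec)
  f1 <- fit_type1_unequal(tab1)
  expect_equal(f1$s, 1, tolerance = 1e-8)
  expect_equal(f1$da, f1$d_prime, tolerance = 1e-10)
  expect_equal(f1$c_a, f1$criterion_c, tolerance = 1e-10)
})

test_that("generative evidence-SD ratio is recovered from sampled data", {
  set.seed(202)
  op <- observer_params(sensitivity = 1.5, s = 0.8, meta_noise_sd = 0.3)
  stim <- sample(c("S1", "S2"), 10000, replace = TRUE)
  sep <- 1.5 * sqrt((1 + 1 / 0.8^2) / 2)
  tr <- metacogsdt:::simulate_rating_batch(op, stim, sep)
  fit <- fit_type1_unequal(pad_counts(counts_from_trials(tr)))
  expect_lt(abs(fit$s - 0.8), 0.05)
  expect_lt(abs(fit$da - 1.5), 0.1)
})

test_that("estimates are invariant to trial order and monotone in sensitivity", {
  set.seed(303)
  op <- observer_params(sensitivity = 1.0, meta_noise_sd = 0.5)
  stim <- sample(c("S1", "S2"), 4000, replace = TRUE)
  tr <- metacogsdt:::simulate_rating_batch(op, stim, 1.0)
  shuffled <- tr[sample.int(nrow(tr)), ]
  f1 <- fit_type1_equal(pad_counts(counts_from_trials(tr)))
  f2 <- fit_type1_equal(pad_counts(counts_from_trials(shuffled)))
  expect_identical(f1$d_prime, f2$d_prime)

  tr_hi <- metacogsdt:::simulate_rating_batch(op, stim, 1.8)
  f_hi <- fit_type1_equal(pad_counts(counts_from_trials(tr_hi)))
  expect_gt(f_hi$d_prime, f1$d_prime)
})

test_that("unequal fit demands enough usable ROC structure", {
  cnt <- array(0, dim = c(2, 2, 2))
  cnt[, , 1] <- 10
  cnt[, , 2] <- 10
  expect_error(fit_type1_unequal(rating_table(cnt)), "K >= 3")
})
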