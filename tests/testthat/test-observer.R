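test_that("single trials carry valid fields and the degenerate limits hold", {
  set.seed(1)
  op <- observer_params(sensitivity = 8, meta_noise_sd = 0)
  tr <- do.call(rbind, lapply(1:200, function(i) simulate_trial(op, "S2")))
  expect_true(all(tr$confidence %in% 1:6))
  expect_true(all(tr$rt_ms > 0 & tr$ct_ms > 0))
  expect_gt(mean(tr$correct), 0.98)          # near-perfect at huge d'
  expect_gt(mean(tr$confidence == 6), 0.9)   # noise-free: top confidence

  op0 <- observer_params(sensitivity = 0)
  stim <- sample(c("S1", "S2"), 4e4, replace = TRUE)
  tr0 <- metacogsdt:::simulate_rating_batch(op0, stim, 0)
  expect_lt(abs(mean(tr0$correct) - 0.5), 0.02)
})

test_that("generative accuracy matches the closed-form Gaussian prediction", {
  set.seed(2)
  for (d in c(0.8, 1.5)) {
    op <- observer_params(sensitivity = d)
    stim <- sample(c("S1", "S2"), 4e4, replace = TRUE)
    tr <- metacogsdt:::simulate_rating_batch(op, stim, d)
    pred <- pnorm(d / 2)
    se <- sqrt(pred * (1 - pred) / 4e4)
    expect_lt(abs(mean(tr$correct) - pred), 4 * se + 0.002)
  }
})

test_that("memory session design is balanced old/new x imageability", {
  set.seed(3)
  op <- observer_params(sensitivity = 1, s = 0.8)
  mem <- simulate_memory_session(op)
  expect_equal(nrow(mem), 200)
  cells <- table(mem$stimulus, mem$imageability)
  expect_true(all(cells == 50))

  tiny <- simulate_memory_session(op, n_learn = 2, n_test = 4)
  expect_true(all(table(tiny$stimulus, tiny$imageability) == 1))

  expect_error(simulate_memory_session(op, n_learn = 3, n_test = 6), "even")
  expect_error(simulate_memory_session(op, n_learn = 100, n_test = 150),
               "n_test")
})

test_that("choice noise needs equal variances and bad params are refused", {
  expect_error(observer_params(s = 0.8, choice_noise_sd = 0.5), "s = 1")
  expect_error(observer_params(meta_noise_sd = -1))
  expect_error(observer_params(confidence_offsets = c(1, 0.5, 2, 3, 4)))
})

test_that("noise mapping is monotone and anchored at the ideal observer", {
  expect_equal(noise_for_m_ratio(1)$meta_noise_sd, 0)
  expect_equal(noise_for_m_ratio(1)$choice_noise_sd, 0)
  sig <- vapply(c(0.9, 0.7, 0.5, 0.3),
                function(m) noise_for_m_ratio(m)$meta_noise_sd, numeric(1))
  expect_true(all(diff(sig) > 0))   # lower target M needs more noise
  sc <- vapply(c(1.1, 1.4, 1.8),
               function(m) noise_for_m_ratio(m)$choice_noise_sd, numeric(1))
  expect_true(all(diff(sc) > 0))
  expect_equal(noise_for_m_ratio(0.7)$choice_noise_sd, 0)
  expect_equal(noise_for_m_ratio(1.4)$meta_noise_sd, 0)
})

test_that("calibration rebuild reproduces the stored curve at its seeds", {
  pt <- calibrate_noise_map(0.75, kind = "meta", n = 1e5)
  stored <- metacogsdt:::meta_noise_curve
  expect_lt(abs(pt$m_ratio - stored$m_ratio[stored$sigma == 0.75]), 0.03)
})

test_that("cohort generation is reproducible and matches its manifest", {
  spec <- cohort_spec(n_sdi = 3, n_control = 3)
  c1 <- simulate_cohort(spec, seed = 42)
  c2 <- simulate_cohort(spec, seed = 42)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$manifest, c2$manifest)
  c3 <- simulate_cohort(spec, seed = 43)
  expect_false(identical(c1$trials, c3$trials))

  # manifest and data never disagree on staircase accuracy
  perc <- c1$trials[c1$trials$task == "perceptual", ]
  acc <- tapply(perc$correct, perc$subject_id, mean)
  expect_equal(as.numeric(acc[c1$manifest$subject_id]),
               c1$manifest$perc_accuracy)

  # schema is valid as produced
  expect_silent(validate_trials(c1$trials))
})

test_that("default cohort lands in the reported confidence band", {
  ch <- simulate_cohort(cohort_spec(), seed = 7)
  for (g in c("sdi", "control")) {
    tr <- ch$trials[ch$trials$group == g, ]
    expect_gt(mean(tr$confidence), 4.3)
    expect_lt(mean(tr$confidence), 5.1)
  }
})
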