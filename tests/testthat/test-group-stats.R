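mk_measures <- function(a, b, col = "x") {
  out <- data.frame(group = rep(c("sdi", "control"), c(length(a), length(b))))
  out[[col]] <- c(a, b)
  out
}

test_that("identical groups give t = 0, p = 1", {
  cmp <- compare_groups(mk_measures(c(1, 2, 3), c(1, 2, 3)), "x")
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("pooled t-test matches the textbook closed form to 4 decimals", {
  cmp <- compare_groups(mk_measures(c(1, 2, 3), c(4, 5, 6)), "x")
  expect_equal(cmp$variance_assumption, "pooled")
  # hand computation: means 2 and 5, pooled variance 1, se = sqrt(2/3)
  t_hand <- (2 - 5) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(round(cmp$t_statistic, 3), -3.674)
  expect_equal(cmp$p_value, 2 * pt(t_hand, df = 4), tolerance = 1e-10)
  expect_equal(round(cmp$p_value, 4), 0.0213)
  expect_equal(cmp$df, 4)
})

test_that("Levene decides between pooled and Welch branches", {
  set.seed(10)
  a <- rnorm(20, 0, 1)
  b <- rnorm(20, 0, 8)
  cmp <- compare_groups(mk_measures(a, b), "x")
  expect_lt(cmp$levene_p, 0.05)
  expect_equal(cmp$variance_assumption, "welch")
  # Welch statistic and Satterthwaite df by hand
  se2 <- var(a) / 20 + var(b) / 20
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 20)^2 / 19 + (var(b) / 20)^2 / 19)
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(cmp$df, df_hand, tolerance = 1e-8)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)

  # same-variance samples take the pooled branch
  set.seed(13)
  cmp2 <- compare_groups(mk_measures(rnorm(15), rnorm(15)), "x")
  expect_gte(cmp2$levene_p, 0.05)
  expect_equal(cmp2$variance_assumption, "pooled")
  expect_equal(cmp2$df, 28)
})

test_that("group comparison refuses degenerate group sizes", {
  expect_error(compare_groups(mk_measures(c(1, 2), c(3, NA)), "x"),
               "at least 2 finite")
})

test_that("Pearson correlation matches hand computation", {
  expect_equal(pearson_cor(1:10, 1:10)$r, 1, tolerance = 1e-12)
  # hand computation: centered cross product 9, SDs sqrt(10) each
  res <- pearson_cor(c(1, 2, 3, 4, 5), c(2, 1, 3, 4, 5))
  expect_equal(res$r, 9 / 10, tolerance = 1e-12)
  expect_equal(round(res$r, 4), 0.9)
  # two-tailed p from the t transform of r with n - 2 df
  t_r <- res$r * sqrt(3 / (1 - res$r^2))
  expect_equal(res$p_value, 2 * pt(-abs(t_r), df = 3), tolerance = 1e-10)

  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_cor(c(1, 2), c(1, 2)), "at least 3")
})

mk_long <- function(y_sdi_t1, y_sdi_t2, y_ctl_t1, y_ctl_t2) {
  n1 <- length(y_sdi_t1)
  n2 <- length(y_ctl_t1)
  ids <- c(sprintf("s%02d", seq_len(n1)), sprintf("c%02d", seq_len(n2)))
  data.frame(
    subject_id = rep(ids, times = 2),
    group = rep(rep(c("sdi", "control"), c(n1, n2)), 2),
    task = rep(c("perceptual", "memory"), each = n1 + n2),
    value = c(y_sdi_t1, y_ctl_t1, y_sdi_t2, y_ctl_t2))
}

test_that("mixed ANOVA agrees with its t-test decompositions", {
  set.seed(20)
  a1 <- rnorm(10, 1.0, 0.5); a2 <- rnorm(10, 1.4, 0.5)
  b1 <- rnorm(12, 1.2, 0.5); b2 <- rnorm(12, 1.3, 0.5)
  res <- mixed_anova(mk_long(a1, a2, b1, b2))
  tab <- res$table
  expect_equal(tab$effect, c("group", "task", "group:task"))

  # group main effect F equals the squared pooled t on subject means
  t_group <- t.test((a1 + a2) / 2, (b1 + b2) / 2, var.equal = TRUE)$statistic
  expect_equal(tab$F[tab$effect == "group"], unname(t_group)^2,
               tolerance = 1e-8)

  # interaction F equals the squared pooled t on within-subject differences
  t_int <- t.test(a1 - a2, b1 - b2, var.equal = TRUE)$statistic
  expect_equal(tab$F[tab$effect == "group:task"], unname(t_int)^2,
               tolerance = 1e-8)

  # partial eta^2 identity for df1 = 1 effects
  expect_equal(tab$eta_sq_partial,
               tab$F / (tab$F + tab$df2), tolerance = 1e-10)
  expect_equal(tab$df2[tab$effect == "group"], 20)
})

test_that("mixed ANOVA handles planted effects, dropouts and constants", {
  set.seed(21)
  base <- rnorm(24, 0, 0.1)
  # pure interaction: group difference in one task only
  d <- mk_long(base[1:6] + 2, base[1:6], base[7:12], base[13:18])
  res <- mixed_anova(d)
  expect_lt(res$table$p[res$table$effect == "group:task"], 1e-6)

  # subject missing one task is dropped and reported
  d2 <- d[-1, ]
  res2 <- mixed_anova(d2)
  expect_equal(res2$dropped, "s01")

  # constant dependent variable flagged degenerate
  d3 <- d
  d3$value <- 1
  res3 <- mixed_anova(d3)
  expect_true(res3$degenerate)
  expect_true(all(res3$table$F == 0))
})
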