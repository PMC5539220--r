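# Group-level statistics: Levene-guided two-sample t-tests, the mixed
# Group x Task ANOVA with partial eta-squared, and Pearson correlations.

#' Compare a measure between the two groups
#'
#' Classic Levene's test (absolute deviations from the group means)
#' decides the variance assumption at the given alpha: the pooled
#' two-sample t-test when variances look equal, Welch otherwise. The
#' difference is taken in the order of `group_levels` (first minus
#' second), and the p-value is two-tailed.
#'
#' @param measures data frame from [extract_measures()] (or any frame
#'   with a `group` column and the measure column).
#' @param measure name of the measure column.
#' @param alpha significance level for Levene's test (default 0.05).
#' @param group_levels order of the two groups (default
#'   `c("sdi", "control")`, so negative t means the patient group is
#'   lower).
#' @return object of class `group_comparison` with group means/SDs/n,
#'   `levene_p`, `variance_assumption` (`"pooled"` or `"welch"`),
#'   `t_statistic`, `df` (fractional for Welch), `p_value`, `alpha`.
#' @export
compare_groups <- function(measures, measure, alpha = 0.05,
                           group_levels = c("sdi", "control")) {
  stopifnot(is.data.frame(measures), measure %in% names(measures),
            "group" %in% names(measures), length(group_levels) == 2L)
  g <- factor(measures$group, levels = group_levels)
  v <- measures[[measure]]
  keep <- !is.na(v) & !is.na(g)
  g <- droplevels(g[keep])
  v <- v[keep]
  ns <- table(g)
  if (length(ns) < 2L || any(ns < 2L)) {
    stop("need at least 2 finite values per group for measure '", measure, "'")
  }
  lev <- car::leveneTest(v ~ g, center = mean)
  levene_p <- lev[["Pr(>F)"]][1L]
  pooled <- is.na(levene_p) || levene_p >= alpha
  tt <- stats::t.test(v[g == group_levels[1L]], v[g == group_levels[2L]],
                      var.equal = pooled)
  structure(list(
    measure = measure,
    groups = group_levels,
    n = as.integer(ns[group_levels]),
    means = vapply(group_levels, function(l) mean(v[g == l]), numeric(1)),
    sds = vapply(group_levels, function(l) stats::sd(v[g == l]), numeric(1)),
    levene_p = levene_p,
    variance_assumption = if (pooled) "pooled" else "welch",
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    alpha = alpha), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s %.2f (%.2f) vs %s %.2f (%.2f)\n", x$measure,
              x$groups[1], x$means[1], x$sds[1],
              x$groups[2], x$means[2], x$sds[2]))
  cat(sprintf("  Levene p = %.3f -> %s t(%.1f) = %.3f, p = %.4f\n",
              x$levene_p, x$variance_assumption, x$df, x$t_statistic,
              x$p_value))
  invisible(x)
}

#' Mixed two-factor ANOVA (between group x within condition)
#'
#' Classic mixed-design ANOVA via `aov` with an error stratum per
#' subject: one between-subject factor (group) and one within-subject
#' factor with two levels (e.g. task, or word imageability). Reports F,
#' degrees of freedom, p and partial eta-squared
#' (SS_effect / (SS_effect + SS_error of the matching stratum)) for the
#' group and condition main effects and their interaction. Subjects with
#' a missing level are dropped (listed in `dropped`). A constant
#' dependent variable is flagged degenerate with F = 0.
#'
#' @param data long-format data frame with columns `subject_id`, `group`,
#'   a within-factor column and `value`.
#' @param within name of the within-subject factor column (default
#'   `"task"`).
#' @return object of class `mixed_anova`: data frame `table` with one row
#'   per effect plus `dropped`, `degenerate`.
#' @export
mixed_anova <- function(data, within = "task") {
  stopifnot(is.data.frame(data),
            all(c("subject_id", "group", within, "value") %in% names(data)))
  data <- data[, c("subject_id", "group", within, "value")]
  names(data)[3L] <- "cond"
  lv <- sort(unique(data$cond))
  if (length(lv) != 2L) stop("within factor must have exactly 2 levels")
  ok_subj <- vapply(split(data, data$subject_id), function(d) {
    nrow(d) == 2L && setequal(d$cond, lv) && all(is.finite(d$value))
  }, logical(1))
  dropped <- names(ok_subj)[!ok_subj]
  data <- data[data$subject_id %in% names(ok_subj)[ok_subj], , drop = FALSE]
  if (length(unique(data$group)) < 2L || length(unique(data$subject_id)) < 4L) {
    stop("need complete data from at least 2 subjects per group")
  }
  if (stats::var(data$value) == 0) {
    tab <- data.frame(effect = c("group", "cond", "group:cond"),
                      df1 = 1L, df2 = NA_integer_, F = 0, p = 1,
                      eta_sq_partial = 0)
    return(structure(list(table = tab, within = within, dropped = dropped,
                          degenerate = TRUE), class = "mixed_anova"))
  }
  data$group <- factor(data$group)
  data$cond <- factor(data$cond)
  data$subject_id <- factor(data$subject_id)
  fit <- stats::aov(value ~ group * cond + Error(subject_id / cond),
                    data = data)
  sm <- summary(fit)
  btw <- as.data.frame(sm[["Error: subject_id"]][[1L]])
  wth <- as.data.frame(sm[["Error: subject_id:cond"]][[1L]])
  clean <- function(x) trimws(x)
  row_of <- function(tab, nm) which(clean(rownames(tab)) == nm)
  eff <- function(tab, nm) {
    i <- row_of(tab, nm)
    r <- row_of(tab, "Residuals")
    data.frame(effect = nm,
               df1 = tab$Df[i], df2 = tab$Df[r],
               F = tab$`F value`[i], p = tab$`Pr(>F)`[i],
               eta_sq_partial = tab$`Sum Sq`[i] /
                 (tab$`Sum Sq`[i] + tab$`Sum Sq`[r]))
  }
  tab <- rbind(eff(btw, "group"), eff(wth, "cond"), eff(wth, "group:cond"))
  tab$effect <- c("group", within, paste0("group:", within))
  structure(list(table = tab, within = within, dropped = dropped,
                 degenerate = FALSE), class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed ANOVA (group x ", x$within, ")",
      if (x$degenerate) " [degenerate: constant dependent variable]",
      "\n", sep = "")
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf("  %-12s F(%d,%s) = %.2f, p = %.3f, eta_p^2 = %.3f\n",
                r$effect, r$df1, format(r$df2), r$F, r$p, r$eta_sq_partial))
  }
  if (length(x$dropped)) {
    cat("  dropped (incomplete):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pearson correlation with two-tailed test
#'
#' @param x,y paired numeric vectors; pairs with missing values are
#'   dropped (at least 3 complete pairs required).
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in a variable; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
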