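#' Equal-variance type-1 SDT fit
#'
#' Collapses the rating table over confidence and estimates the classic
#' equal-variance yes/no parameters: sensitivity `d' = z(H) - z(F)` and
#' criterion `c = -(z(H) + z(F))/2`, with `H = P(respond S2 | S2)` and
#' `F = P(respond S2 | S1)`. The perceptual task is scored yes/no-style
#' over intervals (S1 = target in interval 1), not with the sqrt(2) 2-AFC
#' correction, matching how staircase-controlled oddball data are usually
#' summarised (d' near 1.1 at 71% correct).
#'
#' @param table a padded `rating_table` (see [pad_counts()]).
#' @return object of class `type1_fit`: list with `d_prime`,
#'   `criterion_c`, `hit_rate`, `fa_rate`, `s` (fixed at 1), `da`
#'   (= `d_prime`), `c_a` (= `criterion_c`), `model = "equal"`,
#'   `padding_applied`.
#' @examples
#' tr <- data.frame(stimulus = rep(c("S1", "S2"), each = 100),
#'                  response = rep(c("S1", "S2", "S1", "S2"), c(71, 29, 29, 71)),
#'                  confidence = 4)
#' fit_type1_equal(pad_counts(counts_from_trials(tr)))
#' @export
fit_type1_equal <- function(table) {
  rates <- choice_rates(table)
  zH <- stats::qnorm(rates["H"])
  zF <- stats::qnorm(rates["F"])
  structure(list(d_prime = unname(zH - zF),
                 criterion_c = unname(-(zH + zF) / 2),
                 hit_rate = unname(rates["H"]), fa_rate = unname(rates["F"]),
                 s = 1, da = unname(zH - zF), c_a = unname(-(zH + zF) / 2),
                 model = "equal", zroc = NULL,
                 padding_applied = isTRUE(table$padded)),
            class = "type1_fit")
}

#' Unequal-variance type-1 SDT fit (zROC slope and da)
#'
#' Estimates the evidence-SD ratio `s` (S1-to-S2, e.g. new-to-old in
#' recognition memory) as the slope of the zROC: ordinary least squares of
#' `z(hit cumulative)` on `z(false-alarm cumulative)` across the 2K-1
#' rating criteria, excluding endpoints at 0/1. Sensitivity is then
#' `da = sqrt(2 / (1 + s^2)) * (z(H) - s z(F))` at the choice criterion,
#' with the analogous criterion
#' `c_a = -sqrt(2 / (1 + s^2)) * (z(H) + s z(F)) / 2`; both reduce to
#' `d'` and `c` when `s = 1`.
#'
#' @param table a padded `rating_table` with `K >= 3`.
#' @return a `type1_fit` with `model = "unequal"`, fitted `s`, `da`,
#'   `c_a`, plus the equal-variance `d_prime`/`criterion_c` computed on
#'   the same collapse, and the zROC points used (`zroc`).
#' @export
fit_type1_unequal <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  if (table$K < 3) stop("unequal-variance fit needs K >= 3 confidence levels")
  rates <- choice_rates(table)
  cum <- cumulative_rates(table)
  usable <- cum["S1", ] > 0 & cum["S1", ] < 1 & cum["S2", ] > 0 & cum["S2", ] < 1
  zF <- stats::qnorm(cum["S1", usable])
  zH <- stats::qnorm(cum["S2", usable])
  if (length(unique(round(zF, 12))) < 2) stop("degenerate ROC")
  fit <- stats::lm.fit(cbind(1, zF), zH)
  s <- unname(fit$coefficients[2L])
  if (!is.finite(s) || s <= 0) stop("degenerate ROC")
  zHc <- stats::qnorm(rates["H"])
  zFc <- stats::qnorm(rates["F"])
  da <- sqrt(2 / (1 + s^2)) * (zHc - s * zFc)
  c_a <- -sqrt(2 / (1 + s^2)) * (zHc + s * zFc) / 2
  structure(list(d_prime = unname(zHc - zFc),
                 criterion_c = unname(-(zHc + zFc) / 2),
                 hit_rate = unname(rates["H"]), fa_rate = unname(rates["F"]),
                 s = s, da = unname(da), c_a = unname(c_a),
                 model = "unequal",
                 zroc = data.frame(zF = unname(zF), zH = unname(zH)),
                 padding_applied = isTRUE(table$padded)),
            class = "type1_fit")
}

#' @export
print.type1_fit <- function(x, ...) {
  cat("Type-1 SDT fit (", x$model, " variance)\n", sep = "")
  cat(sprintf("  d' = %.4f  c = %.4f  (H = %.3f, F = %.3f)\n",
              x$d_prime, x$criterion_c, x$hit_rate, x$fa_rate))
  if (x$model == "unequal") {
    cat(sprintf("  s = %.4f  da = %.4f  c_a = %.4f\n", x$s, x$da, x$c_a))
  }
  invisible(x)
}

# Internal: collapsed hit / false-alarm rates with the padding contract
# enforced (rates must be strictly inside (0,1)).
choice_rates <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  n <- table$counts
  tot1 <- sum(n["S1", , ])
  tot2 <- sum(n["S2", , ])
  if (tot1 <= 0 || tot2 <= 0) stop("a stimulus class has no trials")
  H <- sum(n["S2", "S2", ]) / tot2
  F_ <- sum(n["S1", "S2", ]) / tot1
  if (H <= 0 || H >= 1 || F_ <= 0 || F_ >= 1) {
    stop("hit/false-alarm rate at 0 or 1 after padding; ",
         "pad the table first (padding contract broken)")
  }
  c(H = H, F = F_)
}

# Internal: type-1 sensitivity/criterion pair appropriate to the model.
type1_sens <- function(type1) {
  if (type1$model == "unequal") c(sens = type1$da, crit = type1$c_a)
  else c(sens = type1$d_prime, crit = type1$criterion_c)
}
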