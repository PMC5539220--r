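# Type-2 SDT: maximum-likelihood meta-d' / meta-da and M-ratio.
#
# Model: confidence ratings are generated by a second ("meta") SDT model
# with the same structure as the type-1 model but its own sensitivity
# meta_d. Evidence distributions are N(-sep/2, 1) for S1 and
# N(+sep/2, 1/s) for S2 with sep = meta_d * sqrt((1 + 1/s^2)/2), so that
# meta_d is on the da scale (equal to d' when s = 1). The type-1 decision
# criterion is carried into the meta model at the same relative position
# c' = c/d' (c_a/da for the unequal model), and the 2(K-1) confidence
# criteria are free parameters, monotone on each response side. Only the
# response-conditional rating probabilities enter the likelihood; type-1
# choice behavior is taken from the data, not re-fit.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

# Internal: cell probabilities along the evidence axis for given meta
# parameters. cvec is the full ascending vector of 2K-1 criteria
# (K-1 lower confidence criteria, the type-1 criterion, K-1 upper).
t2_cells <- function(sep, cvec, s) {
  K <- (length(cvec) + 1L) / 2L
  mu <- c(-sep / 2, sep / 2)
  sdv <- c(1, 1 / s)
  out <- vector("list", 2L)
  for (i in 1:2) {
    P <- stats::pnorm((cvec - mu[i]) / sdv[i])
    out[[i]] <- list(p = diff(c(0, P, 1)), r1 = P[K])
  }
  out
}

# Internal workhorse: negative log-likelihood of the response-conditional
# confidence counts and its analytic gradient.
# theta = (meta_d, u[1..K-1], v[1..K-1]); upper criteria are
# tc + cumsum(softplus(u)), lower are tc - rev(cumsum(softplus(v))),
# tc = meta_d * c_rel * b the carried type-1 criterion on the evidence
# axis (b converts from the da-scale criterion).
metad_eval <- function(theta, ev, K, s, c_rel, grad = TRUE) {
  tiny <- 1e-300
  a <- sqrt((1 + 1 / s^2) / 2)
  b <- sqrt((1 + s^2) / 2) / s
  m <- theta[1L]
  u <- theta[2:K]
  v <- theta[(K + 1):(2 * K - 1)]
  # parameters are box-bounded well below overflow, so log1p(exp(.)) is safe
  du <- log1p(exp(u))
  dv <- log1p(exp(v))
  tc <- m * c_rel * b
  cvec <- c(tc - rev(cumsum(dv)), tc, tc + cumsum(du))
  mu <- c(-m * a / 2, m * a / 2)
  sdv <- c(1, 1 / s)
  nll <- 0
  d_list <- vector("list", 2L)
  for (i in 1:2) {
    z <- (cvec - mu[i]) / sdv[i]
    P <- stats::pnorm(z)
    p <- diff(c(0, P, 1))
    r1 <- P[K]
    n <- ev[i, ]
    N1 <- sum(n[1:K])
    N2 <- sum(n[(K + 1):(2 * K)])
    nll <- nll - sum(n * log(pmax(p, tiny))) +
      N1 * log(max(r1, tiny)) + N2 * log(max(1 - r1, tiny))
    if (grad) {
      phi <- stats::dnorm(z) / sdv[i]
      w <- n / pmax(p, tiny)
      d_i <- phi * (w[1:(2 * K - 1)] - w[2:(2 * K)])
      d_i[K] <- d_i[K] - phi[K] * (N1 / max(r1, tiny) - N2 / max(1 - r1, tiny))
      d_list[[i]] <- d_i
    }
  }
  if (!grad) return(list(nll = nll))
  g <- d_list[[1L]] + d_list[[2L]]
  dmu <- c(-sum(d_list[[1L]]), -sum(d_list[[2L]]))
  dll_dm <- sum(g) * c_rel * b - dmu[1L] * a / 2 + dmu[2L] * a / 2
  gu <- g[(K + 1):(2 * K - 1)]
  gl <- g[(K - 1):1]
  dll_du <- stats::plogis(u) * rev(cumsum(rev(gu)))
  dll_dv <- -stats::plogis(v) * rev(cumsum(rev(gl)))
  list(nll = nll, grad = -c(dll_dm, dll_du, dll_dv))
}

#' Predicted response-conditional confidence probabilities
#'
#' Evaluates the type-2 model: the probability of each confidence level
#' given the stimulus class and the response, for a meta-level observer
#' with sensitivity `meta_d` (da scale), type-1 criterion `meta_c` (on
#' the evidence axis) and the given confidence criteria.
#'
#' @param meta_d meta-level sensitivity (z-units, da scale; may be
#'   negative).
#' @param meta_c type-1 criterion carried into the meta model, on the
#'   evidence axis.
#' @param t2_criteria_s1,t2_criteria_s2 ascending vectors of K-1
#'   confidence criteria for "S1" responses (below `meta_c`) and "S2"
#'   responses (above `meta_c`).
#' @param s evidence-SD ratio (S1 to S2); 1 for the equal-variance model.
#' @return a 2 x 2 x K array `P[stimulus, response, confidence]`; each
#'   `[stimulus, response, ]` slice sums to 1.
#' @examples
#' p <- type2_predicted_probs(1.5, 0, seq(-2, -0.5, length.out = 5),
#'                            seq(0.5, 2, length.out = 5))
#' apply(p, c(1, 2), sum)  # all 1
#' @export
type2_predicted_probs <- function(meta_d, meta_c, t2_criteria_s1,
                                  t2_criteria_s2, s = 1) {
  stopifnot(length(t2_criteria_s1) == length(t2_criteria_s2), s > 0,
            is.finite(meta_d), is.finite(meta_c))
  K <- length(t2_criteria_s1) + 1L
  cvec <- c(t2_criteria_s1, meta_c, t2_criteria_s2)
  if (any(diff(cvec) <= 0)) stop("criteria not monotone")
  sep <- meta_d * sqrt((1 + 1 / s^2) / 2)
  cells <- t2_cells(sep, cvec, s)
  out <- array(NA_real_, dim = c(2L, 2L, K),
               dimnames = list(stimulus = c("S1", "S2"),
                               response = c("S1", "S2"),
                               confidence = as.character(seq_len(K))))
  for (i in 1:2) {
    p <- cells[[i]]$p
    r1 <- cells[[i]]$r1
    out[i, "S1", ] <- p[K:1] / r1
    out[i, "S2", ] <- p[(K + 1):(2 * K)] / (1 - r1)
  }
  out
}

#' Maximum-likelihood meta-d' / meta-da fit
#'
#' Fits the type-2 sensitivity by maximising the multinomial likelihood of
#' the response-conditional confidence counts, with the type-1 criterion
#' held at the same relative position as in the type-1 fit
#' (c' = c/d', or c_a/da for the unequal-variance model) and the
#' evidence-SD ratio `s` fixed from the type-1 fit when
#' `variance_model = "unequal"`. Confidence criteria are parameterised as
#' the carried criterion plus cumulative softplus increments, so
#' monotonicity holds throughout an unconstrained search; the optimiser
#' (`nlminb` with analytic gradients) is run from three deterministic
#' starts and the best converged solution is kept. `meta_d` is searched in
#' [-5, 5] and reported as fitted, including negative values.
#'
#' @param table a padded `rating_table`.
#' @param type1 the `type1_fit` obtained from the same table
#'   ([fit_type1_equal()] for `"equal"`, [fit_type1_unequal()] for
#'   `"unequal"`).
#' @param variance_model `"equal"` (meta-d') or `"unequal"` (meta-da).
#' @param n_starts number of optimiser starts (>= 1; default 3).
#' @return object of class `type2_fit`: `meta_d`, `variance_model`, `s`,
#'   `meta_c` (carried criterion, da scale), `t1_criterion_meta`
#'   (evidence axis), `t2_criteria_s1resp`, `t2_criteria_s2resp`,
#'   `log_likelihood`, `converged`, `n_trials`, `message`.
#' @export
fit_meta_d <- function(table, type1, variance_model = c("equal", "unequal"),
                       n_starts = 3L) {
  variance_model <- match.arg(variance_model)
  stopifnot(inherits(table, "rating_table"), inherits(type1, "type1_fit"))
  if (variance_model == "unequal" && type1$model != "unequal") {
    stop("unequal-variance meta fit needs a type1 fit with model = 'unequal'")
  }
  K <- table$K
  raw <- if (!is.null(table$unpadded_counts)) table$unpadded_counts else table$counts
  conf_marg <- apply(raw, 3L, sum)
  if (sum(conf_marg > 0) < 2L) stop("type-2 data degenerate")

  s <- if (variance_model == "unequal") type1$s else 1
  sc <- type1_sens(type1)
  sens <- sc[["sens"]]
  c_rel <- if (abs(sens) > 1e-3) sc[["crit"]] / sens else 0
  c_rel <- max(min(c_rel, 5), -5)
  ev <- evidence_counts(table)

  starts <- metad_starts(sens, K, n_starts)
  lower <- c(-5, rep(-15, 2 * K - 2))
  upper <- c(5, rep(10, 2 * K - 2))
  best <- NULL
  objs <- numeric(0)
  cache <- new.env(parent = emptyenv())
  cached_eval <- function(th) {
    if (is.null(cache$th) || !identical(th, cache$th)) {
      cache$th <- th
      cache$res <- metad_eval(th, ev, K, s, c_rel)
    }
    cache$res
  }
  for (st in starts) {
    fit <- stats::nlminb(
      start = st,
      objective = function(th) cached_eval(th)$nll,
      gradient = function(th) cached_eval(th)$grad,
      lower = lower, upper = upper,
      control = list(rel.tol = 1e-10, iter.max = 500, eval.max = 1000))
    fit$converged <- fit$convergence == 0 && is.finite(fit$objective)
    objs <- c(objs, fit$objective)
    if (is.null(best) ||
        (fit$converged && !best$converged) ||
        (fit$converged == best$converged && fit$objective < best$objective - 1e-12)) {
      best <- fit
    }
  }
  theta <- best$par
  m <- theta[1L]
  b <- sqrt((1 + s^2) / 2) / s
  tc <- m * c_rel * b
  du <- softplus(theta[2:K])
  dv <- softplus(theta[(K + 1):(2 * K - 1)])
  structure(list(meta_d = m, variance_model = variance_model, s = s,
                 meta_c = m * c_rel, meta_c_rel = c_rel,
                 t1_criterion_meta = tc,
                 t2_criteria_s1resp = tc - rev(cumsum(dv)),
                 t2_criteria_s2resp = tc + cumsum(du),
                 log_likelihood = -best$objective,
                 converged = best$converged,
                 n_trials = table$n_trials,
                 n_starts = length(starts), start_objectives = objs,
                 message = best$message),
            class = "type2_fit")
}

# Internal: deterministic multi-start values for the meta fit. Start 1
# uses the type-1 sensitivity and evenly spaced criteria; later starts
# shrink/stretch the sensitivity and perturb the criterion spacing with a
# fixed pattern (no RNG involved).
metad_starts <- function(sens, K, n_starts) {
  n_starts <- max(1L, as.integer(n_starts))
  m0 <- max(min(sens, 4.5), -4.5)
  if (abs(m0) < 0.1) m0 <- 0.1
  base_inc <- softplus_inv(0.4)
  jit <- c(-0.6, 0.5, -0.3, 0.4, -0.2, 0.3, -0.1, 0.2)
  scales <- c(1, 0.5, 1.5, 0.25, 2)
  starts <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    sc <- scales[((k - 1L) %% length(scales)) + 1L]
    inc <- rep(base_inc, K - 1L)
    if (k > 1L) {
      inc <- inc + jit[seq_len(K - 1L) %% length(jit) + 1L] * (k - 1L) / n_starts
    }
    starts[[k]] <- c(max(min(m0 * sc, 4.5), -4.5), inc, inc)
  }
  starts
}

#' @export
print.type2_fit <- function(x, ...) {
  cat("Type-2 SDT fit (", x$variance_model, " variance)\n", sep = "")
  cat(sprintf("  meta_d = %.4f  (s = %.3f, carried c' = %.4f)\n",
              x$meta_d, x$s, x$meta_c_rel))
  cat(sprintf("  logL = %.3f  converged: %s  trials: %s\n",
              x$log_likelihood, x$converged, x$n_trials))
  invisible(x)
}

#' Metacognitive efficiency (M-ratio)
#'
#' The ratio of type-2 to type-1 sensitivity: meta-d'/d' for the
#' equal-variance model, meta-da/da for the unequal-variance model.
#' Negative values (negative meta-d' with positive d') are preserved.
#'
#' @param type1 a `type1_fit`.
#' @param type2 a `type2_fit` fitted with the matching variance model.
#' @return object of class `meta_measure`: `m_ratio`, `variant`
#'   (`"equal"` or `"unequal"`), `type1_sensitivity`,
#'   `type2_sensitivity`.
#' @export
m_ratio <- function(type1, type2) {
  stopifnot(inherits(type1, "type1_fit"), inherits(type2, "type2_fit"))
  if ((type2$variance_model == "unequal") != (type1$model == "unequal")) {
    stop("variance models of type-1 and type-2 fits do not match")
  }
  sens <- type1_sens(type1)[["sens"]]
  if (sens == 0) stop("undefined efficiency: type-1 sensitivity is zero")
  structure(list(m_ratio = type2$meta_d / sens,
                 variant = type2$variance_model,
                 type1_sensitivity = sens,
                 type2_sensitivity = type2$meta_d),
            class = "meta_measure")
}

#' @export
print.meta_measure <- function(x, ...) {
  cat(sprintf("M-ratio (%s variance): %.4f  [type2 %.4f / type1 %.4f]\n",
              x$variant, x$m_ratio, x$type2_sensitivity,
              x$type1_sensitivity))
  invisible(x)
}
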