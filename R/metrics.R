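#' Mean squared error against known true survival curves
#'
#' For simulated data where the true conditional survival functions are
#' known: the mean over individuals of the mean over evaluation times of the
#' squared difference between estimated and true survival.
#'
#' @param est,truth Numeric n x K survival matrices on the same time points.
#' @return Nonnegative scalar.
#' @export
mse_true_survival <- function(est, truth) {
  if (!is.matrix(est)) est <- as.matrix(est)
  if (!is.matrix(truth)) truth <- as.matrix(truth)
  if (!identical(dim(est), dim(truth))) {
    abort_validation("`est` and `truth` must have identical dimensions")
  }
  mean((est - truth)^2)
}

#' Time-dependent concordance (Antolini)
#'
#' Probability of correctly ranking two comparable individuals: over ordered
#' pairs (i, j) where i experiences the event first (T_i < T_j and D_i = 1,
#' or T_i = T_j with D_i = 1, D_j = 0), a pair scores 1 when
#' S-hat(T_i | x_i) < S-hat(T_i | x_j), 0.5 on a prediction tie, else 0; the
#' statistic is the mean score over comparable pairs.
#'
#' @param durations Observed times.
#' @param events Binary event indicators.
#' @param surv_at_times Numeric n x n matrix: entry (i, k) is the predicted
#'   survival of individual i evaluated at individual k's observed time, as
#'   produced by [eval_survival()] with `t = durations`.
#' @return Scalar in \[0, 1\].
#' @export
concordance_td <- function(durations, events, surv_at_times) {
  check_surv_vectors(durations, events)
  n <- length(durations)
  if (!is.matrix(surv_at_times) || nrow(surv_at_times) != n ||
    ncol(surv_at_times) != n) {
    abort_config("`surv_at_times` must be an n x n matrix")
  }
  num <- 0
  den <- 0
  for (i in which(events == 1)) {
    comparable <- durations > durations[i] |
      (durations == durations[i] & events == 0)
    if (!any(comparable)) next
    si <- surv_at_times[i, i]
    sj <- surv_at_times[comparable, i]
    num <- num + sum(si < sj) + 0.5 * sum(si == sj)
    den <- den + sum(comparable)
  }
  if (den == 0) abort_validation("no comparable pairs; concordance undefined")
  num / den
}

#' Brier score at a fixed time with IPCW
#'
#' Inverse-probability-of-censoring weighted squared error of survival
#' predictions at time `t`:
#' mean over i of
#' 1\{T_i <= t, D_i = 1\} S-hat(t|x_i)^2 / G(T_i-)
#' + 1\{T_i > t\} (1 - S-hat(t|x_i))^2 / G(t),
#' where G is the censoring-survival estimate and G(T-) its left limit.
#' Individuals censored at or before `t` contribute 0. Terms whose weight
#' denominator is 0 are dropped with a warning.
#'
#' @param t Single evaluation time.
#' @param durations,events Observed times and event indicators.
#' @param surv_at_t Length-n vector of predicted survival at `t`.
#' @param censor_G A `surv_step` estimate of the censoring survival, e.g.
#'   from [censoring_kaplan_meier()].
#' @return Nonnegative scalar.
#' @export
brier_score <- function(t, durations, events, surv_at_t, censor_G) {
  check_surv_vectors(durations, events)
  stopifnot(length(t) == 1, inherits(censor_G, "surv_step"))
  n <- length(durations)
  if (length(surv_at_t) != n) abort_validation("`surv_at_t` has wrong length")
  g_at_obs <- eval_step(censor_G, durations, left = TRUE)
  g_at_t <- eval_step(censor_G, t)
  had_event <- durations <= t & events == 1
  still_at_risk <- durations > t
  w1 <- ifelse(had_event, 1 / g_at_obs, 0)
  w2 <- ifelse(still_at_risk, 1 / g_at_t, 0)
  bad <- (had_event & g_at_obs == 0) | (still_at_risk & g_at_t == 0)
  if (any(bad)) {
    warning(sprintf("%d contribution(s) dropped: zero censoring weight", sum(bad)))
    w1[bad] <- 0
    w2[bad] <- 0
  }
  sum(w1 * surv_at_t^2 + w2 * (1 - surv_at_t)^2) / n
}

#' Integrated Brier score over an evaluation grid
#'
#' Numerical integral (trapezoidal rule) of [brier_score()] over the grid,
#' divided by the grid's time span. The conventional grid is 100 equidistant
#' points between the minimum and maximum observed times.
#'
#' @param eval_times Strictly increasing positive evaluation times (>= 2).
#' @param durations,events Observed times and event indicators.
#' @param surv_fn Either an n x length(eval_times) matrix of predicted
#'   survival, or a function mapping a time vector to such a matrix.
#' @param censor_G A `surv_step` censoring-survival estimate.
#' @return Nonnegative scalar.
#' @export
integrated_brier_score <- function(eval_times, durations, events, surv_fn,
                                   censor_G) {
  if (length(eval_times) < 2 || any(diff(eval_times) <= 0)) {
    abort_config("`eval_times` must be >= 2 strictly increasing times")
  }
  surv_mat <- if (is.function(surv_fn)) surv_fn(eval_times) else surv_fn
  if (ncol(surv_mat) != length(eval_times)) {
    abort_validation("survival matrix columns must match `eval_times`")
  }
  bs <- vapply(
    seq_along(eval_times),
    function(k) brier_score(eval_times[k], durations, events, surv_mat[, k], censor_G),
    numeric(1)
  )
  span <- diff(range(eval_times))
  sum(diff(eval_times) * (bs[-1] + bs[-length(bs)]) / 2) / span
}

#' Equidistant evaluation grid between observed extremes
#'
#' @param durations Observed times.
#' @param n_points Number of points (default 100).
#' @return Numeric vector of evaluation times.
#' @export
make_eval_grid <- function(durations, n_points = 100) {
  seq(min(durations), max(durations), length.out = n_points)
}
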