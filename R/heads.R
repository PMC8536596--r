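# The three output heads share one contract: a network emits an unbounded
# logit matrix phi (n x m, one column per grid interval); each head maps phi
# to its parameters, defines a mean negative log-likelihood (the training
# loss) computed directly from the logits through log-sigmoid / log-sum-exp
# identities, and reconstructs survival curves. Probabilities are never
# materialized inside a logarithm.

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

log_sigmoid <- function(x) -softplus(-x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# rowwise log(sum(exp(x))) for a matrix
row_logsumexp <- function(x) {
  mx <- apply(x, 1, max)
  mx + log(rowSums(exp(x - mx)))
}

check_phi <- function(phi) {
  if (!is.matrix(phi) || !all(is.finite(phi))) {
    abort_validation("`phi` must be a finite numeric matrix")
  }
  invisible(phi)
}

check_labels <- function(phi, labels) {
  if (!inherits(labels, "discrete_labels")) {
    abort_config("`labels` must come from discretize_labels()")
  }
  if (labels$m != ncol(phi)) {
    abort_config(
      "label grid size (%d) does not match logit columns (%d)",
      labels$m, ncol(phi)
    )
  }
  if (nrow(phi) != length(labels$idx)) {
    abort_config("row count of `phi` does not match the labels")
  }
  invisible(labels)
}

#' Discrete hazards from network logits
#'
#' Applies the logistic (sigmoid) link elementwise, so each entry is the
#' conditional probability h(tau_j | x) of the event at tau_j given survival
#' past tau_{j-1}.
#'
#' @param phi Numeric n x m logit matrix.
#' @return An n x m matrix of hazards in (0, 1).
#' @export
hazard_from_logits <- function(phi) {
  check_phi(phi)
  sigmoid(phi)
}

#' Survival curves from discrete hazards
#'
#' S(tau_j | x) = prod_{k <= j} (1 - h_k), computed in log space, with the
#' leading column S(tau_0) = 1 prepended.
#'
#' @param hazard Numeric n x m matrix with entries in \[0, 1\].
#' @param grid Optional [time_grid] attached to the result.
#' @return A `surv_curves` object: list with `grid` and the n x (m+1)
#'   survival matrix `surv`.
#' @export
surv_from_hazard <- function(hazard, grid = NULL) {
  if (any(hazard < 0 | hazard > 1)) abort_validation("hazards must lie in [0, 1]")
  log_s <- t(apply(log1p(-pmin(hazard, 1)), 1, cumsum))
  if (ncol(hazard) == 1) log_s <- matrix(log_s, ncol = 1)
  new_surv_curves(cbind(1, exp(log_s)), grid)
}

#' Logistic-Hazard loss (discrete hazard negative log-likelihood)
#'
#' Mean over individuals of the Bernoulli negative log-likelihood of the
#' discrete hazards up to the individual's discrete index: with
#' y_ij = 1\{j = idx_i, d_i = 1\},
#' loss_i = -sum_{j <= idx_i} \[y_ij log h_j + (1 - y_ij) log(1 - h_j)\].
#' Computed from the logits via log-sigmoid forms. Individuals with idx = 0
#' contribute 0.
#'
#' @param phi Numeric n x m logit matrix.
#' @param labels Labels from [discretize_labels()] on the same grid.
#' @return Nonnegative scalar loss.
#' @export
logistic_hazard_loss <- function(phi, labels) {
  check_phi(phi)
  check_labels(phi, labels)
  m <- ncol(phi)
  jj <- matrix(seq_len(m), nrow(phi), m, byrow = TRUE)
  at_risk <- jj <= labels$idx # j <= idx_i
  y <- (jj == labels$idx) * labels$event
  # -[y log h + (1-y) log(1-h)] = y softplus(-phi) + (1-y) softplus(phi)
  terms <- (y * softplus(-phi) + (1 - y) * softplus(phi)) * at_risk
  mean(rowSums(terms))
}

logistic_hazard_grad <- function(phi, labels) {
  m <- ncol(phi)
  jj <- matrix(seq_len(m), nrow(phi), m, byrow = TRUE)
  at_risk <- jj <= labels$idx
  y <- (jj == labels$idx) * labels$event
  (sigmoid(phi) - y) * at_risk / nrow(phi)
}

#' PMF and tail mass from network logits
#'
#' The softmax parameterization with a fixed extra logit of 0: the event-time
#' mass is f(tau_j | x) = exp(phi_j) / (1 + sum_k exp(phi_k)) and the tail
#' is S(tau_m | x) = 1 / (1 + sum_k exp(phi_k)), the probability of surviving
#' past the last cut. Rows of (pmf, tail) sum to 1. Evaluated through a
#' log-sum-exp over the augmented logits.
#'
#' @param phi Numeric n x m logit matrix.
#' @return List with `pmf` (n x m) and `tail` (length n).
#' @export
pmf_from_logits <- function(phi) {
  check_phi(phi)
  lse <- row_logsumexp(cbind(phi, 0))
  list(pmf = exp(phi - lse), tail = exp(-lse))
}

#' Survival curves from a PMF and tail mass
#'
#' S(tau_j | x) = sum_{k > j} f(tau_k | x) + tail, computed as reverse
#' cumulative sums, with S(tau_0) = 1.
#'
#' @param pmf Numeric n x m matrix of event-time masses.
#' @param tail Length-n vector of tail masses S(tau_m | x).
#' @param grid Optional [time_grid] attached to the result.
#' @return A `surv_curves` object.
#' @export
surv_from_pmf <- function(pmf, tail, grid = NULL) {
  if (!is.matrix(pmf)) abort_validation("`pmf` must be a matrix")
  m <- ncol(pmf)
  # S(tau_j) = tail + sum_{k>j} f_k; reverse cumulative sum over columns
  rev_cum <- t(apply(pmf[, rev(seq_len(m)), drop = FALSE], 1, cumsum))
  if (m == 1) rev_cum <- matrix(rev_cum, ncol = 1)
  s <- cbind(rev_cum[, rev(seq_len(m)), drop = FALSE][, -1, drop = FALSE], 0) + tail
  new_surv_curves(cbind(1, pmin(pmax(s, 0), 1)), grid)
}

#' PMF loss (softmax negative log-likelihood with right censoring)
#'
#' With sigma the softmax of the augmented logits (phi, 0):
#' loss_i = -\[d_i log sigma_idx + (1 - d_i) log sum_{k > idx} sigma_k\],
#' averaged over individuals. Censored individuals contribute the log of the
#' mass beyond their index, including the tail; a censoring with idx = 0
#' contributes 0 (log of the full mass 1). The tail sums are evaluated in log
#' space.
#'
#' @inheritParams logistic_hazard_loss
#' @return Nonnegative scalar loss.
#' @export
pmf_loss <- function(phi, labels) {
  check_phi(phi)
  check_labels(phi, labels)
  if (any(labels$event == 1 & labels$idx == 0)) {
    abort_validation("an event cannot have discrete index 0")
  }
  aug <- cbind(phi, 0)
  lse <- row_logsumexp(aug)
  n <- nrow(phi)
  contrib <- numeric(n)
  for (i in seq_len(n)) {
    k <- labels$idx[i]
    if (labels$event[i] == 1) {
      contrib[i] <- aug[i, k] - lse[i]
    } else if (k == 0) {
      contrib[i] <- 0
    } else {
      tail_lse <- row_logsumexp(aug[i, (k + 1):(ncol(aug)), drop = FALSE])
      contrib[i] <- tail_lse - lse[i]
    }
  }
  -mean(contrib)
}

pmf_grad <- function(phi, labels) {
  m <- ncol(phi)
  n <- nrow(phi)
  aug <- cbind(phi, 0)
  lse <- row_logsumexp(aug)
  sig <- exp(aug - lse) # n x (m+1) softmax
  grad <- matrix(0, n, m)
  jj <- matrix(seq_len(m), n, m, byrow = TRUE)
  ev <- labels$event == 1
  if (any(ev)) {
    onehot <- (jj[ev, , drop = FALSE] == labels$idx[ev])
    grad[ev, ] <- sig[ev, seq_len(m), drop = FALSE] - onehot
  }
  if (any(!ev)) {
    k <- labels$idx[!ev]
    sig_c <- sig[!ev, , drop = FALSE]
    # P_i = sum_{l > k_i} sigma_l
    past <- jj[!ev, , drop = FALSE] > k # n_c x m, tail cols among 1..m
    p_tail <- rowSums(sig_c[, seq_len(m), drop = FALSE] * past) + sig_c[, m + 1]
    grad[!ev, ] <- sig_c[, seq_len(m), drop = FALSE] * (1 - past / p_tail)
  }
  grad / n
}

#' Softplus link for piecewise-constant hazard increments
#'
#' Maps logits to the nonnegative cumulative-hazard increments
#' eta_j = hazard_j * (tau_j - tau_{j-1}) via the overflow-safe softplus
#' log(1 + exp(phi)) = max(phi, 0) + log1p(exp(-|phi|)).
#'
#' @param phi Numeric n x m logit matrix.
#' @return An n x m matrix of positive increments.
#' @export
softplus_rates <- function(phi) {
  check_phi(phi)
  softplus(phi)
}

#' PC-Hazard loss (piecewise-constant hazard negative log-likelihood)
#'
#' With eta_j = softplus(phi_j) the cumulative-hazard increment of interval j,
#' kappa the containing interval of the observed time and rho its elapsed
#' fraction:
#' loss_i = -\[d_i log eta_kappa - eta_kappa rho - sum_{j < kappa} eta_j\],
#' averaged over individuals. The constant d_i log(delta tau_kappa) of the
#' exact likelihood is dropped, so values are comparable only within one grid
#' and may be negative. Individuals with kappa = 0 contribute 0.
#'
#' @inheritParams logistic_hazard_loss
#' @return Scalar loss (may be negative).
#' @export
pc_hazard_loss <- function(phi, labels) {
  check_phi(phi)
  check_labels(phi, labels)
  if (any(labels$event == 1 & labels$kappa == 0)) {
    abort_validation("an event cannot have interval index 0")
  }
  m <- ncol(phi)
  n <- nrow(phi)
  eta <- softplus(phi)
  # log(eta) = log(softplus(phi)); for very negative phi, softplus ~ exp(phi)
  log_eta <- ifelse(phi < -30, phi, log(eta))
  jj <- matrix(seq_len(m), n, m, byrow = TRUE)
  prior <- jj < labels$kappa
  kap <- pmax(labels$kappa, 1L)
  pick <- cbind(seq_len(n), kap)
  active <- labels$kappa >= 1
  ll <- labels$event * log_eta[pick] - eta[pick] * labels$frac -
    rowSums(eta * prior)
  -mean(ll * active)
}

pc_hazard_grad <- function(phi, labels) {
  m <- ncol(phi)
  n <- nrow(phi)
  eta <- softplus(phi)
  sig <- sigmoid(phi) # d eta / d phi
  jj <- matrix(seq_len(m), n, m, byrow = TRUE)
  prior <- jj < labels$kappa
  kap <- pmax(labels$kappa, 1L)
  pick <- cbind(seq_len(n), kap)
  active <- labels$kappa >= 1
  grad <- prior * sig
  at_kappa <- (labels$frac - labels$event / pmax(eta[pick], 1e-300)) * sig[pick]
  grad[pick] <- grad[pick] + at_kappa
  grad * active / n
}

#' PC-Hazard survival at arbitrary times
#'
#' S(t | x) = exp(-eta_kappa(t) rho(t)) prod_{j < kappa(t)} exp(-eta_j):
#' the exponential of minus the piecewise-linear cumulative hazard. Times
#' above tau_m are clipped to tau_m (constant extension).
#'
#' @param eta Numeric n x m matrix of positive increments, e.g. from
#'   [softplus_rates()].
#' @param grid A [time_grid] with m intervals.
#' @param t Positive evaluation times.
#' @return An n x length(t) matrix of survival probabilities.
#' @export
surv_pc_hazard <- function(eta, grid, t) {
  stopifnot(inherits(grid, "time_grid"))
  if (!is.matrix(eta)) eta <- matrix(eta, nrow = 1)
  if (ncol(eta) != grid$m) abort_config("`eta` columns must match the grid")
  if (any(!is.finite(t) | t <= 0)) abort_validation("times must be positive and finite")
  ai <- assign_interval(pmin(t, max(grid$cuts)), grid)
  cum <- cbind(0, t(apply(eta, 1, cumsum)))
  if (grid$m == 1) cum <- cbind(0, matrix(eta, ncol = 1))
  h_total <- cum[, ai$kappa, drop = FALSE] +
    eta[, ai$kappa, drop = FALSE] * rep(ai$rho, each = nrow(eta))
  exp(-h_total)
}

new_surv_curves <- function(surv, grid = NULL) {
  structure(list(grid = grid, surv = surv), class = "surv_curves")
}

#' @export
print.surv_curves <- function(x, ...) {
  cat(sprintf(
    "<surv_curves> %d individuals over %d grid points\n",
    nrow(x$surv), ncol(x$surv)
  ))
  invisible(x)
}

#' @method as_tibble surv_curves
#' @export
as_tibble.surv_curves <- function(x, ...) {
  times <- if (!is.null(x$grid)) x$grid$cuts else seq_len(ncol(x$surv)) - 1
  tibble::tibble(
    id = rep(seq_len(nrow(x$surv)), times = ncol(x$surv)),
    time = rep(times, each = nrow(x$surv)),
    survival = as.vector(x$surv)
  )
}
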