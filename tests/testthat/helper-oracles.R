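# Independent oracles used across test files. These deliberately use the
# slowest, most literal formulation of each quantity so they stay
# independent of the implementation paths they check.

# Product-limit estimator by an explicit loop over risk sets, with events
# processed before censorings at tied times.
km_brute <- function(durations, events) {
  times <- sort(unique(durations[events == 1]))
  values <- numeric(length(times))
  s <- 1
  for (k in seq_along(times)) {
    t <- times[k]
    at_risk <- sum(durations >= t)
    d <- sum(durations == t & events == 1)
    s <- s * (1 - d / at_risk)
    values[k] <- s
  }
  list(times = times, values = values)
}

# Evaluate km_brute output as a right-continuous step function.
km_brute_eval <- function(km, t) {
  vapply(t, function(tt) {
    below <- km$times <= tt
    if (!any(below)) 1 else km$values[max(which(below))]
  }, numeric(1))
}

# Discrete-time negative log-likelihood in its density/survival form,
# computed by chaining hazard -> survival -> mass, one individual at a time.
nll_pmf_form <- function(hazard, labels) {
  n <- nrow(hazard)
  total <- 0
  for (i in seq_len(n)) {
    k <- labels$idx[i]
    s <- cumprod(1 - hazard[i, ])
    if (labels$event[i] == 1) {
      f_k <- hazard[i, k] * if (k > 1) s[k - 1] else 1
      total <- total - log(f_k)
    } else if (k >= 1) {
      total <- total - log(s[k])
    }
  }
  total / n
}

# Literal double-loop time-dependent concordance.
concordance_brute <- function(durations, events, surv_at_times) {
  num <- 0
  den <- 0
  n <- length(durations)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (durations[i] < durations[j] && events[i] == 1) ||
        (durations[i] == durations[j] && events[i] == 1 && events[j] == 0)
      if (!comparable) next
      den <- den + 1
      si <- surv_at_times[i, i]
      sj <- surv_at_times[j, i]
      num <- num + if (si < sj) 1 else if (si == sj) 0.5 else 0
    }
  }
  num / den
}

# Random dataset generator for property tests.
random_surv <- function(n, max_t = 10) {
  list(
    durations = round(stats::runif(n, 0.1, max_t), 1),
    events = stats::rbinom(n, 1, 0.7)
  )
}

# Random labels on a given grid.
random_labels <- function(n, grid) {
  t <- stats::runif(n, 1e-3, max(grid$cuts))
  d <- stats::rbinom(n, 1, 0.6)
  discretize_labels(t, d, grid)
}

# Total loss of a network under a head, for finite-difference checks.
net_loss <- function(net, x, labels, loss_fn) {
  loss_fn(hazardnet:::mlp_forward(net, x)$phi, labels)
}
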