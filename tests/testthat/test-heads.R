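make_labels <- function(idx, event, m, kappa = NULL, frac = NULL) {
  structure(
    list(
      idx = as.integer(idx), event = as.numeric(event),
      kappa = as.integer(if (is.null(kappa)) pmax(idx, 1) else kappa),
      frac = if (is.null(frac)) rep(1, length(idx)) else frac,
      m = as.integer(m)
    ),
    class = "discrete_labels"
  )
}

test_that("sigmoid link maps logits to hazards", {
  expect_equal(hazard_from_logits(matrix(0, 1, 3)), matrix(0.5, 1, 3))
  expect_lt(hazard_from_logits(matrix(-50, 1, 1))[1], 1e-20)
  expect_equal(hazard_from_logits(matrix(log(3), 1, 1))[1], 0.75)
})

test_that("survival from hazards is the cumulative product", {
  s <- surv_from_hazard(matrix(c(0.5, 0.5), 1, 2))$surv
  expect_equal(s, matrix(c(1, 0.5, 0.25), 1, 3))
  expect_equal(surv_from_hazard(matrix(0, 2, 4))$surv, matrix(1, 2, 5))
  expect_equal(
    surv_from_hazard(matrix(c(1, 0.3), 1, 2))$surv,
    matrix(c(1, 0, 0), 1, 3)
  )
})

test_that("logistic-hazard loss reproduces hand-computed values", {
  expect_equal(
    logistic_hazard_loss(matrix(0, 1, 3), make_labels(1, 1, 3)),
    -log(0.5),
    tolerance = 1e-9
  )
  expect_equal(
    logistic_hazard_loss(matrix(0, 1, 2), make_labels(2, 0, 2)),
    -2 * log(0.5),
    tolerance = 1e-9
  )
  expect_equal(
    logistic_hazard_loss(matrix(0, 1, 2), make_labels(0, 0, 2)), 0
  )
})

test_that("hazard-form loss equals the density/survival-form loss", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(1:20, 1)
    m <- sample(1:10, 1)
    phi <- matrix(stats::rnorm(n * m, 0, 2), n, m)
    idx <- sample(0:m, n, replace = TRUE)
    event <- ifelse(idx == 0, 0, stats::rbinom(n, 1, 0.6))
    labels <- make_labels(idx, event, m)
    expect_equal(
      logistic_hazard_loss(phi, labels),
      nll_pmf_form(hazard_from_logits(phi), labels),
      tolerance = 1e-10
    )
  }
})

test_that("pmf head normalizes and matches direct softmax evaluation", {
  p <- pmf_from_logits(matrix(0, 1, 2))
  expect_equal(p$pmf, matrix(1 / 3, 1, 2))
  expect_equal(p$tail, 1 / 3)
  p1 <- pmf_from_logits(matrix(0, 1, 1))
  expect_equal(c(p1$pmf, p1$tail), c(0.5, 0.5))
  p2 <- pmf_from_logits(matrix(c(log(2), 0), 1, 2))
  expect_equal(p2$pmf, matrix(c(0.5, 0.25), 1, 2))
  expect_equal(p2$tail, 0.25)
})

test_that("pmf rows plus tail sum to one under extreme logits", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(1:10, 1)
    m <- sample(1:12, 1)
    phi <- matrix(stats::runif(n * m, -30, 30), n, m)
    p <- pmf_from_logits(phi)
    expect_equal(rowSums(p$pmf) + p$tail, rep(1, n), tolerance = 1e-12)
  }
})

test_that("survival from pmf is the reverse cumulative sum plus tail", {
  s <- surv_from_pmf(matrix(c(1 / 3, 1 / 3), 1, 2), 1 / 3)$surv
  expect_equal(s, matrix(c(1, 2 / 3, 1 / 3), 1, 3))
  expect_equal(
    surv_from_pmf(matrix(0, 1, 3), 1)$surv, matrix(1, 1, 4)
  )
  expect_equal(
    surv_from_pmf(matrix(c(1, 0), 1, 2), 0)$surv, matrix(c(1, 0, 0), 1, 3)
  )
})

test_that("pmf loss reproduces hand-computed values", {
  expect_equal(
    pmf_loss(matrix(0, 1, 1), make_labels(1, 1, 1)), -log(0.5),
    tolerance = 1e-9
  )
  expect_equal(
    pmf_loss(matrix(0, 1, 2), make_labels(1, 0, 2)), -log(2 / 3),
    tolerance = 1e-9
  )
  expect_equal(pmf_loss(matrix(0, 1, 2), make_labels(0, 0, 2)), 0)
  expect_error(
    pmf_loss(matrix(0, 1, 2), make_labels(0, 1, 2)),
    class = "hazardnet_validation_error"
  )
})

test_that("softplus link matches its closed form and asymptote", {
  expect_equal(softplus_rates(matrix(0, 1, 1))[1], log(2), tolerance = 1e-12)
  expect_equal(softplus_rates(matrix(50, 1, 1))[1], 50, tolerance = 1e-12)
  expect_equal(
    softplus_rates(matrix(log(exp(1) - 1), 1, 1))[1], 1,
    tolerance = 1e-12
  )
})

test_that("pc-hazard loss reproduces hand-computed values", {
  # eta = 1 <=> phi = log(e - 1)
  phi1 <- matrix(log(exp(1) - 1), 1, 1)
  lab1 <- make_labels(1, 1, 1, kappa = 1, frac = 0.5)
  expect_equal(pc_hazard_loss(phi1, lab1), 0.5, tolerance = 1e-9)

  phi2 <- matrix(log(exp(1) - 1), 1, 2)
  lab2 <- make_labels(2, 0, 2, kappa = 2, frac = 1)
  expect_equal(pc_hazard_loss(phi2, lab2), 2.0, tolerance = 1e-9)

  lab0 <- make_labels(0, 0, 2, kappa = 0, frac = 1)
  expect_equal(pc_hazard_loss(matrix(0, 1, 2), lab0), 0)
})

test_that("pc-hazard survival is the piecewise-linear cumulative hazard", {
  g <- time_grid(c(0, 1, 2))
  eta <- matrix(log(2), 1, 2)
  expect_equal(surv_pc_hazard(eta, g, 1)[1], 0.5, tolerance = 1e-12)
  expect_equal(
    surv_pc_hazard(eta, g, 1.5)[1], 0.5 * exp(-0.5 * log(2)),
    tolerance = 1e-12
  )
  expect_equal(surv_pc_hazard(matrix(0, 1, 2), g, c(0.5, 1, 2)),
    matrix(1, 1, 3),
    tolerance = 1e-15
  )
  # at the cuts: exactly the cumulative product of exp(-eta_j)
  set.seed(9)
  eta2 <- matrix(stats::rexp(8), 2, 4)
  g4 <- time_grid(0:4)
  expect_equal(
    surv_pc_hazard(eta2, g4, 1:4),
    t(apply(exp(-eta2), 1, cumprod)),
    tolerance = 1e-12
  )
  # continuity at interior cuts
  for (tc in c(1, 2, 3)) {
    left <- surv_pc_hazard(eta2, g4, tc - 1e-10)
    right <- surv_pc_hazard(eta2, g4, tc + 1e-10)
    expect_equal(left, right, tolerance = 1e-9)
  }
})

test_that("all heads produce monotone survival curves starting at 1", {
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(1:8, 1)
    m <- sample(1:10, 1)
    phi <- matrix(stats::rnorm(n * m, 0, 3), n, m)
    s1 <- surv_from_hazard(hazard_from_logits(phi))$surv
    p <- pmf_from_logits(phi)
    s2 <- surv_from_pmf(p$pmf, p$tail)$surv
    g <- time_grid(0:m)
    s3 <- cbind(1, surv_pc_hazard(softplus_rates(phi), g, seq_len(m)))
    for (s in list(s1, s2, s3)) {
      expect_equal(s[, 1], rep(1, n))
      expect_true(all(s >= 0 & s <= 1 + 1e-12))
      expect_true(all(apply(s, 1, function(r) all(diff(r) <= 1e-12))))
    }
  }
})

test_that("bias-only maximum likelihood matches closed forms", {
  set.seed(21)
  n <- 2000
  # follow-up ends at t = 10: later times are administratively censored
  # there, so every interval keeps censored individuals at risk and all
  # maximum-likelihood hazards are interior
  t <- stats::runif(n, 0.05, 13)
  d <- stats::rbinom(n, 1, 0.7)
  d[t > 10] <- 0
  t[t > 10] <- 10
  grid <- make_equidistant_grid(10, 10)
  lab <- discretize_labels(t, d, grid)
  df <- data.frame(duration = t, event = d, x = stats::rnorm(n))

  # Logistic-Hazard: h_j = events at tau_j / at risk at tau_j,
  # so the fitted curve equals the KM curve of the discretized data
  fit_lh <- fit_surv_net(df, grid,
    head = "logistic_hazard", bias_only = TRUE,
    batch_norm = FALSE, epochs = 300, patience = 300,
    batch_size = n, lr = 0.1, val_data = df, seed = 1
  )
  h_hat <- hazard_from_logits(
    hazardnet:::mlp_forward(fit_lh$net, matrix(0, 1, 1))$phi
  )
  events_j <- vapply(1:10, function(j) sum(lab$idx == j & lab$event == 1), 1)
  atrisk_j <- vapply(1:10, function(j) sum(lab$idx >= j), 1)
  expect_equal(as.vector(h_hat), events_j / atrisk_j, tolerance = 1e-3)

  t_disc <- grid$cuts[lab$idx + 1]
  keep <- lab$idx >= 1 | lab$event == 1
  km_disc <- kaplan_meier(pmax(t_disc[keep], 1e-9), lab$event[keep])
  curve <- predict(fit_lh, df[1, , drop = FALSE])$surv[1, -1]
  expect_equal(curve, eval_step(km_disc, grid$cuts[-1]),
    tolerance = 1e-3, ignore_attr = TRUE
  )

  # PC-Hazard: eta_j = events in interval j / fractional exposure in j
  fit_pc <- fit_surv_net(df, grid,
    head = "pc_hazard", bias_only = TRUE,
    batch_norm = FALSE, epochs = 400, patience = 400,
    batch_size = n, lr = 0.1, val_data = df, seed = 1
  )
  eta_hat <- softplus_rates(
    hazardnet:::mlp_forward(fit_pc$net, matrix(0, 1, 1))$phi
  )
  ev_j <- vapply(1:10, function(j) {
    sum(lab$kappa == j & lab$event == 1)
  }, 1)
  expo_j <- vapply(1:10, function(j) {
    sum(lab$kappa > j) + sum(lab$frac[lab$kappa == j])
  }, 1)
  expect_equal(as.vector(eta_hat), ev_j / expo_j, tolerance = 1e-3)
})
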