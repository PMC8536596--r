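test_that("true-survival MSE matches direct arithmetic", {
  truth <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(mse_true_survival(truth, truth), 0)
  expect_equal(mse_true_survival(matrix(c(1, 0), 1, 2), truth), 0.25)
  est <- matrix(0.4, 3, 5)
  expect_equal(mse_true_survival(est, est + 0.1), 0.01, tolerance = 1e-12)
  expect_error(
    mse_true_survival(matrix(0, 1, 2), matrix(0, 2, 2)),
    class = "hazardnet_validation_error"
  )
})

test_that("concordance credits perfect rankings, ties, and errors", {
  t <- c(1, 2, 3)
  d <- c(1, 1, 1)
  # lower survival for earlier events at every evaluation time
  s_perfect <- matrix(c(
    0.1, 0.1, 0.1,
    0.5, 0.5, 0.5,
    0.9, 0.9, 0.9
  ), 3, 3, byrow = TRUE)
  expect_equal(concordance_td(t, d, s_perfect), 1)
  expect_equal(concordance_td(t, d, matrix(0.5, 3, 3)), 0.5)
  expect_equal(concordance_td(t, d, 1 - s_perfect), 0)
  expect_error(
    concordance_td(1, 1, matrix(0.5, 1, 1)),
    class = "hazardnet_validation_error"
  )
})

test_that("concordance equals the brute-force double loop", {
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(3:30, 1)
    d <- random_surv(n)
    if (sum(d$events) == 0) next
    s <- matrix(stats::runif(n * n), n, n)
    got <- tryCatch(
      concordance_td(d$durations, d$events, s),
      hazardnet_validation_error = function(e) NA
    )
    if (is.na(got)) next
    expect_identical(got, concordance_brute(d$durations, d$events, s))
  }
})

test_that("concordance is invariant to monotone transforms per time point", {
  set.seed(43)
  n <- 20
  d <- random_surv(n)
  s <- matrix(stats::runif(n * n), n, n)
  s2 <- apply(s, 2, function(col) stats::plogis(3 * col - 1)) # columnwise monotone
  expect_equal(
    concordance_td(d$durations, d$events, s),
    concordance_td(d$durations, d$events, s2)
  )
})

test_that("Brier score matches hand computations and the uncensored identity", {
  t <- c(1, 3)
  d <- c(1, 1)
  g <- censoring_kaplan_meier(t, d) # no censoring: G = 1
  expect_equal(brier_score(2, t, d, c(0.2, 0.9), g), (0.04 + 0.01) / 2)
  # oracle step predictions: zero error
  expect_equal(brier_score(2, t, d, c(0, 1), g), 0)
  # constant 0.5 prediction scores 0.25 whatever happens
  expect_equal(brier_score(2, t, d, c(0.5, 0.5), g), 0.25)

  set.seed(45)
  n <- 40
  tt <- stats::runif(n, 0.1, 10)
  dd <- rep(1, n)
  s_hat <- stats::runif(n)
  gg <- censoring_kaplan_meier(tt, dd)
  for (at in c(2, 5, 8)) {
    expect_equal(
      brier_score(at, tt, dd, s_hat, gg),
      mean((as.numeric(tt > at) - s_hat)^2),
      tolerance = 1e-12
    )
  }
})

test_that("IBS integrates exactly for constant and linear integrands", {
  t <- c(1, 3)
  d <- c(1, 1)
  g <- censoring_kaplan_meier(t, d)
  grid <- seq(0.5, 2.5, length.out = 100)
  # constant 0.5 predictions: integrand 0.25 everywhere
  expect_equal(
    integrated_brier_score(grid, t, d, matrix(0.5, 2, 100), g), 0.25
  )
  # oracle predictions: integrand 0
  oracle <- function(ts) {
    rbind(as.numeric(ts < 1), as.numeric(ts < 3))
  }
  expect_equal(integrated_brier_score(grid, t, d, oracle, g), 0)
})

test_that("trapezoid IBS is invariant to refining a piecewise-linear integrand", {
  # single uncensored individual, prediction linear in t
  t <- 10
  d <- 1
  g <- censoring_kaplan_meier(t, d)
  # S chosen so the integrand (1 - S(t))^2 = t/20 is linear in t
  s_sqrt <- function(ts) matrix(1 - sqrt(ts / 20), 1)
  coarse <- c(2, 8)
  fine <- c(2, 3.5, 5, 6.5, 8)
  expect_equal(
    integrated_brier_score(coarse, t, d, s_sqrt, g),
    integrated_brier_score(fine, t, d, s_sqrt, g),
    tolerance = 1e-12
  )
})

test_that("zero censoring weights are dropped with a warning", {
  # external censoring estimate that hits 0 before the events
  g0 <- hazardnet:::new_surv_step(1, 0)
  expect_warning(
    b <- brier_score(2.5, c(2, 3), c(1, 1), c(0.5, 0.5), g0),
    "dropped"
  )
  expect_identical(b, 0)
})
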