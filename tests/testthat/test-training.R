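test_that("analytic head gradients match finite differences", {
  set.seed(61)
  n <- 6
  m <- 5
  grid <- time_grid(0:m)
  labels <- random_labels(n, grid)
  heads <- list(
    logistic_hazard = list(
      loss = logistic_hazard_loss, grad = hazardnet:::logistic_hazard_grad
    ),
    pmf = list(loss = pmf_loss, grad = hazardnet:::pmf_grad),
    pc_hazard = list(loss = pc_hazard_loss, grad = hazardnet:::pc_hazard_grad)
  )
  phi <- matrix(stats::rnorm(n * m), n, m)
  eps <- 1e-6
  for (hd in heads) {
    analytic <- hd$grad(phi, labels)
    numeric <- matrix(0, n, m)
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        up <- phi
        up[i, j] <- up[i, j] + eps
        dn <- phi
        dn[i, j] <- dn[i, j] - eps
        numeric[i, j] <- (hd$loss(up, labels) - hd$loss(dn, labels)) / (2 * eps)
      }
    }
    expect_equal(analytic, numeric, tolerance = 1e-5)
  }
})

test_that("backpropagation matches finite differences through the network", {
  set.seed(63)
  n <- 12
  q <- 4
  m <- 3
  grid <- time_grid(0:m)
  labels <- random_labels(n, grid)
  x <- matrix(stats::rnorm(n * q), n, q)
  for (batch_norm in c(FALSE, TRUE)) {
    net <- hazardnet:::mlp_init(q, c(5, 4), m, batch_norm = batch_norm)
    # jitter all parameters off zero so no ReLU sits exactly at its kink,
    # where the loss is not differentiable and finite differences disagree
    net$params <- lapply(net$params, function(p) {
      p + stats::rnorm(length(p), 0, 0.05)
    })
    fw <- hazardnet:::mlp_forward(net, x, training = TRUE)
    dphi <- hazardnet:::logistic_hazard_grad(fw$phi, labels)
    grads <- hazardnet:::mlp_backward(fw$net, fw$cache, dphi)
    total <- function(net) {
      logistic_hazard_loss(
        hazardnet:::mlp_forward(net, x, training = TRUE)$phi, labels
      )
    }
    eps <- 1e-6
    for (nm in names(grads)) {
      p <- net$params[[nm]]
      probe <- sample(length(p), min(4, length(p)))
      for (k in probe) {
        up <- net
        up$params[[nm]][k] <- p[k] + eps
        dn <- net
        dn$params[[nm]][k] <- p[k] - eps
        fd <- (total(up) - total(dn)) / (2 * eps)
        expect_equal(grads[[nm]][k], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("training is deterministic given a seed", {
  sim <- sample_surv_data(sim_config(400), seed = 2)
  grid <- make_equidistant_grid(100, 8)
  args <- list(
    data = sim$data, grid = grid, head = "logistic_hazard",
    hidden = c(8), epochs = 6, seed = 77
  )
  f1 <- do.call(fit_surv_net, args)
  f2 <- do.call(fit_surv_net, args)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$net$params, f2$net$params)
})

test_that("training loss decreases and early stopping returns the best epoch", {
  sim <- sample_surv_data(sim_config(800), seed = 4)
  grid <- suppressMessages(
    make_km_quantile_grid(sim$data$durations, sim$data$events, 10)
  )
  for (hd in c("logistic_hazard", "pmf", "pc_hazard")) {
    fit <- fit_surv_net(sim$data, grid,
      head = hd, hidden = c(16),
      epochs = 15, patience = 3, seed = 5
    )
    h <- fit$history
    expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
    # best epoch is the argmin of the logged validation losses
    expect_equal(fit$best_epoch, which.min(h$val_loss))
    expect_equal(fit$best_val_loss, min(h$val_loss))
  }
})

test_that("dropout and batch norm train without numerical failures", {
  sim <- sample_surv_data(sim_config(400), seed = 6)
  grid <- make_equidistant_grid(100, 5)
  fit <- fit_surv_net(sim$data, grid,
    head = "logistic_hazard",
    hidden = c(16, 16), dropout = 0.5, batch_norm = TRUE,
    epochs = 5, seed = 8
  )
  expect_true(all(is.finite(fit$history$val_loss)))
  p <- predict(fit, sim$data, times = c(10, 50, 90))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("fitted models are restored intact from JSON", {
  sim <- sample_surv_data(sim_config(300), seed = 12)
  grid <- make_equidistant_grid(100, 6)
  fit <- fit_surv_net(sim$data, grid,
    head = "pc_hazard", hidden = c(8),
    epochs = 3, seed = 3
  )
  path <- withr::local_tempfile(fileext = ".json")
  save_surv_net(fit, path)
  back <- load_surv_net(path)
  t_eval <- c(5, 25, 75)
  expect_equal(
    predict(back, sim$data, times = t_eval),
    predict(fit, sim$data, times = t_eval),
    tolerance = 1e-12
  )
})

test_that("grid search selects by likelihood on one grid, IBS across grids", {
  sim <- sample_surv_data(sim_config(600), seed = 14)
  val <- sample_surv_data(sim_config(300), seed = 15)
  g10 <- make_equidistant_grid(100, 10)
  g5 <- make_equidistant_grid(100, 5)
  cfgs <- list(
    list(hidden = c(8L), epochs = 4L),
    list(hidden = c(16L), epochs = 4L)
  )
  one <- grid_search(sim$data, list(g10), cfgs,
    head = "logistic_hazard", val_data = val$data, seed = 2
  )
  expect_equal(unique(one$leaderboard$selection_metric), "val_nll")
  expect_equal(nrow(one$leaderboard), 2)
  expect_equal(
    one$leaderboard$candidate[one$leaderboard$selected],
    which.min(one$leaderboard$val_nll)
  )
  two <- grid_search(sim$data, list(g10, g5), cfgs[1],
    head = "logistic_hazard", val_data = val$data, seed = 2
  )
  expect_equal(unique(two$leaderboard$selection_metric), "val_ibs")
  expect_s3_class(two$best, "surv_net")
})
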