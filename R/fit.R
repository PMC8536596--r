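#' Fit a neural survival model
#'
#' Trains a multilayer perceptron under one of the three likelihood heads:
#'
#' * `"logistic_hazard"` — discrete hazards through a sigmoid link, binary
#'   cross-entropy loss over the at-risk intervals;
#' * `"pmf"` — event-time probability mass through a softmax with a fixed
#'   zero tail logit;
#' * `"pc_hazard"` — continuous-time piecewise-constant hazard through a
#'   softplus link, fitted by the exact censored-data likelihood.
#'
#' Optimization is minibatch Adam with validation-loss early stopping: the
#' returned parameters are those of the epoch with the lowest validation
#' loss. Covariates are standardized with training-set statistics. The grid
#' must be built from training data only; it is stored with the model so
#' that predictions and labels for new data reuse it.
#'
#' @param data A data frame (or [surv_data]) of training observations.
#' @param grid A [time_grid] defining the discretization.
#' @param head Likelihood head, see above.
#' @param duration_col,event_col Column names when `data` is a data frame.
#' @param hidden Integer vector of hidden-layer widths; `integer(0)` gives a
#'   linear model.
#' @param bias_only Ignore covariates and fit a single logit vector (the
#'   closed-form maximum-likelihood test vehicle).
#' @param dropout Dropout probability in \[0, 1).
#' @param batch_norm Apply batch normalization after each hidden activation.
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param batch_size Minibatch size (default 256).
#' @param lr Adam learning rate.
#' @param val_data Explicit validation set (data frame or [surv_data]); when
#'   `NULL`, `val_fraction` of the training rows are held out.
#' @param val_fraction Fraction held out for validation when `val_data` is
#'   `NULL`.
#' @param standardize Standardize covariates with training statistics.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param verbose Print per-epoch losses.
#' @return A `surv_net` object with the fitted network, the grid, the
#'   configuration, and a per-epoch training log (`history`).
#' @examples
#' \donttest{
#' sim <- sample_surv_data(sim_config(500), seed = 1)
#' grid <- make_km_quantile_grid(sim$data$durations, sim$data$events, 10)
#' fit <- fit_surv_net(sim$data, grid,
#'   head = "logistic_hazard",
#'   hidden = c(16), epochs = 10, seed = 1
#' )
#' glance(fit)
#' }
#' @export
fit_surv_net <- function(data, grid,
                         head = c("logistic_hazard", "pmf", "pc_hazard"),
                         duration_col = "duration", event_col = "event",
                         hidden = c(32L, 32L), bias_only = FALSE,
                         dropout = 0, batch_norm = TRUE,
                         epochs = 100L, patience = 10L, batch_size = 256L,
                         lr = 0.01, val_data = NULL, val_fraction = 0.2,
                         standardize = TRUE, seed = 1L, verbose = FALSE) {
  head <- match.arg(head)
  stopifnot(inherits(grid, "time_grid"))
  if (patience < 1 || batch_size < 1) {
    abort_config("`patience` and `batch_size` must be >= 1")
  }
  if (dropout < 0 || dropout >= 1) abort_config("`dropout` must be in [0, 1)")
  ds <- as_surv_data(data, duration_col, event_col)
  set.seed(seed)
  if (is.null(val_data)) {
    n <- length(ds$durations)
    n_val <- floor(val_fraction * n)
    if (n_val < 1) abort_config("validation split is empty")
    val_rows <- sample.int(n, n_val)
    vs <- subset_surv_data(ds, val_rows)
    ds <- subset_surv_data(ds, setdiff(seq_len(n), val_rows))
  } else {
    vs <- as_surv_data(val_data, duration_col, event_col)
  }
  if (length(vs$durations) == 0) abort_config("validation split is empty")

  center <- rep(0, ncol(ds$covariates))
  scale <- rep(1, ncol(ds$covariates))
  if (standardize && ncol(ds$covariates) > 0) {
    center <- colMeans(ds$covariates)
    scale <- apply(ds$covariates, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  x_tr <- scale_cov(ds$covariates, center, scale)
  x_val <- scale_cov(vs$covariates, center, scale)
  lab_tr <- suppressWarnings(discretize_labels(ds$durations, ds$events, grid))
  lab_val <- suppressWarnings(discretize_labels(vs$durations, vs$events, grid))

  head_fns <- head_functions(head)
  net <- mlp_init(ncol(x_tr), hidden, grid$m, batch_norm, bias_only)
  opt <- adam_init(net$params)
  n_tr <- nrow(x_tr)
  best <- list(loss = Inf, params = net$params, bn = net$bn_stats, epoch = 0L)
  history <- vector("list", epochs)

  for (epoch in seq_len(epochs)) {
    perm <- sample.int(n_tr)
    starts <- seq(1, n_tr, by = batch_size)
    for (s in starts) {
      rows <- perm[s:min(s + batch_size - 1L, n_tr)]
      fw <- mlp_forward(net, x_tr[rows, , drop = FALSE],
        training = TRUE, dropout = dropout
      )
      net <- fw$net
      dphi <- head_fns$grad(fw$phi, subset_labels(lab_tr, rows))
      if (!all(is.finite(dphi))) {
        rlang::abort(
          sprintf("non-finite gradient in epoch %d, batch starting at %d", epoch, s),
          class = "hazardnet_numeric_error"
        )
      }
      grads <- mlp_backward(net, fw$cache, dphi)
      upd <- adam_step(net$params, grads, opt, lr)
      net$params <- upd$params
      opt <- upd$state
    }
    train_loss <- head_fns$loss(mlp_forward(net, x_tr)$phi, lab_tr)
    val_loss <- head_fns$loss(mlp_forward(net, x_val)$phi, lab_val)
    if (!is.finite(val_loss) || !is.finite(train_loss)) {
      rlang::abort(sprintf("non-finite loss at epoch %d", epoch),
        class = "hazardnet_numeric_error"
      )
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = train_loss, val_loss = val_loss
    )
    if (verbose) {
      message(sprintf(
        "epoch %3d  train %.5f  val %.5f", epoch, train_loss, val_loss
      ))
    }
    if (val_loss < best$loss) {
      best <- list(
        loss = val_loss, params = net$params, bn = net$bn_stats, epoch = epoch
      )
    } else if (epoch - best$epoch >= patience) {
      break
    }
  }
  net$params <- best$params
  net$bn_stats <- best$bn

  structure(
    list(
      net = net, head = head, grid = grid,
      center = center, scale = scale,
      covariate_names = ds$covariate_names,
      config = list(
        hidden = hidden, bias_only = bias_only, dropout = dropout,
        batch_norm = batch_norm, epochs = epochs, patience = patience,
        batch_size = batch_size, lr = lr, seed = seed,
        standardize = standardize
      ),
      history = dplyr::bind_rows(history),
      best_epoch = best$epoch,
      best_val_loss = best$loss
    ),
    class = "surv_net"
  )
}

as_surv_data <- function(data, duration_col = "duration", event_col = "event") {
  if (inherits(data, "surv_data")) {
    return(data)
  }
  surv_data(data, duration_col, event_col)
}

subset_surv_data <- function(x, rows) {
  structure(
    list(
      covariates = x$covariates[rows, , drop = FALSE],
      durations = x$durations[rows],
      events = x$events[rows],
      covariate_names = x$covariate_names
    ),
    class = "surv_data"
  )
}

subset_labels <- function(lab, rows) {
  structure(
    list(
      idx = lab$idx[rows], event = lab$event[rows],
      kappa = lab$kappa[rows], frac = lab$frac[rows], m = lab$m
    ),
    class = "discrete_labels"
  )
}

scale_cov <- function(x, center, scale) {
  if (ncol(x) == 0) {
    return(x)
  }
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

head_functions <- function(head) {
  switch(head,
    logistic_hazard = list(loss = logistic_hazard_loss, grad = logistic_hazard_grad),
    pmf = list(loss = pmf_loss, grad = pmf_grad),
    pc_hazard = list(loss = pc_hazard_loss, grad = pc_hazard_grad)
  )
}

#' Predict survival from a fitted neural survival model
#'
#' With `times = NULL`, returns the model's survival curves at the grid
#' points as a `surv_curves` object. With explicit `times`, returns the
#' n x length(times) matrix of survival probabilities: the discrete heads
#' are evaluated through the requested scheme (step, constant-density or
#' constant-hazard interpolation), while PC-Hazard — whose hazard is
#' genuinely piecewise constant — is evaluated exactly; its `scheme`
#' argument is ignored.
#'
#' @param object A `surv_net` fit.
#' @param newdata Data frame, [surv_data], or covariate matrix.
#' @param times Optional positive evaluation times.
#' @param scheme Interpolation scheme for the discrete heads.
#' @param ... Unused.
#' @return A `surv_curves` object or a numeric matrix.
#' @export
predict.surv_net <- function(object, newdata, times = NULL,
                             scheme = c("step", "cdi", "chi"), ...) {
  scheme <- match.arg(scheme)
  x <- extract_covariates(object, newdata)
  phi <- mlp_forward(object$net, scale_cov(x, object$center, object$scale))$phi
  if (object$head == "pc_hazard") {
    eta <- softplus_rates(phi)
    if (is.null(times)) {
      cum <- t(apply(cbind(0, eta), 1, cumsum))
      return(new_surv_curves(exp(-cum), object$grid))
    }
    return(surv_pc_hazard(eta, object$grid, times))
  }
  curves <- if (object$head == "logistic_hazard") {
    surv_from_hazard(hazard_from_logits(phi), object$grid)
  } else {
    pm <- pmf_from_logits(phi)
    surv_from_pmf(pm$pmf, pm$tail, object$grid)
  }
  if (is.null(times)) {
    return(curves)
  }
  eval_survival(curves, scheme, times)
}

extract_covariates <- function(object, newdata) {
  if (inherits(newdata, "surv_data")) {
    return(newdata$covariates[, object$covariate_names, drop = FALSE])
  }
  if (is.matrix(newdata)) {
    return(newdata)
  }
  if (is.data.frame(newdata)) {
    missing <- setdiff(object$covariate_names, names(newdata))
    if (length(missing) > 0) {
      abort_config("newdata lacks covariate(s): %s", paste(missing, collapse = ", "))
    }
    return(as.matrix(newdata[object$covariate_names]))
  }
  abort_config("`newdata` must be a data frame, surv_data, or matrix")
}

#' @export
print.surv_net <- function(x, ...) {
  cat(sprintf(
    "<surv_net> head = %s, m = %d intervals, hidden = [%s]%s\n",
    x$head, x$grid$m, paste(x$config$hidden, collapse = ", "),
    if (x$config$bias_only) " (bias-only)" else ""
  ))
  cat(sprintf(
    "  best epoch %d of %d trained, validation loss %.5f\n",
    x$best_epoch, nrow(x$history), x$best_val_loss
  ))
  invisible(x)
}

#' @describeIn fit_surv_net Per-epoch training log as a tibble.
#' @param x A `surv_net` fit.
#' @param ... Unused.
#' @method tidy surv_net
#' @export
tidy.surv_net <- function(x, ...) {
  x$history
}

#' @describeIn fit_surv_net One-row model summary.
#' @method glance surv_net
#' @export
glance.surv_net <- function(x, ...) {
  tibble::tibble(
    head = x$head,
    m = x$grid$m,
    n_parameters = sum(vapply(x$net$params, length, integer(1))),
    epochs_trained = nrow(x$history),
    best_epoch = x$best_epoch,
    val_loss = x$best_val_loss
  )
}
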