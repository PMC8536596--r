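#' Specification of a simulation experiment sweep
#'
#' Describes a factorial sweep over likelihood heads, discretization schemes,
#' grid sizes, training-set sizes, and replications, on simulated data with
#' known true survival curves. Every run gets a deterministic identifier, so
#' a sweep can be resumed: completed runs found in the output file are
#' skipped.
#'
#' @param heads Character vector of likelihood heads.
#' @param schemes Discretization schemes, subset of `c("equidistant", "km")`.
#' @param grid_sizes Integer vector of interval counts m.
#' @param train_sizes Integer vector of training-set sizes.
#' @param replications Number of replications per combination.
#' @param n_val,n_test Validation and (uncensored) test sizes.
#' @param censor_rate Per-step censoring hazard for train/validation draws.
#' @param hidden,dropout,batch_norm,lr,epochs,patience,batch_size Network
#'   and optimizer settings shared by all runs.
#' @param seed_base Base seed; all run-level seeds derive from it.
#' @return An `experiment_spec` object.
#' @export
experiment_spec <- function(heads = "logistic_hazard",
                            schemes = "km",
                            grid_sizes = 25,
                            train_sizes = 3000,
                            replications = 1,
                            n_val = 1000, n_test = 2000,
                            censor_rate = DEFAULT_CENSOR_RATE,
                            hidden = c(64L, 64L), dropout = 0,
                            batch_norm = FALSE, lr = 0.005,
                            epochs = 200L, patience = 25L, batch_size = 256L,
                            seed_base = 1L) {
  stopifnot(all(schemes %in% c("equidistant", "km")))
  structure(
    list(
      heads = heads, schemes = schemes, grid_sizes = as.integer(grid_sizes),
      train_sizes = as.integer(train_sizes),
      replications = as.integer(replications),
      n_val = as.integer(n_val), n_test = as.integer(n_test),
      censor_rate = censor_rate,
      hidden = hidden, dropout = dropout, batch_norm = batch_norm, lr = lr,
      epochs = as.integer(epochs), patience = as.integer(patience),
      batch_size = as.integer(batch_size),
      seed_base = as.integer(seed_base)
    ),
    class = "experiment_spec"
  )
}

#' Run a simulation experiment sweep
#'
#' For each replication, draws fresh training/validation data (censored) and
#' an uncensored test set with its true survival matrix; then fits every
#' (head, scheme, m, train size) combination and scores it on the test set:
#' true-survival MSE of the step predictions and of the constant-hazard
#' interpolated predictions on the fine grid, time-dependent concordance,
#' and the IPCW integrated Brier score. Results are appended to `out_csv`
#' (when given) one row at a time; rerunning skips run identifiers already
#' present. A run that fails is recorded with an error message and the sweep
#' continues.
#'
#' @param spec An [experiment_spec].
#' @param out_csv Optional path for incremental CSV output (enables resume).
#' @param verbose Print per-run progress.
#' @return A tibble with one row per run.
#' @export
run_experiment <- function(spec, out_csv = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  done <- character(0)
  prev <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    prev <- tibble::as_tibble(utils::read.csv(out_csv))
    done <- prev$run_id
  }
  combos <- expand.grid(
    head = spec$heads, scheme = spec$schemes, m = spec$grid_sizes,
    n_train = spec$train_sizes, rep = seq_len(spec$replications),
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (r in sort(unique(combos$rep))) {
    rep_seed <- spec$seed_base + 1000L * r
    sub <- combos[combos$rep == r, , drop = FALSE]
    todo <- sub[!run_ids(sub) %in% done, , drop = FALSE]
    if (nrow(todo) == 0) next
    data_cache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(todo))) {
      run <- todo[i, ]
      id <- run_ids(run)
      res <- tryCatch(
        one_run(run, spec, rep_seed, data_cache),
        error = function(e) {
          tibble::tibble(
            mse_step = NA_real_, mse_chi = NA_real_,
            concordance = NA_real_, ibs = NA_real_,
            error = conditionMessage(e)
          )
        }
      )
      row <- dplyr::bind_cols(
        tibble::tibble(
          run_id = id, head = run$head, scheme = run$scheme, m = run$m,
          n_train = run$n_train, rep = run$rep
        ),
        res
      )
      if (!"error" %in% names(row)) row$error <- NA_character_
      rows[[length(rows) + 1]] <- row
      if (!is.null(out_csv)) {
        utils::write.table(row, out_csv,
          sep = ",", row.names = FALSE,
          col.names = !file.exists(out_csv), append = file.exists(out_csv)
        )
      }
      if (verbose) message(sprintf("done: %s", id))
    }
  }
  out <- dplyr::bind_rows(c(list(prev), rows))
  dplyr::arrange(out, .data$rep, .data$head, .data$scheme, .data$m, .data$n_train)
}

run_ids <- function(runs) {
  sprintf(
    "%s_%s_m%d_n%d_rep%d",
    runs$head, runs$scheme, runs$m, runs$n_train, runs$rep
  )
}

one_run <- function(run, spec, rep_seed, cache) {
  key <- sprintf("n%d", run$n_train)
  if (!exists(key, envir = cache)) {
    train <- sample_surv_data(
      sim_config(run$n_train, censor_rate = spec$censor_rate),
      seed = rep_seed, keep_truth = FALSE
    )
    val <- sample_surv_data(
      sim_config(spec$n_val, censor_rate = spec$censor_rate),
      seed = rep_seed + 1L, keep_truth = FALSE
    )
    test <- sample_surv_data(
      sim_config(spec$n_test, censor_rate = 0),
      seed = rep_seed + 2L, keep_truth = TRUE
    )
    assign(key, list(train = train, val = val, test = test), envir = cache)
  }
  dat <- get(key, envir = cache)
  tr <- dat$train$data
  grid <- if (run$scheme == "km") {
    suppressMessages(make_km_quantile_grid(tr$durations, tr$events, run$m))
  } else {
    make_equidistant_grid(max(tr$durations), run$m)
  }
  fit <- fit_surv_net(
    tr, grid,
    head = run$head, hidden = spec$hidden, dropout = spec$dropout,
    batch_norm = spec$batch_norm, lr = spec$lr, epochs = spec$epochs,
    patience = spec$patience, batch_size = spec$batch_size,
    val_data = dat$val$data, seed = rep_seed + 17L
  )
  score_fit(fit, dat$test)
}

score_fit <- function(fit, test) {
  te <- test$data
  fine_times <- test$times
  s_step <- predict(fit, te, times = fine_times, scheme = "step")
  s_chi <- predict(fit, te, times = fine_times, scheme = "chi")
  s_at_obs <- predict(fit, te, times = te$durations, scheme = "chi")
  eval_times <- make_eval_grid(te$durations, 100)
  g_cens <- censoring_kaplan_meier(te$durations, te$events)
  tibble::tibble(
    mse_step = mse_true_survival(s_step, test$truth),
    mse_chi = mse_true_survival(s_chi, test$truth),
    concordance = concordance_td(te$durations, te$events, s_at_obs),
    ibs = integrated_brier_score(
      eval_times, te$durations, te$events,
      predict(fit, te, times = eval_times, scheme = "chi"), g_cens
    )
  )
}
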