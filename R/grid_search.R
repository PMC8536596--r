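#' Hyperparameter search over grids and network configurations
#'
#' Fits every combination of candidate discretization grid and network
#' configuration and selects the best model. When all candidates share a
#' single grid, the selection metric is the validation negative
#' log-likelihood (the training loss at the best epoch). When the candidates
#' span different grids, likelihoods are not comparable — they depend on the
#' granularity of the discretization — so selection switches to the
#' validation integrated Brier score.
#'
#' @inheritParams fit_surv_net
#' @param grids List of candidate [time_grid]s.
#' @param configs List of candidate configuration lists; each may set any of
#'   `hidden`, `dropout`, `batch_norm`, `lr`, `batch_size`, `epochs`,
#'   `patience`, `bias_only`.
#' @param val_data Explicit validation set used for selection (required, so
#'   every candidate is scored on the same data).
#' @param ibs_points Number of evaluation points for the validation IBS.
#' @param seed Base seed; candidate k trains with `seed + k - 1`.
#' @return List with `best` (the winning `surv_net`), and `leaderboard`
#'   (a tibble with one row per candidate, its scores, and the selection
#'   metric used).
#' @export
grid_search <- function(data, grids, configs,
                        head = c("logistic_hazard", "pmf", "pc_hazard"),
                        val_data = NULL,
                        duration_col = "duration", event_col = "event",
                        ibs_points = 100, seed = 1L, ...) {
  head <- match.arg(head)
  if (length(grids) == 0 || length(configs) == 0) {
    abort_config("`grids` and `configs` must be nonempty")
  }
  if (is.null(val_data)) abort_config("`val_data` is required for selection")
  vs <- as_surv_data(val_data, duration_col, event_col)
  single_grid <- length(unique(vapply(
    grids, function(g) paste(signif(g$cuts, 12), collapse = ","), character(1)
  ))) == 1
  metric <- if (single_grid) "val_nll" else "val_ibs"

  eval_times <- make_eval_grid(vs$durations, ibs_points)
  g_cens <- censoring_kaplan_meier(vs$durations, vs$events)

  rows <- list()
  fits <- list()
  k <- 0L
  for (gi in seq_along(grids)) {
    for (ci in seq_along(configs)) {
      k <- k + 1L
      cfg <- configs[[ci]]
      args <- c(
        list(
          data = data, grid = grids[[gi]], head = head,
          duration_col = duration_col, event_col = event_col,
          val_data = val_data, seed = seed + k - 1L
        ),
        cfg, list(...)
      )
      fit <- do.call(fit_surv_net, args)
      surv_val <- predict(fit, vs, times = eval_times, scheme = "chi")
      ibs <- integrated_brier_score(
        eval_times, vs$durations, vs$events, surv_val, g_cens
      )
      fits[[k]] <- fit
      rows[[k]] <- tibble::tibble(
        candidate = k, grid = gi, m = grids[[gi]]$m, config = ci,
        val_nll = fit$best_val_loss, val_ibs = ibs,
        selection_metric = metric
      )
    }
  }
  leaderboard <- dplyr::bind_rows(rows)
  score <- leaderboard[[metric]]
  best_k <- which.min(score)
  leaderboard$selected <- seq_len(nrow(leaderboard)) == best_k
  list(best = fits[[best_k]], leaderboard = leaderboard)
}
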