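#' Time-discretization grids
#'
#' A `time_grid` holds the cut points 0 = tau_0 < tau_1 < ... < tau_m that
#' partition the follow-up period into half-open intervals (tau_{j-1}, tau_j].
#' This half-open convention is used consistently throughout the package: an
#' observed time t belongs to the unique interval kappa(t) with
#' tau_{kappa-1} < t <= tau_kappa.
#'
#' @param cuts Numeric vector starting at 0, strictly increasing.
#' @return A `time_grid` object.
#' @export
time_grid <- function(cuts) {
  cuts <- as.numeric(cuts)
  if (length(cuts) < 2) abort_config("a grid needs at least one interval")
  if (cuts[1] != 0) abort_config("the first cut must be 0")
  if (any(diff(cuts) <= 0)) abort_config("cuts must be strictly increasing")
  structure(list(cuts = cuts, m = length(cuts) - 1L), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> m = %d intervals on (0, %g]\n", x$m, max(x$cuts)))
  invisible(x)
}

#' Equidistant discretization grid
#'
#' Cuts \[0, t_max\] into `m` intervals of equal width.
#'
#' @param t_max Largest time covered by the grid (> 0).
#' @param m Number of intervals (>= 1).
#' @return A [time_grid].
#' @export
make_equidistant_grid <- function(t_max, m) {
  if (!is.numeric(t_max) || length(t_max) != 1 || !is.finite(t_max) || t_max <= 0) {
    abort_config("`t_max` must be a positive number")
  }
  if (m < 1) abort_config("`m` must be >= 1")
  time_grid(seq(0, t_max, length.out = m + 1))
}

#' Kaplan-Meier quantile discretization grid
#'
#' Places the cuts at quantiles of the marginal Kaplan-Meier survival
#' estimate, so every interval carries (approximately) the same drop in the
#' estimated survival: with S-hat the KM estimate and t_max the largest
#' observed time, the targets are zeta_j = 1 - j (1 - S-hat(t_max)) / m and
#' tau_j is the smallest observed time with S-hat(t) <= zeta_j. This yields a
#' denser grid where events are frequent. Duplicate cuts (several quantiles
#' hit by one steep KM drop) are collapsed, so the returned grid may have
#' fewer than `m` intervals; a message reports the collapse. The final cut is
#' forced to t_max.
#'
#' @inheritParams kaplan_meier
#' @param m Requested number of intervals (>= 1).
#' @return A [time_grid] with at most `m` intervals.
#' @export
make_km_quantile_grid <- function(durations, events, m) {
  check_surv_vectors(durations, events)
  if (m < 1) abort_config("`m` must be >= 1")
  if (sum(events) == 0) {
    abort_config("KM-quantile grid requires at least one observed event")
  }
  km <- kaplan_meier(durations, events)
  t_max <- max(durations)
  s_tail <- eval_step(km, t_max)
  zeta <- 1 - seq_len(m) * (1 - s_tail) / m
  # smallest observed time with S-hat(t) <= zeta_j (tolerance for fp noise)
  cuts <- vapply(zeta, function(z) {
    km$times[which(km$values <= z + 1e-12)[1]]
  }, numeric(1))
  cuts[m] <- t_max
  cuts <- unique(c(0, cuts))
  if (length(cuts) < m + 1) {
    message(sprintf(
      "KM-quantile grid collapsed from %d to %d intervals (tied quantile times)",
      m, length(cuts) - 1
    ))
  }
  time_grid(cuts)
}

#' Locate a time within a grid
#'
#' Returns, for each time t, the interval index kappa(t) such that
#' tau_{kappa-1} < t <= tau_kappa, and the within-interval proportion
#' rho(t) = (t - tau_{kappa-1}) / (tau_kappa - tau_{kappa-1}) in (0, 1\].
#' Times above tau_m are clipped to tau_m (kappa = m, rho = 1).
#'
#' @param t Positive times.
#' @param grid A [time_grid].
#' @return A list with integer vector `kappa` and numeric vector `rho`.
#' @export
assign_interval <- function(t, grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (any(!is.finite(t) | t <= 0)) abort_validation("times must be positive and finite")
  cuts <- grid$cuts
  t <- pmin(t, cuts[length(cuts)])
  kappa <- findInterval(t, cuts, left.open = TRUE)
  rho <- (t - cuts[kappa]) / (cuts[kappa + 1] - cuts[kappa])
  list(kappa = as.integer(kappa), rho = rho)
}

#' Discretize right-censored observations onto a grid
#'
#' Produces the labels consumed by the likelihood heads. Two coordinates are
#' recorded per individual:
#'
#' * `idx` — the discrete-time index after the rounding rule used by the
#'   discrete heads: an event in (tau_{j-1}, tau_j\] is moved to the end of
#'   its interval (idx = j), a censoring to the end of the previous interval
#'   (idx = j - 1). A censoring exactly at a cut keeps idx = j. idx = 0 marks
#'   censorings before tau_1; they contribute no likelihood terms.
#' * `kappa`, `frac` — the containing interval and elapsed fraction rho(t) of
#'   the original, unrounded time, used by the continuous-time PC-Hazard
#'   likelihood.
#'
#' Durations above tau_m are clipped to tau_m (event indicator preserved)
#' with a warning.
#'
#' @inheritParams kaplan_meier
#' @param grid A [time_grid].
#' @return A `discrete_labels` object; its tibble form has columns
#'   `idx`, `event`, `kappa`, `frac`.
#' @export
discretize_labels <- function(durations, events, grid) {
  check_surv_vectors(durations, events)
  stopifnot(inherits(grid, "time_grid"))
  t_max <- max(grid$cuts)
  if (any(durations > t_max)) {
    warning(sprintf(
      "%d duration(s) above the grid maximum %g were clipped",
      sum(durations > t_max), t_max
    ))
    durations <- pmin(durations, t_max)
  }
  ai <- assign_interval(durations, grid)
  at_cut <- durations %in% grid$cuts
  idx <- ifelse(events == 1 | at_cut, ai$kappa, ai$kappa - 1L)
  structure(
    list(
      idx = as.integer(idx),
      event = as.numeric(events),
      kappa = as.integer(ai$kappa),
      frac = ai$rho,
      m = grid$m
    ),
    class = "discrete_labels"
  )
}

#' @export
print.discrete_labels <- function(x, ...) {
  cat(sprintf(
    "<discrete_labels> n = %d on a grid of m = %d intervals\n",
    length(x$idx), x$m
  ))
  invisible(x)
}

#' @method as_tibble discrete_labels
#' @export
as_tibble.discrete_labels <- function(x, ...) {
  tibble::tibble(idx = x$idx, event = x$event, kappa = x$kappa, frac = x$frac)
}
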