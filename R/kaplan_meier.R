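#' Kaplan-Meier estimate of the marginal survival function
#'
#' Product-limit estimator of S(t) = P(T* > t) from right-censored data.
#' At tied event and censoring times the events are processed first, so a
#' censored individual counts as at risk for a tied event. Computation is
#' delegated to [survival::survfit()].
#'
#' @param durations Positive observed times.
#' @param events Binary event indicators (1 = event, 0 = censored).
#' @return A `surv_step` object: a right-continuous step function with fields
#'   `times` (sorted unique observed times) and `values` (estimates in
#'   \[0, 1\], nonincreasing). The value before the first stored time is 1.
#' @seealso [censoring_kaplan_meier()], [eval_step()]
#' @examples
#' km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
#' eval_step(km, c(0.5, 1, 2.5))
#' @export
kaplan_meier <- function(durations, events) {
  check_surv_vectors(durations, events)
  fit <- survival::survfit(survival::Surv(durations, events) ~ 1,
    conf.type = "none", se.fit = FALSE
  )
  new_surv_step(fit$time, fit$surv)
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Estimates G(t) = P(C* > t) by the product-limit method applied with
#' flipped indicators (1 - d). The tie convention mirrors [kaplan_meier()]:
#' at a tied time, individuals with an event remain in the risk set for the
#' censoring "event", so censorings are effectively processed after events.
#' Used for inverse-probability-of-censoring weights in [brier_score()].
#'
#' @inheritParams kaplan_meier
#' @return A `surv_step` object estimating the censoring survival G(t).
#' @export
censoring_kaplan_meier <- function(durations, events) {
  check_surv_vectors(durations, events)
  kaplan_meier(durations, 1 - events)
}

check_surv_vectors <- function(durations, events) {
  if (length(durations) == 0) abort_validation("empty survival data")
  if (length(durations) != length(events)) {
    abort_validation("durations and events differ in length")
  }
  if (any(!is.finite(durations) | durations <= 0)) {
    abort_validation(
      "non-positive or non-finite duration in row %d",
      which(!is.finite(durations) | durations <= 0)[1]
    )
  }
  if (!all(events %in% c(0, 1))) {
    abort_validation("event indicators must be 0 or 1")
  }
  invisible(TRUE)
}

new_surv_step <- function(times, values) {
  o <- order(times)
  structure(list(times = times[o], values = values[o]), class = "surv_step")
}

#' Evaluate a step estimate at arbitrary times
#'
#' Right-continuous step-function semantics: the value at `t` is the value at
#' the largest stored time <= `t`, and 1 when `t` lies below all stored times.
#' `left = TRUE` returns the left limit (largest stored time strictly < `t`),
#' the convention used for the censoring weight G(T-) in the Brier score.
#'
#' @param step A `surv_step` object.
#' @param t Numeric vector of evaluation times.
#' @param left Evaluate the left limit instead of the value at `t`.
#' @return Numeric vector of step values, same length as `t`.
#' @export
eval_step <- function(step, t, left = FALSE) {
  stopifnot(inherits(step, "surv_step"))
  idx <- findInterval(t, step$times, left.open = left)
  c(1, step$values)[idx + 1]
}

#' @export
print.surv_step <- function(x, ...) {
  cat(sprintf(
    "<surv_step> %d steps on [%g, %g], final value %.4f\n",
    length(x$times), min(x$times), max(x$times), x$values[length(x$values)]
  ))
  invisible(x)
}

#' @method tidy surv_step
#' @export
tidy.surv_step <- function(x, ...) {
  tibble::tibble(time = x$times, estimate = x$values)
}

#' Write a step estimate as (time, value) pairs
#'
#' @param x A `surv_step` object.
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @export
write_step_estimate <- function(x, path) {
  utils::write.csv(tidy.surv_step(x), path, row.names = FALSE)
  invisible(x)
}
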