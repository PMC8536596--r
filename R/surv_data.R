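#' Construct a right-censored survival dataset
#'
#' Bundles the (x_i, t_i, d_i) triples of classical right-censored survival
#' data: a numeric covariate matrix, a strictly positive observed time per
#' individual (event or censoring time), and a binary event indicator
#' (1 = event observed, 0 = right-censored).
#'
#' @param data A data frame holding one row per individual. All columns other
#'   than `duration_col` and `event_col` are treated as numeric covariates.
#' @param duration_col,event_col Names of the duration and event columns.
#' @return An object of class `surv_data`: a list with elements `covariates`
#'   (n x q numeric matrix), `durations`, `events`, and `covariate_names`.
#' @examples
#' df <- data.frame(duration = c(1, 2.5, 4), event = c(1, 0, 1), x1 = c(0.2, -1, 3))
#' sd <- surv_data(df)
#' sd$durations
#' @export
surv_data <- function(data, duration_col = "duration", event_col = "event") {
  if (!is.data.frame(data)) abort_config("`data` must be a data frame")
  for (col in c(duration_col, event_col)) {
    if (!col %in% names(data)) {
      abort_config("column '%s' not found in `data`", col)
    }
  }
  durations <- as.numeric(data[[duration_col]])
  events <- data[[event_col]]
  bad_t <- which(!is.finite(durations) | durations <= 0)
  if (length(bad_t) > 0) {
    abort_validation("non-positive or non-finite duration in row %d", bad_t[1])
  }
  if (!all(events %in% c(0, 1))) {
    bad_d <- which(!(events %in% c(0, 1)))[1]
    abort_validation("event indicator outside {0,1} in row %d", bad_d)
  }
  cov_cols <- setdiff(names(data), c(duration_col, event_col))
  covariates <- as.matrix(as.data.frame(lapply(data[cov_cols], as.numeric)))
  if (length(cov_cols) == 0) {
    covariates <- matrix(numeric(0), nrow = nrow(data), ncol = 0)
  }
  if (anyNA(covariates) || (length(covariates) && !all(is.finite(covariates)))) {
    abort_validation("covariates contain missing or non-finite values")
  }
  structure(
    list(
      covariates = covariates,
      durations = durations,
      events = as.numeric(events),
      covariate_names = cov_cols
    ),
    class = "surv_data"
  )
}

#' @export
print.surv_data <- function(x, ...) {
  cat(sprintf(
    "<surv_data> n = %d, q = %d covariates, %.1f%% censored\n",
    length(x$durations), ncol(x$covariates),
    100 * mean(x$events == 0)
  ))
  invisible(x)
}

#' @method as_tibble surv_data
#' @export
as_tibble.surv_data <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$covariates))
  tibble::add_column(out,
    duration = x$durations, event = x$events,
    .before = 1
  )
}

#' Read a right-censored survival table from a delimited file
#'
#' Reads a comma-separated file with a header row into a [surv_data] object.
#' Every column other than the duration and event columns must be numeric and
#' is taken as a covariate (column order preserved).
#'
#' @param path Path to a CSV file.
#' @inheritParams surv_data
#' @return A [surv_data] object.
#' @export
read_survival_table <- function(path, duration_col = "duration",
                                event_col = "event") {
  if (!file.exists(path)) abort_config("file '%s' does not exist", path)
  df <- utils::read.csv(path, check.names = FALSE)
  surv_data(df, duration_col = duration_col, event_col = event_col)
}

#' Write a survival dataset to CSV
#'
#' @param x A [surv_data] object.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_survival_table <- function(x, path) {
  stopifnot(inherits(x, "surv_data"))
  utils::write.csv(as_tibble.surv_data(x), path, row.names = FALSE)
  invisible(x)
}
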