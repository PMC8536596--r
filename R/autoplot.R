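#' Plot survival curves
#'
#' Draws the per-individual survival curves of a `surv_curves` object as
#' step functions over the grid.
#'
#' @param object A `surv_curves` object.
#' @param max_curves Cap on the number of individuals drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot surv_curves
#' @export
autoplot.surv_curves <- function(object, max_curves = 20, ...) {
  df <- as_tibble(object)
  keep <- unique(df$id)[seq_len(min(max_curves, length(unique(df$id))))]
  ggplot2::ggplot(
    df[df$id %in% keep, ],
    ggplot2::aes(x = .data$time, y = .data$survival, group = .data$id)
  ) +
    ggplot2::geom_step(alpha = 0.6) +
    ggplot2::labs(x = "time", y = "S(t | x)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier style step estimate
#'
#' @param object A `surv_step` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot surv_step
#' @export
autoplot.surv_step <- function(object, ...) {
  df <- tidy(object)
  df <- rbind(tibble::tibble(time = 0, estimate = 1), df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "estimate") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the training history of a fitted model
#'
#' Training and validation loss per epoch, with the early-stopping epoch
#' marked.
#'
#' @param object A `surv_net` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot surv_net
#' @export
autoplot.surv_net <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
    names_to = "split", values_to = "loss"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "mean negative log-likelihood") +
    ggplot2::theme_minimal()
}
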