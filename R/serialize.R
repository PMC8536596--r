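#' Save or load a fitted model as JSON
#'
#' Serializes a `surv_net` fit — head, grid cuts, configuration, network
#' weights, standardization constants, and the training log — to a single
#' human-readable JSON file, so predictions are reproducible without R
#' binary formats.
#'
#' @param fit A `surv_net` object.
#' @param path Output path.
#' @return `fit`, invisibly.
#' @export
save_surv_net <- function(fit, path) {
  stopifnot(inherits(fit, "surv_net"))
  payload <- list(
    head = fit$head,
    cuts = fit$grid$cuts,
    config = fit$config,
    covariate_names = fit$covariate_names,
    center = fit$center,
    scale = fit$scale,
    arch = fit$net$arch,
    params = lapply(fit$net$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p)) else list(dim = NULL, data = p)
    }),
    bn_stats = fit$net$bn_stats,
    history = fit$history,
    best_epoch = fit$best_epoch,
    best_val_loss = fit$best_val_loss
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(fit)
}

#' @rdname save_surv_net
#' @param path Path to a JSON file written by [save_surv_net()].
#' @return For `load_surv_net()`: the restored `surv_net` object.
#' @export
load_surv_net <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(p$params, function(x) {
    if (length(x$dim) == 2) {
      matrix(as.numeric(x$data), x$dim[1], x$dim[2])
    } else {
      as.numeric(x$data)
    }
  })
  arch <- p$arch
  arch$hidden <- as.integer(arch$hidden)
  bn <- lapply(p$bn_stats, as.numeric)
  structure(
    list(
      net = list(arch = arch, params = params, bn_stats = bn),
      head = p$head,
      grid = time_grid(p$cuts),
      center = as.numeric(p$center),
      scale = as.numeric(p$scale),
      covariate_names = p$covariate_names,
      config = p$config,
      history = tibble::as_tibble(p$history),
      best_epoch = p$best_epoch,
      best_val_loss = p$best_val_loss
    ),
    class = "surv_net"
  )
}
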