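# Single-file, versioned checkpoints storing the network configuration
# alongside the weights (and the history for fitted models).

CHECKPOINT_FORMAT <- "vesselnet-checkpoint"
CHECKPOINT_VERSION <- 1L

#' Save a model checkpoint
#'
#' @param model A `"vessel_net"` or `"vessel_net_fit"`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  fit <- inherits(model, "vessel_net_fit")
  net <- as_vessel_net(model)
  obj <- list(format = CHECKPOINT_FORMAT, version = CHECKPOINT_VERSION,
              fitted = fit, config = net$config, params = net$params,
              bufs = net$bufs,
              history = if (fit) model$history else NULL,
              control = if (fit) model$control else NULL,
              best_epoch = if (fit) model$best_epoch else NULL)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return A `"vessel_net"` or `"vessel_net_fit"`, matching what was saved.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, CHECKPOINT_FORMAT))
    stop(sprintf("'%s' is not a network checkpoint", path))
  if (obj$version > CHECKPOINT_VERSION)
    stop(sprintf("checkpoint version %d is newer than supported (%d)",
                 obj$version, CHECKPOINT_VERSION))
  net <- structure(list(config = obj$config, params = obj$params,
                        bufs = obj$bufs,
                        n_params = length(unlist(obj$params))),
                   class = "vessel_net")
  if (isTRUE(obj$fitted))
    structure(list(model = net, history = obj$history, control = obj$control,
                   best_epoch = obj$best_epoch),
              class = "vessel_net_fit")
  else net
}
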