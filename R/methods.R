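# S3 methods for the model objects.

#' @export
print.vessel_net <- function(x, ...) {
  cat("Dual-attention fusion segmentation network (untrained weights unless fitted)\n")
  cat(sprintf("  %s parameters | input %dx%dx%d\n",
              format(x$n_params, big.mark = ","),
              x$config$input_size[1L], x$config$input_size[2L],
              x$config$input_channels))
  print(x$config)
  invisible(x)
}

#' @export
print.vessel_net_fit <- function(x, ...) {
  h <- x$history
  cat("Fitted dual-attention fusion segmentation network\n")
  cat(sprintf("  epochs: %d | final train loss: %.5f | best epoch: %s\n",
              nrow(h), h$train_loss[nrow(h)], format(x$best_epoch)))
  if (any(!is.na(h$val_accuracy))) {
    i <- which(!is.na(h$val_accuracy))
    i <- i[length(i)]
    cat(sprintf("  last validation: Acc %.4f | Sen %.4f | Spe %.4f\n",
                h$val_accuracy[i], h$val_sensitivity[i], h$val_specificity[i]))
  }
  invisible(x)
}

#' @export
summary.vessel_net_fit <- function(object, ...) {
  print(object)
  cat("\nTap shapes (batch, channel, height, width):\n")
  print(inspect_taps(object))
  cat("\nTraining history (last 5 epochs):\n")
  print(tail(object$history, 5L), row.names = FALSE)
  invisible(object)
}

#' @export
summary.vessel_net <- function(object, ...) {
  print(object)
  cat("\nTap shapes (batch, channel, height, width):\n")
  print(inspect_taps(object))
  invisible(object)
}

#' Predict vessel probabilities or masks
#'
#' Tiled, overlap-averaged inference on one image or a list of image pairs.
#'
#' @param object A `"vessel_net_fit"` (or `"vessel_net"`).
#' @param newdata An `"image_pair"`, an `H x W x 3` array, or a list of
#'   either.
#' @param type `"prob"` for the probability map, `"mask"` for the
#'   thresholded binary mask.
#' @param threshold Threshold for `type = "mask"`.
#' @param stride Tiling stride.
#' @param ... Unused.
#' @return A matrix (single input) or list of matrices.
#' @export
predict.vessel_net_fit <- function(object, newdata, type = c("prob", "mask"),
                                   threshold = 0.5, stride = 32L, ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "image_pair") || is.array(newdata)
  items <- if (single) list(newdata) else newdata
  out <- lapply(items, function(it) {
    p <- predict_image(object, it, stride = stride)$prob
    if (type == "mask") binarize(p, threshold) else p
  })
  if (single) out[[1L]] else out
}

#' @export
predict.vessel_net <- predict.vessel_net_fit

#' @export
coef.vessel_net_fit <- function(object, ...) object$model$params

#' @export
coef.vessel_net <- function(object, ...) object$params

#' Plot training history
#'
#' Training loss and, when present, validation accuracy/sensitivity per
#' epoch.
#'
#' @param x A `"vessel_net_fit"`.
#' @param ... Passed to `plot`.
#' @export
plot.vessel_net_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1L, if (any(!is.na(h$val_accuracy))) 2L else 1L))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
       ylab = "training loss", main = "Cross-entropy loss", ...)
  if (any(!is.na(h$val_accuracy))) {
    keep <- !is.na(h$val_accuracy)
    plot(h$epoch[keep], h$val_accuracy[keep], type = "b", col = "black",
         ylim = c(0, 1), xlab = "epoch", ylab = "validation metric",
         main = "Validation")
    graphics::lines(h$epoch[keep], h$val_sensitivity[keep], type = "b",
                    col = "red3")
    graphics::legend("bottomright", c("accuracy", "sensitivity"),
                     col = c("black", "red3"), lty = 1, bty = "n")
  }
  invisible(x)
}
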