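# Pixel-level evaluation: confusion counts and Acc/Sen/Spe.

#' Pixel confusion counts
#'
#' Tallies TP/TN/FP/FN with vessel as the positive class, over the
#' field-of-view pixels when a FOV mask is supplied and over all pixels
#' otherwise.
#'
#' @param pred_mask,true_mask Binary arrays of identical shape.
#' @param fov Optional binary FOV mask; only pixels with `fov == 1` count.
#' @return An object of class `"confusion_counts"`: list `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion_counts <- function(pred_mask, true_mask, fov = NULL) {
  if (!identical(dim(pred_mask), dim(true_mask)) &&
      length(pred_mask) != length(true_mask))
    stop("prediction and truth have different shapes")
  p <- as.vector(pred_mask); t <- as.vector(true_mask)
  if (!is.null(fov)) {
    keep <- as.vector(fov) == 1
    p <- p[keep]; t <- t[keep]
  }
  if (!all(p %in% c(0, 1)) || !all(t %in% c(0, 1)))
    stop("confusion counts require strictly binary masks")
  structure(list(tp = sum(p == 1 & t == 1), tn = sum(p == 0 & t == 0),
                 fp = sum(p == 1 & t == 0), fn = sum(p == 0 & t == 1)),
            class = "confusion_counts")
}

#' Sum confusion counts
#'
#' Micro-averaging over images: metrics of the summed counts.
#'
#' @param ... `"confusion_counts"` objects (or one list of them).
#' @return A `"confusion_counts"` object.
#' @export
sum_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "confusion_counts")) xs <- xs[[1L]]
  out <- list(tp = 0, tn = 0, fp = 0, fn = 0)
  for (x in xs) for (f in names(out)) out[[f]] <- out[[f]] + x[[f]]
  structure(out, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d TN=%d FP=%d FN=%d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Segmentation metrics from confusion counts
#'
#' `Accuracy = (TP+TN)/(TP+FN+TN+FP)`, `Sensitivity = TP/(TP+FN)` (vessel
#' recall), `Specificity = TN/(TN+FP)` (background recall).  A metric whose
#' denominator is zero is reported as `NA`, never as 0/0.
#'
#' @param counts A `"confusion_counts"` object, or `tp` given as such.
#' @param tp,tn,fp,fn Counts given directly.
#' @return A list with `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' seg_metrics(tp = 8, fn = 2, tn = 85, fp = 5)
#' @export
seg_metrics <- function(counts = NULL, tp = 0, tn = 0, fp = 0, fn = 0) {
  if (inherits(counts, "confusion_counts")) {
    tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  }
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated pixels: all counts are zero")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(accuracy = ratio(tp + tn, total),
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp))
}

#' Evaluate a model over image pairs
#'
#' Tiled inference on each pair followed by per-image and micro-averaged
#' (summed-count) Acc/Sen/Spe.
#'
#' @param model A `"vessel_net"` or `"vessel_net_fit"`.
#' @param pairs List of `"image_pair"` objects.
#' @param stride Tiling stride for inference.
#' @param threshold Binarization threshold.
#' @param use_fov Restrict counting to the FOV when a pair carries one.
#' @param batch_size Tiles per forward batch.
#' @return An object of class `"metric_report"`: list with `aggregate`
#'   (metrics + counts) and `per_image` (data frame).
#' @export
evaluate_pairs <- function(model, pairs, stride = 32L, threshold = 0.5,
                           use_fov = TRUE, batch_size = 64L) {
  if (inherits(pairs, "image_pair")) pairs <- list(pairs)
  rows <- list(); counts <- list()
  for (pr in pairs) {
    prob <- predict_image(model, pr$image, stride = stride,
                          batch_size = batch_size)$prob
    pm <- binarize(prob, threshold)
    fov <- if (use_fov && !is.null(pr$fov)) pr$fov else
      array(1, dim(pr$mask))
    fov <- fov * !is.na(pm)        # pixels no tile covered are not scored
    cc <- confusion_counts(pm, pr$mask, fov)
    mt <- seg_metrics(cc)
    counts[[length(counts) + 1L]] <- cc
    rows[[length(rows) + 1L]] <- data.frame(
      id = pr$source_id, tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
      accuracy = mt$accuracy, sensitivity = mt$sensitivity,
      specificity = mt$specificity, stringsAsFactors = FALSE)
  }
  total <- sum_counts(counts)
  structure(list(aggregate = c(seg_metrics(total),
                               list(counts = total)),
                 per_image = do.call(rbind, rows)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("aggregate over %d image(s): Acc %.4f | Sen %.4f | Spe %.4f\n",
              nrow(x$per_image), a$accuracy, a$sensitivity, a$specificity))
  invisible(x)
}
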