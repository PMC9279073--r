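# Training: per-pixel binary cross-entropy, Adam with per-epoch exponential
# learning-rate decay, seeded shuffling and on-the-fly flip/rotation
# augmentation.  Labels are replicated across the head's output channels;
# the inference vessel probability is the channel mean.

#' Binary cross-entropy loss
#'
#' Mean over all elements of `-[y log(p) + (1-y) log(1-p)]`, with
#' probabilities clamped to `[eps, 1-eps]` to avoid `log(0)`.
#'
#' @param pred Predicted probabilities, any numeric array.
#' @param target Binary labels of the same shape.
#' @param eps Clamp epsilon (default `1e-7`).
#' @return A non-negative scalar.
#' @examples
#' bce_loss(rep(0.5, 10), rep(c(0, 1), 5))  # log(2)
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  if (length(pred) != length(target))
    stop("prediction and target have different shapes")
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Training control parameters
#'
#' Defaults mirror the published schedule: Adam, initial learning rate
#' 0.001 decayed by a factor 0.9 every epoch, batch size 128, 100 epochs.
#'
#' @param epochs Number of epochs.
#' @param batch_size Mini-batch size.
#' @param initial_lr Initial learning rate.
#' @param lr_decay Per-epoch multiplicative decay of the learning rate.
#' @param beta1,beta2,adam_eps Adam moment coefficients and stabilizer.
#' @param seed Seed covering patch sampling, shuffling and augmentation.
#' @param patches_per_image Random patches drawn per training image.
#' @param augment Apply random flips/right-angle rotations per batch.
#' @param val_stride Tiling stride for validation inference.
#' @param val_every Validate every this many epochs.
#' @param verbose Print a line per epoch.
#' @return An object of class `"train_control"`.
#' @export
train_control <- function(epochs = 100L, batch_size = 128L,
                          initial_lr = 0.001, lr_decay = 0.9,
                          beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                          seed = 1L, patches_per_image = 500L,
                          augment = TRUE, val_stride = 32L, val_every = 1L,
                          verbose = FALSE) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr_decay > 0, lr_decay <= 1,
            initial_lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, lr_decay = lr_decay,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 seed = as.integer(seed),
                 patches_per_image = as.integer(patches_per_image),
                 augment = isTRUE(augment),
                 val_stride = as.integer(val_stride),
                 val_every = as.integer(val_every),
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

# stack a list of patch_sets / patches into engine tensors
patches_to_tensors <- function(patch_sets) {
  if (inherits(patch_sets, "patch_set")) patch_sets <- list(patch_sets)
  ps <- unlist(lapply(patch_sets, function(s) s$patches), recursive = FALSE)
  n <- length(ps)
  sz <- dim(ps[[1L]]$mask)
  x <- array(0, c(sz[1L], sz[2L], dim(ps[[1L]]$image)[3L], n))
  y <- array(0, c(sz[1L], sz[2L], n))
  for (i in seq_len(n)) {
    x[, , , i] <- ps[[i]]$image
    y[, , i] <- ps[[i]]$mask
  }
  list(x = x, y = y, n = n)
}

# random flip/rotation per sample, same op for image and mask
augment_batch <- function(xb, yb) {
  n <- dim(xb)[4L]
  ops <- sample(0:5, n, replace = TRUE)
  for (i in seq_len(n)) {
    k <- ops[i]
    if (k == 0L) next
    op <- c("hflip", "vflip", "rot90", "rot180", "rot270")[k]
    for (c in seq_len(dim(xb)[3L]))
      xb[, , c, i] <- apply_geom(xb[, , c, i], op)
    yb[, , i] <- apply_geom(yb[, , i], op)
  }
  list(x = xb, y = yb)
}

adam_zero <- function(params) rapply(params, function(x) x * 0, how = "replace")

adam_step <- function(params, grads, m, v, lr, b1, b2, eps, t) {
  c1 <- 1 / (1 - b1^t); c2 <- 1 / (1 - b2^t)
  walk <- function(p, g, m, v) {
    for (nm in names(g)) {
      if (is.list(g[[nm]])) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      } else {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
        p[[nm]] <- p[[nm]] - lr * (m[[nm]] * c1) / (sqrt(v[[nm]] * c2) + eps)
      }
    }
    list(p = p, m = m, v = v)
  }
  walk(params, grads, m, v)
}

#' Train the segmentation network
#'
#' Seeded mini-batch optimization of the per-pixel cross-entropy with Adam;
#' the learning rate is multiplied by `control$lr_decay` after every epoch.
#' Training patches are drawn at random origins from the training pairs
#' (`control$patches_per_image` each) and augmented on the fly with flips
#' and right-angle rotations.  When validation pairs are supplied, the model
#' with the best validation accuracy is retained.
#'
#' @param model A `"vessel_net"` (see [vessel_net()]).
#' @param train_pairs List of `"image_pair"` objects, or a `"patch_set"`
#'   (list of patch sets) to use as-is.
#' @param val_pairs Optional list of `"image_pair"` objects for per-epoch
#'   validation.
#' @param control A [train_control()].
#' @return An object of class `"vessel_net_fit"`: list with `model` (the
#'   best/final network), `history` (per-epoch data frame: loss, learning
#'   rate, validation Acc/Sen/Spe), `control` and `best_epoch`.
#' @export
train_vessel_net <- function(model, train_pairs, val_pairs = NULL,
                             control = train_control()) {
  stopifnot(inherits(model, "vessel_net"), inherits(control, "train_control"))
  cfg <- model$config
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(control$seed)

  if (inherits(train_pairs, "image_pair")) train_pairs <- list(train_pairs)
  if (inherits(train_pairs, "patch_set") ||
      (is.list(train_pairs) && length(train_pairs) > 0L &&
       inherits(train_pairs[[1L]], "patch_set"))) {
    sets <- train_pairs
  } else {
    if (length(train_pairs) == 0L) stop("empty training set")
    sets <- lapply(seq_along(train_pairs), function(i)
      extract_patches(train_pairs[[i]], size = cfg$input_size[1L],
                      strategy = "random", n = control$patches_per_image,
                      seed = control$seed + i))
  }
  tens <- patches_to_tensors(sets)
  if (tens$n == 0L) stop("empty training set")

  params <- model$params; bufs <- model$bufs
  mstate <- adam_zero(params); vstate <- adam_zero(params)
  tstep <- 0L
  nb <- ceiling(tens$n / control$batch_size)
  cout <- cfg$output_channels
  hist_rows <- list()
  best <- list(acc = -Inf, params = params, bufs = bufs, epoch = NA_integer_)

  for (epoch in seq_len(control$epochs)) {
    lr <- control$initial_lr * control$lr_decay^(epoch - 1L)
    idx <- sample.int(tens$n)
    epoch_loss <- 0
    for (b in seq_len(nb)) {
      take <- idx[((b - 1L) * control$batch_size + 1L):min(b * control$batch_size, tens$n)]
      xb <- tens$x[, , , take, drop = FALSE]
      yb <- tens$y[, , take, drop = FALSE]
      if (control$augment) {
        au <- augment_batch(xb, yb)
        xb <- au$x; yb <- au$y
      }
      fw <- net_forward(params, bufs, cfg, xb, training = TRUE,
                        keep_cache = TRUE)
      bufs <- fw$bufs
      lg <- bce_grad_cpp(fw$out, tdim(fw$out), yb, 1e-7)
      loss <- lg$loss
      if (!is.finite(loss))
        stop(sprintf("non-finite loss (%g) at epoch %d batch %d: try a lower learning rate",
                     loss, epoch, b))
      epoch_loss <- epoch_loss + loss * length(take)
      bw <- net_backward(params, cfg, fw$cache, dpre = lg$dpre)
      tstep <- tstep + 1L
      st <- adam_step(params, bw$grads, mstate, vstate, lr,
                      control$beta1, control$beta2, control$adam_eps, tstep)
      params <- st$p; mstate <- st$m; vstate <- st$v
    }
    epoch_loss <- epoch_loss / tens$n

    val <- c(accuracy = NA_real_, sensitivity = NA_real_,
             specificity = NA_real_)
    if (!is.null(val_pairs) && epoch %% control$val_every == 0L) {
      snap <- model; snap$params <- params; snap$bufs <- bufs
      rep_ <- evaluate_pairs(snap, val_pairs, stride = control$val_stride)
      val <- c(accuracy = rep_$aggregate$accuracy,
               sensitivity = rep_$aggregate$sensitivity,
               specificity = rep_$aggregate$specificity)
      if (!is.na(val["accuracy"]) && val["accuracy"] > best$acc) {
        best <- list(acc = val[["accuracy"]], params = params, bufs = bufs,
                     epoch = epoch)
      }
    }
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, lr = lr, train_loss = epoch_loss,
      val_accuracy = val[["accuracy"]],
      val_sensitivity = val[["sensitivity"]],
      val_specificity = val[["specificity"]])
    if (control$verbose)
      cat(sprintf("epoch %3d | lr %.5f | loss %.5f | val acc %s sen %s\n",
                  epoch, lr, epoch_loss,
                  format(val[["accuracy"]], digits = 4),
                  format(val[["sensitivity"]], digits = 4)))
  }

  final <- model
  if (is.finite(best$acc)) {
    final$params <- best$params; final$bufs <- best$bufs
  } else {
    final$params <- params; final$bufs <- bufs
    best$epoch <- control$epochs
  }
  structure(list(model = final, history = do.call(rbind, hist_rows),
                 control = control, best_epoch = best$epoch),
            class = "vessel_net_fit")
}

#' Tiled inference on a full-size image
#'
#' Grid-tiles the image with the model's patch size, predicts every tile in
#' eval mode, averages the per-channel sigmoid outputs into a vessel
#' probability, and stitches overlapping tiles by per-pixel averaging.
#'
#' @param model A `"vessel_net"` or `"vessel_net_fit"`.
#' @param image `H x W x 3` array in [0,1] (or an `"image_pair"`).
#' @param stride Tiling stride (default 32: 2x overlap smoothing).
#' @param batch_size Tiles per forward batch.
#' @return A list with `prob` (H x W probability matrix) and `coverage`.
#' @export
predict_image <- function(model, image, stride = 32L, batch_size = 64L) {
  net <- as_vessel_net(model)
  if (inherits(image, "image_pair")) image <- image$image
  size <- net$config$input_size[1L]
  H <- dim(image)[1L]; W <- dim(image)[2L]
  if (H < size || W < size)
    stop(sprintf("image %dx%d is smaller than the %dx%d network input",
                 H, W, size, size))
  og <- expand.grid(row = grid_origins(H, size, stride),
                    col = grid_origins(W, size, stride))
  n <- nrow(og)
  tiles <- vector("list", n)
  for (start in seq(1L, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    xb <- array(0, c(size, size, dim(image)[3L], length(take)))
    for (j in seq_along(take)) {
      i <- take[j]
      xb[, , , j] <- image[og$row[i] + 1:size, og$col[i] + 1:size, , drop = FALSE]
    }
    out <- from_float(net_forward(net$params, net$bufs, net$config, xb,
                                  training = FALSE)$out)
    pm <- rowMeans(aperm(out, c(1L, 2L, 4L, 3L)), dims = 3L)
    for (j in seq_along(take)) {
      i <- take[j]
      tiles[[i]] <- list(prob = pm[, , j], row = og$row[i], col = og$col[i])
    }
  }
  stitch_predictions(tiles, c(H, W))
}
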