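# Loss, metrics and the training loop.

test_that("cross-entropy loss matches its closed forms", {
  y <- rep(c(0, 1), 50)
  expect_equal(bce_loss(y, y), 0, tolerance = 1e-6)        # clamp epsilon only
  expect_equal(bce_loss(rep(0.5, 100), y), log(2), tolerance = 1e-12)
  # label/prediction flip symmetry
  set.seed(1)
  p <- runif(64); t <- round(runif(64))
  expect_equal(bce_loss(p, t), bce_loss(1 - p, 1 - t))
  expect_error(bce_loss(p, t[1:10]), "different shapes")
})

test_that("confusion counts agree with a per-pixel counting oracle", {
  all1 <- matrix(1, 10, 10)
  cc <- confusion_counts(all1, all1)
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 100L, tn = 0L, fp = 0L, fn = 0L),
               ignore_attr = TRUE)
  inv <- confusion_counts(1 - all1, all1)
  expect_equal(inv$tp + inv$tn, 0)
  set.seed(2)
  pm <- matrix(round(runif(64)), 8, 8)
  tm <- matrix(round(runif(64)), 8, 8)
  got <- confusion_counts(pm, tm)
  # brute-force loop count
  tp <- tn <- fp <- fn <- 0
  for (i in 1:8) for (j in 1:8) {
    if (pm[i, j] == 1 && tm[i, j] == 1) tp <- tp + 1
    if (pm[i, j] == 0 && tm[i, j] == 0) tn <- tn + 1
    if (pm[i, j] == 1 && tm[i, j] == 0) fp <- fp + 1
    if (pm[i, j] == 0 && tm[i, j] == 1) fn <- fn + 1
  }
  expect_equal(c(got$tp, got$tn, got$fp, got$fn), c(tp, tn, fp, fn))
  # FOV restriction drops border pixels from the tally
  fov <- matrix(0, 8, 8); fov[3:6, 3:6] <- 1
  gf <- confusion_counts(pm, tm, fov)
  expect_equal(gf$tp + gf$tn + gf$fp + gf$fn, 16)
  expect_error(confusion_counts(pm * 0.5, tm), "binary")
})

test_that("accuracy/sensitivity/specificity follow their definitions", {
  m <- seg_metrics(tp = 1, tn = 1, fp = 1, fn = 1)
  expect_equal(unlist(m), c(accuracy = 0.5, sensitivity = 0.5,
                            specificity = 0.5))
  d <- seg_metrics(tp = 8, fn = 2, tn = 85, fp = 5)
  expect_equal(d$sensitivity, 0.8)
  expect_equal(d$specificity, 85 / 90)
  expect_equal(d$accuracy, 0.93)
  perfect <- seg_metrics(tp = 40, tn = 60)
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1))
  # zero-denominator metrics are undefined, never 0/0
  expect_true(is.na(seg_metrics(tp = 0, fn = 0, tn = 5, fp = 5)$sensitivity))
  expect_error(seg_metrics(tp = 0), "zero")
  # invariance to scaling all counts
  expect_equal(seg_metrics(tp = 3, tn = 5, fp = 2, fn = 1),
               seg_metrics(tp = 21, tn = 35, fp = 14, fn = 7))
})

test_that("micro-averaged metrics equal metrics of the summed counts", {
  set.seed(3)
  counts <- lapply(1:4, function(i)
    confusion_counts(matrix(round(runif(36)), 6, 6),
                     matrix(round(runif(36)), 6, 6)))
  total <- sum_counts(counts)
  expect_equal(total$tp, sum(vapply(counts, `[[`, 0, "tp")))
  agg1 <- seg_metrics(total)
  # the identity the aggregate report relies on
  tp <- sum(vapply(counts, `[[`, 0, "tp")); tn <- sum(vapply(counts, `[[`, 0, "tn"))
  fp <- sum(vapply(counts, `[[`, 0, "fp")); fn <- sum(vapply(counts, `[[`, 0, "fn"))
  expect_equal(agg1$accuracy, (tp + tn) / (tp + tn + fp + fn))
})

test_that("a short training run is finite, seeded and reduces the loss", {
  cfg <- tiny_config("single")
  pair <- small_phantom(seed = 21, size = 64)
  ps <- extract_patches(pair, size = 8, strategy = "random", n = 64, seed = 2)
  ctl <- train_control(epochs = 3, batch_size = 32, seed = 9)
  f1 <- train_vessel_net(vessel_net(cfg, seed = 1), ps, control = ctl)
  expect_equal(nrow(f1$history), 3)
  expect_true(all(is.finite(f1$history$train_loss)))
  # learning-rate schedule: exponential decay per epoch
  expect_equal(f1$history$lr, 0.001 * 0.9^(0:2))
  # identical seeds reproduce the epoch-1 loss exactly
  f2 <- train_vessel_net(vessel_net(cfg, seed = 1), ps, control = ctl)
  expect_identical(f1$history$train_loss[1], f2$history$train_loss[1])
  # optimization sanity on a longer run
  f3 <- train_vessel_net(vessel_net(cfg, seed = 1), ps,
                         control = train_control(epochs = 8, batch_size = 32,
                                                 seed = 9))
  expect_lt(tail(f3$history$train_loss, 1), f3$history$train_loss[1])
  expect_error(train_vessel_net(vessel_net(cfg, seed = 1), list(),
                                control = ctl), "empty")
})

test_that("tiled inference covers the full image and checkpoints reproduce metrics", {
  net <- vessel_net(network_config(), seed = 30)
  pair <- small_phantom(seed = 31, size = 128)
  pr <- predict_image(net, pair$image, stride = 32)
  expect_false(anyNA(pr$prob))
  expect_true(all(pr$coverage >= 1))
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  # save/reload: evaluation metrics are bitwise identical
  rep1 <- evaluate_pairs(net, list(pair))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  rep2 <- evaluate_pairs(back, list(pair))
  expect_identical(rep1$aggregate, rep2$aggregate)
  # predict methods agree with predict_image
  pm <- predict(net, pair, type = "mask")
  expect_identical(pm, binarize(pr$prob, 0.5))
})

test_that("model objects print, summarize, plot and expose coefficients", {
  cfg <- tiny_config("single")
  pair <- small_phantom(seed = 41, size = 64)
  ps <- extract_patches(pair, size = 8, strategy = "random", n = 16, seed = 3)
  fit <- train_vessel_net(vessel_net(cfg, seed = 2), ps, list(pair),
                          train_control(epochs = 1, batch_size = 16, seed = 3))
  expect_output(print(fit), "Fitted dual-attention")
  expect_output(summary(fit), "Tap shapes")
  expect_output(print(fit$model), "parameters")
  cf <- coef(fit)
  expect_true(is.list(cf) && length(unlist(cf)) == fit$model$n_params)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
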