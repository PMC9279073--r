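# Backbone wiring: declared tap shapes, residual unit, determinism,
# fully-convolutional behaviour and gradient flow.

test_that("C_B_R produces the declared shapes and the ReLU clamps", {
  x <- rand_fm(1, 3, 64, 64, seed = 1)
  expect_equal(dim(cbr(x, filters = 32, kernel = 3, stride = 1)),
               c(1, 32, 64, 64))
  x16 <- rand_fm(1, 16, 64, 64, seed = 2)
  expect_equal(dim(cbr(x16, filters = 64, kernel = 3, stride = 2)),
               c(1, 64, 32, 32))
  # gamma = 0, beta < 0 drives every pre-activation negative: all-zero output
  pr <- list(w = array(rnorm(3 * 3 * 3 * 4), c(3, 3, 3, 4)),
             gamma = rep(0, 4), beta = rep(-1, 4))
  expect_true(all(cbr(x, filters = 4, params = pr) == 0))
  expect_error(cbr(x, filters = 4, stride = 3), "stride")
})

test_that("the residual unit is shape-preserving and collapses to ReLU at zero weights", {
  x <- rand_fm(2, 8, 6, 6, seed = 3)
  p <- block1_params(8)
  expect_equal(dim(block1(x, p)), dim(x))
  # zero conv weights and zero BN shift: the inner path vanishes because
  # ECA(0) = 0, leaving the activated identity
  p0 <- p
  p0$conv3$w[] <- 0; p0$conv1$w[] <- 0
  p0$bn1$beta[] <- 0; p0$bn2$beta[] <- 0
  r <- pmax(x, 0); dim(r) <- dim(x)
  expect_equal(block1(x, p0, training = TRUE), r, tolerance = 1e-12)
})

test_that("the residual unit matches the scalar-loop oracle", {
  set.seed(44)
  x <- rand_fm(2, 2, 2, 2, seed = 44)
  p <- block1_params(2)
  p$conv3$w <- array(rnorm(3 * 3 * 2 * 2, sd = 0.4), c(3, 3, 2, 2))
  p$conv1$w <- array(rnorm(2 * 2, sd = 0.4), c(1, 1, 2, 2))
  p$bn1$gamma <- c(1.2, 0.8); p$bn1$beta <- c(0.1, -0.2)
  p$bn2$gamma <- c(0.9, 1.1); p$bn2$beta <- c(0, 0.3)
  p$eca$w <- c(0.7)
  expect_equal(block1(x, p, training = TRUE), oracle_block1(x, p),
               tolerance = 1e-8)
})

test_that("all declared tap shapes are reproduced on the default configuration", {
  tab <- inspect_taps(network_config())
  want <- data.frame(
    tap = c("F1", "F2", "F3", "F4", "F5", "F6", "output"),
    channel = c(16, 64, 64, 64, 64, 128, 3),
    height = c(64, 16, 32, 32, 32, 32, 64),
    width = c(64, 16, 32, 32, 32, 32, 64))
  got <- tab[match(want$tap, tab$tap), ]
  expect_equal(got$channel, want$channel)
  expect_equal(got$height, want$height)
  expect_equal(got$width, want$width)
  expect_true(all(got$batch == 1))
})

test_that("tap shapes hold for any batch size and scale fully convolutionally", {
  net <- vessel_net(network_config(), seed = 1)
  x3 <- rand_fm(3, 3, 64, 64, seed = 5)
  taps <- forward_pass(net, x3)$taps
  expect_equal(unname(taps$F1), c(3, 16, 64, 64))
  expect_equal(unname(taps$F6), c(3, 128, 32, 32))
  # doubling the input side doubles every tap's spatial dims, same channels
  x128 <- rand_fm(1, 3, 128, 128, seed = 6)
  t128 <- forward_pass(net, x128)$taps
  t64 <- forward_pass(net, rand_fm(1, 3, 64, 64, seed = 6))$taps
  for (nm in c("F1", "F2", "F3", "F4", "F5", "F6", "output")) {
    expect_equal(t128[[nm]][["channel"]], t64[[nm]][["channel"]])
    expect_equal(t128[[nm]][["height"]], 2L * t64[[nm]][["height"]])
    expect_equal(t128[[nm]][["width"]], 2L * t64[[nm]][["width"]])
  }
})

test_that("evaluation-mode forward is bitwise deterministic", {
  net <- vessel_net(network_config(), seed = 2)
  x <- rand_fm(2, 3, 64, 64, seed = 7)
  o1 <- forward_pass(net, x)$output
  o2 <- forward_pass(net, x)$output
  expect_identical(o1, o2)
})

test_that("configuration inconsistencies fail construction with named-tap diagnostics", {
  expect_error(network_config(input_size = c(30, 30)), "divisible by 4")
  expect_error(network_config(stem_filters = c(30, 16)),
               "SA at stem.*30.*16")
  expect_error(network_config(branchA_filters = 32), "F4.*F5")
  expect_error(network_config(f3_upsample_factor = 4), "F3")
})

test_that("one optimization step moves every trainable parameter", {
  cfg <- tiny_config("double")
  net <- vessel_net(cfg, seed = 8)
  pair <- small_phantom(seed = 9, size = 64)
  ps <- extract_patches(pair, size = 8, strategy = "random", n = 8, seed = 1)
  fit <- train_vessel_net(net, ps, control = train_control(
    epochs = 1, batch_size = 8, seed = 1, augment = FALSE))
  before <- unlist(net$params)
  after <- unlist(fit$model$params)
  expect_equal(length(before), length(after))
  # guards dead branches in the fusion wiring: no parameter leaf untouched
  walk <- function(a, b) {
    for (nm in names(a)) {
      if (is.list(a[[nm]])) walk(a[[nm]], b[[nm]])
      else expect_false(identical(a[[nm]], b[[nm]]),
                        info = paste("parameter unchanged:", nm))
    }
  }
  walk(net$params, fit$model$params)
})
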