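# Shuffle Attention and Efficient Channel Attention against independent
# scalar-loop oracles.

test_that("global average pooling matches hand-computed spatial means", {
  expect_equal(global_avg_pool(feature_map(rep(2, 36), c(1, 1, 6, 6)))[1, 1], 2)
  expect_equal(global_avg_pool(feature_map(1:4, c(1, 1, 2, 2)))[1, 1], 2.5)
  # 1x1 spatial: pooling is the identity on the channel vector
  v <- c(0.3, -1.2, 4)
  expect_equal(as.vector(global_avg_pool(feature_map(v, c(1, 3, 1, 1)))), v)
  # batch input against the loop oracle
  x <- rand_fm(3, 5, 4, 4, seed = 11)
  expect_equal(global_avg_pool(x), oracle_gap(x))
})

test_that("channel-attention branch gates by sigmoid of the pooled descriptor", {
  x <- rand_fm(1, 2, 3, 3, seed = 2)
  # zero gate parameters: sigmoid(0) = 0.5 everywhere
  expect_equal(channel_attention_branch(x, c(0, 0), c(0, 0)), 0.5 * x)
  # saturated bias: gate ~ 1, input passes through
  expect_equal(channel_attention_branch(x, c(0, 0), c(40, 40)), x,
               tolerance = 1e-12)
  # random input against the scalar oracle
  expect_equal(channel_attention_branch(x, c(1, 1), c(1, 1)),
               oracle_channel_branch(x, c(1, 1), c(1, 1)), tolerance = 1e-12)
  expect_error(channel_attention_branch(x, 1, 1), "channels")
})

test_that("spatial-attention branch gates by sigmoid of group-normalized values", {
  # spatially constant input: GN is 0, gate collapses to sigmoid(b2)
  xc <- feature_map(rep(3, 2 * 2 * 4 * 4), c(2, 2, 4, 4))
  got <- spatial_attention_branch(xc, c(5, -2), c(0.7, 0.7))
  expect_equal(got, plogis(0.7) * xc, tolerance = 1e-8)
  x <- rand_fm(2, 3, 4, 3, seed = 3)
  expect_equal(spatial_attention_branch(x, rep(0, 3), rep(0, 3)), 0.5 * x)
  w2 <- c(0.5, -1, 2); b2 <- c(0.1, 0, -0.3)
  expect_equal(spatial_attention_branch(x, w2, b2),
               oracle_spatial_branch(x, w2, b2), tolerance = 1e-10)
})

test_that("shuffle attention matches the fully unrolled oracle", {
  # degenerate grouping: G = 1 is the two branch results concatenated
  x <- rand_fm(2, 4, 2, 2, seed = 4)
  p <- sa_params(4, groups = 1)
  p$w1 <- c(0.3, -0.2); p$b1 <- c(0.1, 0.4)
  p$w2 <- c(1.1, 0.2); p$b2 <- c(-0.5, 0.2)
  got <- shuffle_attention(x, p)
  manual <- x
  manual[, 1:2, , ] <- channel_attention_branch(x[, 1:2, , , drop = FALSE],
                                                p$w1, p$b1)
  manual[, 3:4, , ] <- spatial_attention_branch(x[, 3:4, , , drop = FALSE],
                                                p$w2, p$b2)
  expect_equal(got, manual, tolerance = 1e-10)
  expect_equal(got, oracle_shuffle_attention(x, 1, p$w1, p$b1, p$w2, p$b2),
               tolerance = 1e-10)

  # grouped case with the inter-group channel shuffle
  x8 <- rand_fm(2, 8, 3, 3, seed = 5)
  p8 <- sa_params(8, groups = 2)
  p8$w1 <- c(0.5, -0.3); p8$b1 <- c(0, 0.2)
  p8$w2 <- c(-1, 0.7); p8$b2 <- c(0.3, 0)
  expect_equal(shuffle_attention(x8, p8),
               oracle_shuffle_attention(x8, 2, p8$w1, p8$b1, p8$w2, p8$b2),
               tolerance = 1e-10)
  # disabling the shuffle keeps the grouped concatenation order
  p8$shuffle <- FALSE
  expect_equal(shuffle_attention(x8, p8),
               oracle_shuffle_attention(x8, 2, p8$w1, p8$b1, p8$w2, p8$b2,
                                        shuffle = FALSE),
               tolerance = 1e-10)
})

test_that("shuffle attention rejects channel counts not divisible by 2G", {
  expect_error(sa_params(6, groups = 2), "6.*4|divisible")
  x <- rand_fm(1, 6, 2, 2)
  p <- sa_params(8, groups = 2)
  expect_error(shuffle_attention(x, p), "6")
})

test_that("adaptive ECA kernel size follows the nearest-odd log2 rule", {
  expect_identical(eca_kernel_size(64, 2, 1), 3L)
  expect_identical(eca_kernel_size(2, 2, 1), 1L)
  expect_identical(eca_kernel_size(256, 2, 1), 5L)
  # non-decreasing in the channel count
  ks <- eca_kernel_size(1:512)
  expect_true(all(diff(ks) >= 0))
  expect_true(all(ks %% 2 == 1))
  expect_error(eca_kernel_size(0), ">= 1")
})

test_that("ECA matches the explicit padded cross-channel convolution oracle", {
  # small channel counts get the adaptive minimum kernel of 1
  p <- eca_params(4, weights = 0.8)
  zero <- feature_map(numeric(4 * 4), c(1, 4, 2, 2))
  expect_equal(eca(zero, p), zero)
  x <- rand_fm(2, 4, 2, 2, seed = 6)
  expect_equal(dim(eca(x, p)), dim(x))
  expect_equal(eca(x, p), oracle_eca(x, p$w), tolerance = 1e-10)
  # 16 channels: kernel 3, true cross-channel mixing incl. zero padding
  p3 <- eca_params(16, weights = c(0.25, 0.5, -0.3))
  expect_identical(p3$kernel_size, 3L)
  x16 <- rand_fm(2, 16, 2, 2, seed = 7)
  expect_equal(eca(x16, p3), oracle_eca(x16, p3$w), tolerance = 1e-10)
  expect_error(eca(rand_fm(1, 8, 2, 2), p), "8 channels")
  # the stored kernel must satisfy the adaptive size rule
  expect_error(eca_params(4, weights = c(1, 2, 3)), "eca_kernel_size")
})

test_that("attention modules preserve shape and attenuate on random shapes", {
  for (seed in 1:8) {
    set.seed(seed)
    G <- sample(1:2, 1)
    C <- 2 * G * sample(1:2, 1)
    h <- sample(1:4, 1); w <- sample(1:4, 1); n <- sample(1:3, 1)
    x <- rand_fm(n, C, h, w, seed = 100 + seed)
    p <- sa_params(C, G)
    cpar <- C / (2 * G)
    p$w1 <- rnorm(cpar); p$b1 <- rnorm(cpar)
    p$w2 <- rnorm(cpar); p$b2 <- rnorm(cpar)
    y <- shuffle_attention(x, p)
    expect_identical(dim(y), dim(x))
    # every gate is strictly inside (0,1): attenuation, never amplification
    # (checked pre-shuffle, where channels align with their sources)
    pns <- p; pns$shuffle <- FALSE
    yns <- shuffle_attention(x, pns)
    expect_true(all(abs(yns) <= abs(x) + 1e-12))
    expect_true(all(abs(yns) > 0 | x == 0))
    # the shuffle itself is a pure channel permutation of the gated map
    expect_equal(sort(as.vector(y)), sort(as.vector(yns)))

    pe <- eca_params(C, weights = rnorm(eca_kernel_size(C)))
    ye <- eca(x, pe)
    expect_identical(dim(ye), dim(x))
    expect_true(all(abs(ye) <= abs(x) + 1e-12))
  }
})
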