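# The differentiable engine: convolution, batch norm, upsampling, and
# end-to-end gradients, verified against loop oracles and finite differences.

ns <- asNamespace("vesselnet")

to_hwcn <- function(x) aperm(x, c(3, 4, 2, 1))
to_nchw <- function(x) aperm(x, c(4, 3, 1, 2))

test_that("conv engine matches the scalar convolution oracle", {
  cases <- list(c(k = 3, s = 1), c(k = 1, s = 1), c(k = 3, s = 2),
                c(k = 1, s = 2))
  for (cs in cases) {
    x <- rand_fm(2, 3, 6, 4, seed = cs[["k"]] * 10 + cs[["s"]])
    set.seed(cs[["k"]] + cs[["s"]])
    w <- array(rnorm(cs[["k"]]^2 * 3 * 5), c(cs[["k"]], cs[["k"]], 3, 5))
    got <- to_nchw(ns$conv_fw(to_hwcn(x), w, stride = cs[["s"]]))
    expect_equal(got, oracle_conv2d(x, w, cs[["s"]]), tolerance = 1e-12)
  }
})

test_that("conv backward agrees with finite differences", {
  set.seed(9)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))   # engine layout
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  dy <- array(rnorm(2 * 2 * 3 * 2), c(2, 2, 3, 2))
  bw <- ns$conv_bw(x, w, dy, stride = 2)
  fd <- function(f, z, eps = 1e-6) {
    g <- array(0, dim(z))
    for (i in seq_along(z)) {
      zp <- z; zp[i] <- z[i] + eps
      zm <- z; zm[i] <- z[i] - eps
      g[i] <- (f(zp) - f(zm)) / (2 * eps)
    }
    g
  }
  expect_equal(bw$dx, fd(function(z) sum(ns$conv_fw(z, w, 2) * dy), x),
               tolerance = 1e-6)
  expect_equal(bw$dw, fd(function(z) sum(ns$conv_fw(x, z, 2) * dy), w),
               tolerance = 1e-6)
})

test_that("batch norm matches the per-channel normalization oracle", {
  x <- rand_fm(3, 4, 5, 5, seed = 21)
  gamma <- c(1, 0.5, 2, 1.5); beta <- c(0, -1, 0.3, 2)
  r <- ns$bn_fw(to_hwcn(x), list(gamma = gamma, beta = beta),
                list(mean = numeric(4), var = rep(1, 4)), training = TRUE)
  expect_equal(to_nchw(r$out), oracle_bn(x, gamma, beta), tolerance = 1e-10)
  # eval mode with fresh running stats (mean 0, var 1) is the affine map
  re <- ns$bn_fw(to_hwcn(x), list(gamma = gamma, beta = beta),
                 list(mean = numeric(4), var = rep(1, 4)), training = FALSE)
  manual <- x
  for (c in 1:4) manual[, c, , ] <- x[, c, , ] / sqrt(1 + 1e-5) * gamma[c] + beta[c]
  expect_equal(to_nchw(re$out), manual, tolerance = 1e-10)
})

test_that("bilinear upsampling doubles size with half-pixel-center weights", {
  # 1-D behaviour along each axis: [a, b] -> [a, .75a+.25b, .25a+.75b, b]
  x <- array(c(1, 3), c(1, 2, 1, 1))   # engine layout (H=1, W=2)
  up <- ns$upsample_fw(x, 2L, "bilinear")
  expect_equal(dim(up$out), c(2L, 4L, 1L, 1L))
  expect_equal(up$out[1, , 1, 1], c(1, 1.5, 2.5, 3))
  # nearest mode replicates
  upn <- ns$upsample_fw(x, 2L, "nearest")
  expect_equal(upn$out[1, , 1, 1], c(1, 1, 3, 3))
  # the backward is the exact adjoint of the forward linear map
  set.seed(31)
  xs <- array(rnorm(4 * 3 * 2 * 2), c(4, 3, 2, 2))
  ys <- array(rnorm(8 * 6 * 2 * 2), c(8, 6, 2, 2))
  f <- ns$upsample_fw(xs, 2L, "bilinear")
  bx <- ns$upsample_bw(f$cache, ys)
  expect_equal(sum(f$out * ys), sum(xs * bx), tolerance = 1e-10)
})

test_that("every parameter gradient of the full network matches finite differences", {
  cfg <- tiny_config("double")
  net <- vessel_net(cfg, seed = 3)
  set.seed(7)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y <- array((runif(8 * 8 * 2) > 0.5) * 1, c(8, 8, 2))
  lossfun <- function(params) {
    fw <- ns$net_forward(params, net$bufs, cfg, x, training = TRUE)
    ns$bce_grad_cpp(fw$out, dim(fw$out), y, 1e-7)$loss
  }
  fw <- ns$net_forward(net$params, net$bufs, cfg, x, training = TRUE,
                       keep_cache = TRUE)
  lg <- ns$bce_grad_cpp(fw$out, dim(fw$out), y, 1e-7)
  bw <- ns$net_backward(net$params, cfg, fw$cache, dpre = lg$dpre)

  leaves <- list()
  walk <- function(g, path) {
    for (nm in names(g)) {
      if (is.list(g[[nm]])) walk(g[[nm]], c(path, nm))
      else leaves[[paste(c(path, nm), collapse = "/")]] <<- g[[nm]]
    }
  }
  walk(bw$grads, character())
  expect_gt(length(leaves), 30)

  getset <- function(params, keys, i, val = NULL) {
    node <- params
    for (k in keys) node <- node[[k]]
    if (is.null(val)) return(node[i])
    expr <- params
    if (length(keys) == 1) params[[keys[1]]][i] <- val
    else if (length(keys) == 2) params[[keys[1]]][[keys[2]]][i] <- val
    else params[[keys[1]]][[keys[2]]][[keys[3]]][i] <- val
    params
  }
  eps <- 1e-5
  worst <- 0
  for (path in names(leaves)) {
    keys <- strsplit(path, "/")[[1]]
    set.seed(sum(utf8ToInt(path)))
    for (i in sample(seq_along(leaves[[path]]), min(2, length(leaves[[path]])))) {
      base <- getset(net$params, keys, i)
      lp <- lossfun(getset(net$params, keys, i, base + eps))
      lm <- lossfun(getset(net$params, keys, i, base - eps))
      fdg <- (lp - lm) / (2 * eps)
      an <- leaves[[path]][i]
      worst <- max(worst, abs(fdg - an) / max(1e-4, abs(fdg), abs(an)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("single-precision forward agrees with the double-precision engine", {
  cfgd <- network_config(precision = "double")
  cfgs <- network_config(precision = "single")
  net <- vessel_net(cfgd, seed = 5)
  set.seed(2)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  od <- ns$net_forward(net$params, net$bufs, cfgd, x, training = TRUE)$out
  os <- ns$net_forward(net$params, net$bufs, cfgs, x, training = TRUE)$out
  expect_lt(max(abs(od - ns$from_float(os))), 1e-5)
})
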