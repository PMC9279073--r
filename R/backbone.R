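# The two-branch fusion backbone.
#
# Wiring (default 64x64x3 input, shapes as height x width x channels):
#   stem:   input -> C_B_R(32,k3,s1) -> SA -> C_B_R(16,k3,s1)      = F1 64x64x16
#   A:      F1 -> SA -> C_B_R(64,k3,s2)                            = F4 32x32x64
#   B:      F1 -> SA -> C_B_R(32,k1,s2) -> Block1 -> C_B_R(64,k1,s2) = F2 16x16x64
#   F5:     F2 -> ECA -> upsample x2                               = F5 32x32x64
#   F3:     F2 -> Block1 -> C_B_R(64,k1,s1) -> upsample x2         = F3 32x32x64
#   fuse:   (F4 + F5) concat F3                                    = F6 32x32x128
#   head:   F6 -> C_B_R(32,k1,s1) -> Conv(3,k1,s1) -> upsample x2 -> sigmoid
#
# C_B_R = Convolution -> BatchNorm -> ReLU.  The head's final unit is a
# plain biased 1x1 logits convolution feeding the sigmoid: a ReLU there
# would be degenerate (sigmoid of a non-negative pre-activation never falls
# below 0.5) and a BN would re-center the logits each batch, preventing the
# confidently negative background logits the class prevalence demands.  The
# source description of this architecture prints a stride-4 upsample ahead
# of F3; a x2 factor is the only one consistent with the declared 32x32 F3
# shape and the fusion concat, and is the default (`f3_upsample_factor`).

#' Network configuration
#'
#' Describes the full backbone wiring: filter counts, attention settings and
#' upsampling behaviour.  The defaults reproduce the published topology for
#' 64x64 RGB patches, including every declared intermediate (tap) shape
#' F1-F6.
#'
#' @param input_size Integer `(height, width)` of a training patch; both must
#'   be divisible by 4 (two stride-2 stages).
#' @param input_channels Number of input channels (3 for RGB fundus patches).
#' @param output_channels Channels of the probability head (default 3; the
#'   per-pixel vessel probability is their mean).
#' @param stem_filters Filters of the two stem C_B_R units.
#' @param branchA_filters Filters of branch A's stride-2 C_B_R.
#' @param branchB_filters Filters of branch B's two stride-2 C_B_R units.
#' @param fusion_head_filters Filters of the two head units.
#' @param sa_groups Shuffle-Attention group count; a scalar or a length-3
#'   vector (stem, branch A, branch B).  Each gated channel count must be
#'   divisible by `2 * groups`.
#' @param eca_r,eca_b Constants of the adaptive ECA kernel-size rule.
#' @param upsample_mode `"bilinear"` (default) or `"nearest"`.
#' @param shuffle Apply the inter-group channel shuffle inside SA modules.
#' @param f3_upsample_factor Upsample factor feeding F3 (see Details).
#' @param head_activation `"sigmoid"` (default, probability head) or
#'   `"relu_sigmoid"` (keep the ReLU of the final C_B_R and squash
#'   afterwards).
#' @param bn_momentum,bn_eps Batch-norm running-statistics momentum and
#'   stabilizer.
#' @param gn_eps Group-norm stabilizer inside SA spatial branches.
#' @param precision Numeric precision of the internal activations:
#'   `"single"` (default; halves memory traffic during training) or
#'   `"double"`.  Parameters, statistics and gradient accumulators are
#'   always double.
#' @return An object of class `"vesselnet_config"`.
#' @export
network_config <- function(input_size = c(64L, 64L),
                           input_channels = 3L,
                           output_channels = 3L,
                           stem_filters = c(32L, 16L),
                           branchA_filters = 64L,
                           branchB_filters = c(32L, 64L),
                           fusion_head_filters = c(32L, 3L),
                           sa_groups = 8L,
                           eca_r = 2, eca_b = 1,
                           upsample_mode = c("bilinear", "nearest"),
                           shuffle = TRUE,
                           f3_upsample_factor = 2L,
                           head_activation = c("sigmoid", "relu_sigmoid"),
                           bn_momentum = 0.1, bn_eps = 1e-5, gn_eps = 1e-5,
                           precision = c("single", "double")) {
  cfg <- list(input_size = as.integer(input_size),
              input_channels = as.integer(input_channels),
              output_channels = as.integer(output_channels),
              stem_filters = as.integer(stem_filters),
              branchA_filters = as.integer(branchA_filters),
              branchB_filters = as.integer(branchB_filters),
              fusion_head_filters = as.integer(fusion_head_filters),
              sa_groups = as.integer(rep(sa_groups, length.out = 3L)),
              eca_r = eca_r, eca_b = eca_b,
              upsample_mode = match.arg(upsample_mode),
              shuffle = isTRUE(shuffle),
              f3_upsample_factor = as.integer(f3_upsample_factor),
              head_activation = match.arg(head_activation),
              bn_momentum = bn_momentum, bn_eps = bn_eps, gn_eps = gn_eps,
              precision = match.arg(precision))
  class(cfg) <- "vesselnet_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  hw <- cfg$input_size
  if (length(hw) != 2L || any(hw < 4L) || any(hw %% 4L != 0L))
    stop("input_size must be two integers divisible by 4 (two stride-2 stages)")
  sa_ch <- c(cfg$stem_filters[1L], cfg$stem_filters[2L], cfg$stem_filters[2L])
  sa_nm <- c("stem", "branch A", "branch B")
  for (i in 1:3) {
    if (sa_ch[i] %% (2L * cfg$sa_groups[i]) != 0L)
      stop(sprintf("SA at %s gates %d channels, not divisible by 2*groups = %d",
                   sa_nm[i], sa_ch[i], 2L * cfg$sa_groups[i]))
  }
  if (cfg$branchA_filters != cfg$branchB_filters[2L])
    stop(sprintf(paste0("tap F4 has %d channels but tap F5 has %d: ",
                        "the elementwise fusion F4 + F5 needs equal shapes"),
                 cfg$branchA_filters, cfg$branchB_filters[2L]))
  if (cfg$f3_upsample_factor * (hw[1L] %/% 4L) != hw[1L] %/% 2L)
    stop(sprintf(paste0("tap F3 would be %dx%d but the fusion concat with F6 ",
                        "needs %dx%d: f3_upsample_factor must be 2"),
                 cfg$f3_upsample_factor * hw[1L] %/% 4L,
                 cfg$f3_upsample_factor * hw[2L] %/% 4L,
                 hw[1L] %/% 2L, hw[2L] %/% 2L))
  invisible(cfg)
}

#' @export
print.vesselnet_config <- function(x, ...) {
  cat("Dual-attention fusion network configuration\n")
  cat(sprintf("  input:  %dx%dx%d  ->  output: %dx%dx%d probabilities\n",
              x$input_size[1L], x$input_size[2L], x$input_channels,
              x$input_size[1L], x$input_size[2L], x$output_channels))
  cat(sprintf("  stem filters %s | branch A %d | branch B %s | head %s\n",
              paste(x$stem_filters, collapse = "/"), x$branchA_filters,
              paste(x$branchB_filters, collapse = "/"),
              paste(x$fusion_head_filters, collapse = "/")))
  cat(sprintf("  SA groups %s (shuffle %s) | ECA r=%g b=%g | upsample %s\n",
              paste(x$sa_groups, collapse = "/"),
              if (x$shuffle) "on" else "off", x$eca_r, x$eca_b,
              x$upsample_mode))
  invisible(x)
}

# ---- parameter initialization ---------------------------------------------

# bias-free He-normal convolution weights (the following BN owns the shift)
he_conv <- function(kh, kw, cin, cout) {
  list(w = array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
                 dim = c(kh, kw, cin, cout)))
}

bn_par <- function(c) list(gamma = rep(1, c), beta = numeric(c))
bn_buf <- function(c) list(mean = numeric(c), var = rep(1, c))

#' Attention-gated residual unit parameters
#'
#' The residual unit computes
#' `y = ReLU(x) + ECA(BN(Conv1x1(ReLU(BN(Conv3x3(x))))))`;
#' both convolutions preserve the channel count so the unit is
#' shape-preserving.
#'
#' @param channels Channel count the unit serves.
#' @param eca_r,eca_b ECA kernel-size constants.
#' @return A list of conv/BN/ECA parameters of class `"block1_params"`.
#' @export
block1_params <- function(channels, eca_r = 2, eca_b = 1) {
  channels <- as.integer(channels)
  p <- list(conv3 = he_conv(3L, 3L, channels, channels),
            bn1 = bn_par(channels),
            conv1 = he_conv(1L, 1L, channels, channels),
            bn2 = bn_par(channels),
            eca = eca_params(channels, eca_r, eca_b))
  class(p) <- "block1_params"
  p
}

block1_buf <- function(channels) list(bn1 = bn_buf(channels), bn2 = bn_buf(channels))

# trainable leaves only (the network's parameter tree holds no metadata)
strip_block <- function(p) {
  p <- unclass(p)
  p$eca <- list(w = p$eca$w)
  p
}

#' Apply the attention-gated residual unit
#'
#' @param x Feature map whose channel count matches `p`.
#' @param p A [block1_params()] object.
#' @param training Use batch statistics (`TRUE`) or running statistics
#'   (`FALSE`, the default: fresh parameters carry mean 0 / var 1).
#' @return Feature map of the same shape as `x`.
#' @export
block1 <- function(x, p, training = FALSE) {
  check_feature_map(x)
  stopifnot(inherits(p, "block1_params"))
  C <- dim(x)[2L]
  buf <- block1_buf(C)
  hwcn_to_nchw(block1_fw(nchw_to_hwcn(x), p, buf, training = training)$out)
}

block1_fw <- function(x, p, buf, training, momentum = 0.1, eps = 1e-5) {
  c3 <- conv_fw(x, p$conv3$w, 1L)
  b1 <- bn_fw(c3, p$bn1, buf$bn1, training, momentum, eps, relu = TRUE)
  c1 <- conv_fw(b1$out, p$conv1$w, 1L)
  b2 <- bn_fw(c1, p$bn2, buf$bn2, training, momentum, eps)
  e <- eca_fw(b2$out, p$eca)
  out <- ew_relu_add(x, e$out, tdim(x))
  list(out = out,
       cache = list(x = x, bn1 = b1$cache, r1out = b1$out,
                    bn2 = b2$cache, eca = e$cache),
       buf = list(bn1 = b1$buf, bn2 = b2$buf))
}

block1_bw <- function(cache, p, dy) {
  de <- eca_bw(cache$eca, dy)
  db2 <- bn_bw(cache$bn2, de$dx)
  dc1 <- conv_bw(cache$r1out, p$conv1$w, db2$dx, 1L)
  db1 <- bn_bw(cache$bn1, dc1$dx)
  dc3 <- conv_bw(cache$x, p$conv3$w, db1$dx, 1L)
  dx <- ew_add(dc3$dx, ew_relu_bw(cache$x, dy, tdim(cache$x)),
               tdim(cache$x))
  list(dx = dx,
       grads = list(conv3 = list(w = dc3$dw),
                    bn1 = list(gamma = db1$dgamma, beta = db1$dbeta),
                    conv1 = list(w = dc1$dw),
                    bn2 = list(gamma = db2$dgamma, beta = db2$dbeta),
                    eca = list(w = de$dw)))
}

# ---- C_B_R -----------------------------------------------------------------

#' Convolution - BatchNorm - ReLU unit
#'
#' The backbone's basic unit: a same-padded 2-D convolution, batch
#' normalization and a ReLU.  Spatial dimensions shrink by `stride`
#' (ceiling division); channels become `filters`.
#'
#' @param x Feature map.
#' @param filters Output channel count.
#' @param kernel Odd kernel size (1 or 3 in the published topology).
#' @param stride Stride (1 or 2).
#' @param params Optional list `(w, gamma, beta)`; defaults to He-normal
#'   weights, unit BN scale, zero shift.  The convolution is bias-free (the
#'   batch norm owns the shift).
#' @param training Use batch statistics for the BN (default `TRUE`).
#' @return Feature map with `filters` channels.
#' @export
cbr <- function(x, filters, kernel = 3L, stride = 1L, params = NULL,
                training = TRUE) {
  check_feature_map(x)
  d <- dim(x)
  if (d[3L] %% stride != 0L || d[4L] %% stride != 0L)
    stop(sprintf("stride %d does not divide spatial dims %dx%d evenly",
                 stride, d[3L], d[4L]))
  cin <- d[2L]
  if (is.null(params)) {
    cv <- he_conv(kernel, kernel, cin, filters)
    params <- list(w = cv$w, gamma = rep(1, filters),
                   beta = numeric(filters))
  }
  xe <- nchw_to_hwcn(x)
  r <- cbr_fw(xe, list(w = params$w),
              list(gamma = params$gamma, beta = params$beta),
              bn_buf(filters), stride = stride, training = training)
  hwcn_to_nchw(r$out)
}

cbr_fw <- function(x, pconv, pbn, buf, stride, training,
                   momentum = 0.1, eps = 1e-5, need_dx = TRUE) {
  cv <- conv_fw(x, pconv$w, stride)
  bn <- bn_fw(cv, pbn, buf, training, momentum, eps, relu = TRUE)
  list(out = bn$out,
       cache = list(x = x, bn = bn$cache, stride = stride, need_dx = need_dx),
       buf = bn$buf)
}

cbr_bw <- function(cache, pconv, dy) {
  db <- bn_bw(cache$bn, dy)
  dc <- conv_bw(cache$x, pconv$w, db$dx, cache$stride, need_dx = cache$need_dx)
  list(dx = dc$dx,
       conv = list(w = dc$dw),
       bn = list(gamma = db$dgamma, beta = db$dbeta))
}

# ---- model construction ----------------------------------------------------

#' Build a dual-attention fusion segmentation network
#'
#' Initializes all trainable parameters (He-normal convolutions, unit-scale
#' batch norms, neutral zero-initialized SA gates) for the topology described
#' by `config`.  The returned object is untrained; fit it with
#' [train_vessel_net()].
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `"vessel_net"` with elements `config`,
#'   `params` (nested list of arrays) and `bufs` (batch-norm running
#'   statistics).
#' @examples
#' net <- vessel_net(seed = 1)
#' net
#' @export
vessel_net <- function(config = network_config(), seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  cf <- config
  f1 <- cf$stem_filters[1L]; f2 <- cf$stem_filters[2L]
  fa <- cf$branchA_filters
  fb1 <- cf$branchB_filters[1L]; fb2 <- cf$branchB_filters[2L]
  fh1 <- cf$fusion_head_filters[1L]; fh2 <- cf$fusion_head_filters[2L]
  G <- cf$sa_groups
  sa_par <- function(ch, g) {
    p <- sa_params(ch, g, eps = cf$gn_eps, shuffle = cf$shuffle)
    list(w1 = p$w1, b1 = p$b1, w2 = p$w2, b2 = p$b2)
  }
  params <- list(
    stem1 = he_conv(3L, 3L, cf$input_channels, f1), stem1_bn = bn_par(f1),
    stem_sa = sa_par(f1, G[1L]),
    stem2 = he_conv(3L, 3L, f1, f2), stem2_bn = bn_par(f2),
    a_sa = sa_par(f2, G[2L]),
    a_conv = he_conv(3L, 3L, f2, fa), a_bn = bn_par(fa),
    b_sa = sa_par(f2, G[3L]),
    b_conv1 = he_conv(1L, 1L, f2, fb1), b_bn1 = bn_par(fb1),
    b_block = strip_block(block1_params(fb1, cf$eca_r, cf$eca_b)),
    b_conv2 = he_conv(1L, 1L, fb1, fb2), b_bn2 = bn_par(fb2),
    f5_eca = list(w = eca_params(fb2, cf$eca_r, cf$eca_b)$w),
    f3_block = strip_block(block1_params(fb2, cf$eca_r, cf$eca_b)),
    f3_conv = he_conv(1L, 1L, fb2, fb2), f3_bn = bn_par(fb2),
    head1 = he_conv(1L, 1L, fa + fb2, fh1), head1_bn = bn_par(fh1))
  if (cf$head_activation == "sigmoid") {
    # probability head: a plain logits convolution (with bias) feeding the
    # sigmoid; no BN, which would re-center the logits every batch and fight
    # confident probabilities
    params$head2 <- c(he_conv(1L, 1L, fh1, fh2), list(b = numeric(fh2)))
  } else {
    params$head2 <- he_conv(1L, 1L, fh1, fh2)
    params$head2_bn <- bn_par(fh2)
  }
  bufs <- list(stem1 = bn_buf(f1), stem2 = bn_buf(f2), a = bn_buf(fa),
               b1 = bn_buf(fb1), b_block = block1_buf(fb1), b2 = bn_buf(fb2),
               f3_block = block1_buf(fb2), f3 = bn_buf(fb2),
               h1 = bn_buf(fh1))
  if (cf$head_activation != "sigmoid") bufs$h2 <- bn_buf(fh2)
  obj <- list(config = config, params = params, bufs = bufs,
              n_params = length(unlist(params)))
  class(obj) <- "vessel_net"
  obj
}

# live sa/eca parameter objects from the stored numeric leaves
sa_live <- function(leaves, channels, groups, cfg) {
  structure(list(channels = channels, groups = groups,
                 w1 = leaves$w1, b1 = leaves$b1,
                 w2 = leaves$w2, b2 = leaves$b2,
                 eps = cfg$gn_eps, shuffle = cfg$shuffle),
            class = "sa_params")
}

eca_live <- function(w, channels, cfg) {
  structure(list(channels = channels, r = cfg$eca_r, b = cfg$eca_b,
                 kernel_size = length(w), w = w),
            class = "eca_params")
}

block_live <- function(p, channels, cfg) {
  p$eca <- eca_live(p$eca$w, channels, cfg)
  p
}

# ---- full forward / backward ----------------------------------------------

# x: engine tensor (H,W,C,N).  Returns output, tap shapes, caches, updated
# running statistics.
net_forward <- function(params, bufs, cfg, x, training = FALSE,
                        keep_cache = FALSE) {
  if (identical(cfg$precision, "single")) x <- to_float(x)
  mom <- cfg$bn_momentum; eps <- cfg$bn_eps
  G <- cfg$sa_groups
  f2 <- cfg$stem_filters[2L]
  fb1 <- cfg$branchB_filters[1L]; fb2 <- cfg$branchB_filters[2L]
  taps <- list()
  cache <- if (keep_cache) list() else NULL

  s1 <- cbr_fw(x, params$stem1, params$stem1_bn, bufs$stem1, 1L, training, mom, eps,
               need_dx = FALSE)
  bufs$stem1 <- s1$buf
  sa1 <- sa_fw(s1$out, sa_live(params$stem_sa, cfg$stem_filters[1L], G[1L], cfg))
  s2 <- cbr_fw(sa1$out, params$stem2, params$stem2_bn, bufs$stem2, 1L, training, mom, eps)
  bufs$stem2 <- s2$buf
  F1 <- s2$out
  taps$F1 <- hwcn_shape(F1)

  saA <- sa_fw(F1, sa_live(params$a_sa, f2, G[2L], cfg))
  ca <- cbr_fw(saA$out, params$a_conv, params$a_bn, bufs$a, 2L, training, mom, eps)
  bufs$a <- ca$buf
  F4 <- ca$out
  taps$F4 <- hwcn_shape(F4)

  saB <- sa_fw(F1, sa_live(params$b_sa, f2, G[3L], cfg))
  cb1 <- cbr_fw(saB$out, params$b_conv1, params$b_bn1, bufs$b1, 2L, training, mom, eps)
  bufs$b1 <- cb1$buf
  blkA <- block1_fw(cb1$out, block_live(params$b_block, fb1, cfg),
                    bufs$b_block, training, mom, eps)
  bufs$b_block <- blkA$buf
  cb2 <- cbr_fw(blkA$out, params$b_conv2, params$b_bn2, bufs$b2, 2L, training, mom, eps)
  bufs$b2 <- cb2$buf
  F2 <- cb2$out
  taps$F2 <- hwcn_shape(F2)

  e5 <- eca_fw(F2, eca_live(params$f5_eca$w, fb2, cfg))
  u5 <- upsample_fw(e5$out, 2L, cfg$upsample_mode)
  F5 <- u5$out
  taps$F5 <- hwcn_shape(F5)

  blkB <- block1_fw(F2, block_live(params$f3_block, fb2, cfg),
                    bufs$f3_block, training, mom, eps)
  bufs$f3_block <- blkB$buf
  c3 <- cbr_fw(blkB$out, params$f3_conv, params$f3_bn, bufs$f3, 1L, training, mom, eps)
  bufs$f3 <- c3$buf
  u3 <- upsample_fw(c3$out, cfg$f3_upsample_factor, cfg$upsample_mode)
  F3 <- u3$out
  taps$F3 <- hwcn_shape(F3)

  dadd <- tdim(F4)
  if (!identical(tdim(F5), dadd))
    stop(sprintf("tap F4 (%s) and tap F5 (%s) are not elementwise-addable",
                 paste(hwcn_shape(F4), collapse = "x"),
                 paste(hwcn_shape(F5), collapse = "x")))
  add45 <- ew_add(F4, F5, dadd)
  d3 <- tdim(F3)
  if (!identical(d3[c(1L, 2L, 4L)], dadd[c(1L, 2L, 4L)]))
    stop(sprintf("tap F3 (%s) cannot be concatenated with F4+F5 (%s)",
                 paste(hwcn_shape(F3), collapse = "x"),
                 paste(hwcn_shape(add45), collapse = "x")))
  F6 <- chan_merge_cpp(add45, F3, dadd, seq_len(dadd[3L] + d3[3L]))
  taps$F6 <- hwcn_shape(F6)

  h1 <- cbr_fw(F6, params$head1, params$head1_bn, bufs$h1, 1L, training, mom, eps)
  bufs$h1 <- h1$buf
  hc <- conv_fw(h1$out, params$head2$w, 1L)
  hr <- NULL; hbn <- NULL
  if (cfg$head_activation == "relu_sigmoid") {
    hb <- bn_fw(hc, params$head2_bn, bufs$h2, training, mom, eps)
    bufs$h2 <- hb$buf
    hbn <- hb$cache
    hr <- relu_fw(hb$out)
    pre <- hr$out
  } else {
    d2 <- tdim(hc)
    pre <- cn_scale_add_cpp(hc, d2, rep(1, d2[3L] * d2[4L]),
                            matrix(params$head2$b, d2[3L], d2[4L]))
  }
  uo <- upsample_fw(pre, 2L, cfg$upsample_mode)
  out <- ew_sigmoid(uo$out, tdim(uo$out))
  taps$output <- hwcn_shape(out)

  if (keep_cache) {
    cache <- list(s1 = s1$cache, sa1 = sa1$cache, s2 = s2$cache,
                  saA = saA$cache, ca = ca$cache,
                  saB = saB$cache, cb1 = cb1$cache, blkA = blkA$cache,
                  cb2 = cb2$cache, e5 = e5$cache, u5 = u5$cache,
                  blkB = blkB$cache, c3 = c3$cache, u3 = u3$cache,
                  h1 = h1$cache, hbn = hbn, h1out = h1$out,
                  hr = if (!is.null(hr)) hr$cache else NULL,
                  uo = uo$cache, out = out,
                  nca = dadd[3L], nc3 = d3[3L])
  }
  list(out = out, taps = taps, cache = cache, bufs = bufs)
}

# dout: gradient of the loss w.r.t. the sigmoid output.  If `dpre` is given
# instead, it is taken as the gradient w.r.t. the upsampled pre-activation
# (the numerically stable path used with the cross-entropy loss).
net_backward <- function(params, cfg, cache, dout = NULL, dpre = NULL) {
  fb1 <- cfg$branchB_filters[1L]; fb2 <- cfg$branchB_filters[2L]
  if (is.null(dpre)) {
    p <- from_float(cache$out)
    dpre <- dout * p * (1 - p)
    dim(dpre) <- dim(p)
    if (is.raw(cache$out)) dpre <- to_float_cpp(dpre, tdim(cache$out))
  }
  dup <- upsample_bw(cache$uo, dpre)
  dhb <- NULL; db2 <- NULL
  if (cfg$head_activation == "relu_sigmoid") {
    dup <- relu_bw(cache$hr, dup)
    dhb <- bn_bw(cache$hbn, dup)
    dup <- dhb$dx
  } else {
    db2 <- rowSums(cn_sum_cpp(dup, tdim(dup)))
  }
  dhc <- conv_bw(cache$h1out, params$head2$w, dup, 1L)
  dh1 <- cbr_bw(cache$h1, params$head1, dhc$dx)

  dF6 <- dh1$dx
  nca <- cache$nca; nc3 <- cache$nc3
  dadd <- chan_gather_cpp(dF6, tdim(dF6), seq_len(nca))
  dF3 <- chan_gather_cpp(dF6, tdim(dF6), nca + seq_len(nc3))
  dF4 <- dadd; dF5 <- dadd

  du3 <- upsample_bw(cache$u3, dF3)
  dc3 <- cbr_bw(cache$c3, params$f3_conv, du3)
  dblkB <- block1_bw(cache$blkB, block_live(params$f3_block, fb2, cfg), dc3$dx)
  dF2 <- dblkB$dx

  du5 <- upsample_bw(cache$u5, dF5)
  de5 <- eca_bw(cache$e5, du5)
  dF2 <- ew_add(dF2, de5$dx, tdim(dF2))

  dcb2 <- cbr_bw(cache$cb2, params$b_conv2, dF2)
  dblkA <- block1_bw(cache$blkA, block_live(params$b_block, fb1, cfg), dcb2$dx)
  dcb1 <- cbr_bw(cache$cb1, params$b_conv1, dblkA$dx)
  dsaB <- sa_bw(cache$saB, dcb1$dx)
  dF1 <- dsaB$dx

  dca <- cbr_bw(cache$ca, params$a_conv, dF4)
  dsaA <- sa_bw(cache$saA, dca$dx)
  dF1 <- ew_add(dF1, dsaA$dx, tdim(dF1))

  ds2 <- cbr_bw(cache$s2, params$stem2, dF1)
  dsa1 <- sa_bw(cache$sa1, ds2$dx)
  ds1 <- cbr_bw(cache$s1, params$stem1, dsa1$dx)

  sa_g <- function(d) list(w1 = d$dw1, b1 = d$db1, w2 = d$dw2, b2 = d$db2)
  grads <- list(
    stem1 = ds1$conv, stem1_bn = ds1$bn,
    stem_sa = sa_g(dsa1),
    stem2 = ds2$conv, stem2_bn = ds2$bn,
    a_sa = sa_g(dsaA),
    a_conv = dca$conv, a_bn = dca$bn,
    b_sa = sa_g(dsaB),
    b_conv1 = dcb1$conv, b_bn1 = dcb1$bn,
    b_block = dblkA$grads,
    b_conv2 = dcb2$conv, b_bn2 = dcb2$bn,
    f5_eca = list(w = de5$dw),
    f3_block = dblkB$grads,
    f3_conv = dc3$conv, f3_bn = dc3$bn,
    head1 = dh1$conv, head1_bn = dh1$bn
  )
  if (cfg$head_activation == "relu_sigmoid") {
    grads$head2 <- list(w = dhc$dw)
    grads$head2_bn <- list(gamma = dhb$dgamma, beta = dhb$dbeta)
  } else {
    grads$head2 <- list(w = dhc$dw, b = db2)
  }
  list(dx = ds1$dx, grads = grads)
}

#' Forward pass with tap records
#'
#' Runs a feature map through the network and records the shape of every
#' named intermediate (F1-F6) plus the output, in
#' `(batch, channel, height, width)` order.
#'
#' @param model A `"vessel_net"` or `"vessel_net_fit"` object.
#' @param x Feature map whose spatial size matches `model$config$input_size`.
#' @param training Use batch statistics in the batch norms.
#' @return A list with `output` (feature map of probabilities) and `taps`
#'   (named list of shape vectors).
#' @examples
#' net <- vessel_net(seed = 1)
#' r <- forward_pass(net, feature_map(rnorm(3 * 64 * 64), c(1, 3, 64, 64)))
#' r$taps$F6
#' @export
forward_pass <- function(model, x, training = FALSE) {
  model <- as_vessel_net(model)
  check_feature_map(x)
  d <- dim(x)
  hw <- model$config$input_size
  if (d[3L] %% 4L != 0L || d[4L] %% 4L != 0L)
    stop(sprintf("input spatial dims %dx%d must be divisible by 4", d[3L], d[4L]))
  if (d[2L] != model$config$input_channels)
    stop(sprintf("input has %d channels, expected %d", d[2L],
                 model$config$input_channels))
  r <- net_forward(model$params, model$bufs, model$config, nchw_to_hwcn(x),
                   training = training)
  list(output = hwcn_to_nchw(from_float(r$out)), taps = r$taps)
}

#' Tap-shape table
#'
#' Executes a single forward pass on a unit batch and tabulates the shape of
#' every tap point -- the executable form of the architecture's declared
#' intermediate shapes (F1 64x64x16, F2 16x16x64, F3/F4/F5 32x32x64,
#' F6 32x32x128 for the default configuration).
#'
#' @param x A [network_config()], `"vessel_net"` or `"vessel_net_fit"`.
#' @param batch Batch size of the probe input.
#' @return A data frame with columns `tap`, `batch`, `channel`, `height`,
#'   `width`.
#' @examples
#' inspect_taps(network_config())
#' @export
inspect_taps <- function(x = network_config(), batch = 1L) {
  model <- if (inherits(x, "vesselnet_config")) vessel_net(x, seed = 0L)
           else as_vessel_net(x)
  hw <- model$config$input_size
  probe <- array(0, c(batch, model$config$input_channels, hw[1L], hw[2L]))
  taps <- forward_pass(model, probe)$taps
  ord <- intersect(c("F1", "F2", "F3", "F4", "F5", "F6", "output"), names(taps))
  data.frame(tap = ord,
             do.call(rbind, lapply(taps[ord], function(s)
               as.data.frame(as.list(s)))),
             row.names = NULL)
}

as_vessel_net <- function(model) {
  if (inherits(model, "vessel_net_fit")) return(model$model)
  if (inherits(model, "vessel_net")) return(model)
  stop("expected a vessel_net or vessel_net_fit object")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible()
}
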