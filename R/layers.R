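# Differentiable layer primitives on (H,W,C,N) engine tensors.
# Each *_fw returns list(out, cache...); each *_bw consumes the cache and the
# upstream gradient and returns the input gradient plus parameter gradients.

# ---- 2-D convolution (same padding, odd kernels) --------------------------

# w: array dim (kh, kw, C_in, F).  Convolutions are bias-free: every conv in
# the topology feeds a batch norm, which absorbs (and would zero the gradient
# of) any constant shift.
conv_fw <- function(x, w, stride = 1L) {
  d <- dim(w)
  wm <- matrix(w, ncol = d[4L])
  conv2d_fw_cpp(x, tdim(x), wm, d[1L], d[2L], as.integer(stride))
}

conv_bw <- function(x, w, dy, stride = 1L, need_dx = TRUE) {
  d <- dim(w)
  wm <- matrix(w, ncol = d[4L])
  r <- conv2d_bw_cpp(x, tdim(x), wm, dy, d[1L], d[2L], as.integer(stride),
                     need_dx)
  list(dx = r$dx, dw = array(r$dw, dim = d))
}

# ---- batch normalization ---------------------------------------------------

# p: list(gamma, beta); buf: list(mean, var) running statistics.
# relu = TRUE fuses the following ReLU into the apply pass; the backward
# recomputes the activation mask from the cached input and statistics.
bn_fw <- function(x, p, buf, training, momentum = 0.1, eps = 1e-5,
                  relu = FALSE) {
  d <- tdim(x)
  if (training) {
    r <- bn_fw_train_cpp(x, d, p$gamma, p$beta, eps, relu)
    cnt <- prod(d[c(1L, 2L, 4L)])
    unb <- if (cnt > 1) r$var * cnt / (cnt - 1) else r$var
    buf$mean <- (1 - momentum) * buf$mean + momentum * r$mean
    buf$var  <- (1 - momentum) * buf$var + momentum * unb
    list(out = r$out,
         cache = list(x = x, mean = r$mean, istd = r$istd, gamma = p$gamma,
                      beta = p$beta, relu = relu),
         buf = buf)
  } else {
    list(out = bn_fw_eval_cpp(x, d, p$gamma, p$beta, buf$mean, buf$var, eps,
                              relu),
         cache = NULL, buf = buf)
  }
}

bn_bw <- function(cache, dy) {
  r <- bn_bw_cpp(cache$x, dy, tdim(cache$x), cache$mean, cache$istd,
                 cache$gamma, cache$beta, cache$relu)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

# ---- ReLU ------------------------------------------------------------------

relu_fw <- function(x) list(out = ew_relu_fw(x, tdim(x)), cache = x)

relu_bw <- function(cache, dy) ew_relu_bw(cache, dy, tdim(cache))

# ---- upsampling ------------------------------------------------------------

# Separable interpolation maps for one axis.  Bilinear uses the
# half-pixel-center convention (output coordinate i samples input coordinate
# (i + 0.5)/factor - 0.5, edge-clamped); nearest snaps to the closest source.
axis_map <- function(n_in, factor, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  n_out <- as.integer(round(n_in * factor))
  i0 <- integer(n_out); i1 <- integer(n_out); t <- numeric(n_out)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) / factor - 0.5
    if (mode == "nearest") {
      j <- min(max(floor(src + 0.5), 0), n_in - 1)
      i0[i] <- j + 1L; i1[i] <- j + 1L; t[i] <- 0
    } else {
      j0 <- floor(src)
      t[i] <- src - j0
      i0[i] <- min(max(j0, 0), n_in - 1) + 1L
      i1[i] <- min(max(j0 + 1, 0), n_in - 1) + 1L
    }
  }
  list(i0 = i0, i1 = i1, t = t)
}

upsample_fw <- function(x, factor = 2L, mode = "bilinear") {
  d <- tdim(x)
  mh <- axis_map(d[1L], factor, mode)
  mw <- axis_map(d[2L], factor, mode)
  out <- upsample_fw_cpp(x, d, mh$i0, mh$i1, mh$t, mw$i0, mw$i1, mw$t)
  list(out = out, cache = list(idim = d, odim = tdim(out), mh = mh, mw = mw))
}

upsample_bw <- function(cache, dy) {
  upsample_bw_cpp(dy, cache$odim, cache$idim,
                  cache$mh$i0, cache$mh$i1, cache$mh$t,
                  cache$mw$i0, cache$mw$i1, cache$mw$t)
}
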