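# Shuffle Attention (SA) and Efficient Channel Attention (ECA).
#
# SA splits the C channels into G groups.  Each group is halved: the first
# half passes through a channel-attention branch (global average pooling,
# per-channel affine gate, sigmoid), the second through a spatial-attention
# branch (group normalization over the half-group, per-channel affine gate,
# sigmoid).  Gate parameters have length C/(2G) and are shared across groups.
# The gated halves are concatenated per group, the groups reassembled, and an
# inter-group channel shuffle mixes information between groups.
#
# ECA gates channels with a sigmoid of a 1-D cross-channel convolution of the
# pooled channel descriptor; the kernel size adapts to the channel count.

#' Global average pooling
#'
#' Spatial mean of every channel: the channel descriptor used by both
#' attention modules.
#'
#' @param x Feature map, `(batch, channel, height, width)` array.
#' @return A `batch x channel` matrix of spatial means.
#' @examples
#' x <- feature_map(1:4, dim = c(1, 1, 2, 2))
#' global_avg_pool(x)  # 2.5
#' @export
global_avg_pool <- function(x) {
  check_feature_map(x)
  d <- dim(x)
  s <- rowSums(matrix(x, nrow = d[1L] * d[2L])) / (d[3L] * d[4L])
  matrix(s, nrow = d[1L], ncol = d[2L])
}

#' Shuffle-Attention parameters
#'
#' @param channels Channel count `C` the parameters will serve.
#' @param groups Number of channel groups `G`; `C` must be divisible by `2*G`.
#' @param gate_init Initial value for the gate weights/biases (default 0, a
#'   neutral gate of sigmoid(0) = 0.5 everywhere).
#' @param eps Group-norm stabilizer.
#' @param shuffle Apply the inter-group channel shuffle after reassembly.
#' @return An object of class `"sa_params"`.
#' @export
sa_params <- function(channels, groups = 8L, gate_init = 0, eps = 1e-5,
                      shuffle = TRUE) {
  channels <- as.integer(channels); groups <- as.integer(groups)
  if (groups < 1L) stop("groups must be a positive integer")
  if (channels %% (2L * groups) != 0L)
    stop(sprintf("channel count %d is not divisible by 2*groups = %d",
                 channels, 2L * groups))
  ch <- channels %/% (2L * groups)
  structure(list(channels = channels, groups = groups,
                 w1 = rep(gate_init, ch), b1 = rep(gate_init, ch),
                 w2 = rep(gate_init, ch), b2 = rep(gate_init, ch),
                 eps = eps, shuffle = isTRUE(shuffle)),
            class = "sa_params")
}

#' Channel-attention branch of Shuffle Attention
#'
#' Gates a half-group by `sigmoid(w1 * GAP(x) + b1)`, broadcast over space.
#'
#' @param x_half Feature map holding one half-group.
#' @param w1,b1 Gate weight and bias vectors, length = channel count of
#'   `x_half`.
#' @return Feature map of the same shape.
#' @export
channel_attention_branch <- function(x_half, w1, b1) {
  check_feature_map(x_half)
  C <- dim(x_half)[2L]
  if (length(w1) != C || length(b1) != C)
    stop(sprintf("gate parameters have length %d/%d but input has %d channels",
                 length(w1), length(b1), C))
  xe <- nchw_to_hwcn(x_half)
  hwcn_to_nchw(sa_channel_fw(xe, w1, b1)$out)
}

#' Spatial-attention branch of Shuffle Attention
#'
#' Gates a half-group by `sigmoid(w2 * GN(x) + b2)` elementwise, where GN
#' normalizes the half-group (all its channels and pixels, per sample) to
#' zero mean and unit variance.
#'
#' @inheritParams channel_attention_branch
#' @param w2,b2 Gate weight and bias vectors, length = channel count.
#' @param eps Group-norm stabilizer.
#' @return Feature map of the same shape.
#' @export
spatial_attention_branch <- function(x_half, w2, b2, eps = 1e-5) {
  check_feature_map(x_half)
  C <- dim(x_half)[2L]
  if (length(w2) != C || length(b2) != C)
    stop(sprintf("gate parameters have length %d/%d but input has %d channels",
                 length(w2), length(b2), C))
  xe <- nchw_to_hwcn(x_half)
  hwcn_to_nchw(sa_spatial_fw(xe, w2, b2, n_groups = 1L, eps = eps)$out)
}

#' Shuffle Attention
#'
#' Applies grouped channel/spatial attention with an inter-group channel
#' shuffle.  Shape-preserving.
#'
#' @param x Feature map with `C` channels, `C` divisible by `2 * p$groups`.
#' @param p An [sa_params()] object.
#' @return Feature map of the same shape as `x`.
#' @export
shuffle_attention <- function(x, p) {
  check_feature_map(x)
  stopifnot(inherits(p, "sa_params"))
  if (dim(x)[2L] != p$channels)
    stop(sprintf("input has %d channels but sa_params was built for %d",
                 dim(x)[2L], p$channels))
  hwcn_to_nchw(sa_fw(nchw_to_hwcn(x), p)$out)
}

#' Adaptive kernel size for Efficient Channel Attention
#'
#' The 1-D cross-channel kernel size grows logarithmically with the channel
#' count: the nearest odd integer to `log2(c)/r + b/r`, with ties resolved
#' toward the smaller odd value and a floor of 1.
#'
#' @param c Channel count (positive integer).
#' @param r,b Tuning constants; defaults `r = 2`, `b = 1`.
#' @return An odd positive integer.
#' @examples
#' eca_kernel_size(64)   # 3
#' eca_kernel_size(256)  # 5
#' @export
eca_kernel_size <- function(c, r = 2, b = 1) {
  if (any(c < 1)) stop("channel count must be >= 1")
  if (r <= 0) stop("r must be positive")
  t <- log2(c) / r + b / r
  lo <- 2 * floor((t - 1) / 2) + 1   # largest odd <= t (or t itself if odd)
  hi <- lo + 2
  k <- ifelse(t - lo <= hi - t, lo, hi)
  as.integer(pmax(1, k))
}

#' Efficient Channel Attention parameters
#'
#' @param channels Channel count the module serves.
#' @param r,b Kernel-size constants, see [eca_kernel_size()].
#' @param weights Optional 1-D convolution kernel (length
#'   `eca_kernel_size(channels, r, b)`); defaults to He-normal draws.
#' @return An object of class `"eca_params"`.
#' @export
eca_params <- function(channels, r = 2, b = 1, weights = NULL) {
  channels <- as.integer(channels)
  k <- eca_kernel_size(channels, r, b)
  if (is.null(weights)) weights <- rnorm(k, sd = sqrt(2 / k))
  if (length(weights) != k)
    stop(sprintf("ECA kernel has length %d but eca_kernel_size(%d, %g, %g) = %d",
                 length(weights), channels, r, b, k))
  if (k %% 2L != 1L) stop("ECA kernel size must be odd")
  structure(list(channels = channels, r = r, b = b,
                 kernel_size = k, w = as.numeric(weights)),
            class = "eca_params")
}

#' Efficient Channel Attention
#'
#' Global average pooling, a same-padded 1-D convolution across the channel
#' axis, a sigmoid, and a broadcast multiply back onto the input.
#' Shape-preserving.
#'
#' @param x Feature map whose channel count matches `p$channels`.
#' @param p An [eca_params()] object.
#' @return Feature map of the same shape as `x`.
#' @export
eca <- function(x, p) {
  check_feature_map(x)
  stopifnot(inherits(p, "eca_params"))
  if (dim(x)[2L] != p$channels)
    stop(sprintf("input has %d channels but eca_params was built for %d",
                 dim(x)[2L], p$channels))
  hwcn_to_nchw(eca_fw(nchw_to_hwcn(x), p)$out)
}

# ===========================================================================
# engine implementations on (H,W,C,N) tensors, with backward passes
# ===========================================================================

# channel branch: g = sigmoid(w1 * GAP(x) + b1); y = g (.) x
# w1/b1 recycle over the channel axis (length C or a divisor of it).
# Forward only: the training path uses the fused sa_fw/sa_bw below.
sa_channel_fw <- function(x, w1, b1) {
  d <- tdim(x); H <- d[1L]; W <- d[2L]
  s <- cn_sum_cpp(x, d) / (H * W)             # C x N
  g <- sigmoid(s * w1 + b1)                   # recycles down columns
  list(out = cn_scale_cpp(x, d, g), s = s, g = g)
}

# spatial branch: xn = GN(x) over n_groups channel groups (per sample);
# g = sigmoid(w2 * xn + b2); y = g (.) x.  Forward only.
sa_spatial_fw <- function(x, w2, b2, n_groups = 1L, eps = 1e-5) {
  d <- tdim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  ch <- C %/% n_groups                        # channels per norm group
  cnt <- ch * H * W
  fold_gn <- function(m)                      # (C x N) -> (G x N) group sums
    colSums(array(m, c(ch, n_groups, N)), dims = 1L)
  expand <- function(m) {
    m <- matrix(m, n_groups, N)
    m[rep(seq_len(n_groups), each = ch), , drop = FALSE]
  }
  mu <- fold_gn(cn_sum_cpp(x, d)) / cnt
  va <- fold_gn(cn_dot_cpp(x, x, d)) / cnt - mu^2
  istd <- 1 / sqrt(pmax(va, 0) + eps)
  out <- sa_apply_fw_cpp(x, d, seq_len(C), rep(2L, C),
                         matrix(0, C, N), expand(mu), expand(istd),
                         rep(w2, length.out = C), rep(b2, length.out = C))
  list(out = out)
}

sa_perm <- function(C, G) as.vector(matrix(seq_len(C), nrow = G, byrow = TRUE))

# channel bookkeeping for the fused SA kernels: br[c] names the branch of
# source channel c, src[j] the source channel of output j (the inter-group
# shuffle folded in)
sa_maps <- function(C, G, shuffle) {
  cg <- C %/% G; ch <- cg %/% 2L
  idx1 <- as.vector(outer(seq_len(ch), (seq_len(G) - 1L) * cg, `+`))
  idx2 <- idx1 + ch
  br <- integer(C); br[idx1] <- 1L; br[idx2] <- 2L
  src <- if (shuffle && G > 1L) sa_perm(C, G) else seq_len(C)
  list(idx1 = idx1, idx2 = idx2, br = br, src = src, ch = ch, G = G)
}

sa_fw <- function(x, p) {
  d <- tdim(x); C <- d[3L]; N <- d[4L]; HW <- d[1L] * d[2L]
  G <- p$groups
  if (C %% (2L * G) != 0L)
    stop(sprintf("channel count %d is not divisible by 2*groups = %d", C, 2L * G))
  mp <- sa_maps(C, G, p$shuffle)
  ch <- mp$ch; cnt <- ch * HW
  st <- sa_stats_cpp(x, d)
  # channel-branch gates from the pooled descriptor
  s1 <- st$s[mp$idx1, , drop = FALSE] / HW
  g1h <- sigmoid(s1 * p$w1 + p$b1)              # w1/b1 recycle within groups
  g1 <- matrix(0, C, N); g1[mp$idx1, ] <- g1h
  # spatial-branch group-norm statistics per (group, sample)
  fold_gn <- function(m) colSums(array(m, c(ch, G, N)), dims = 1L)
  expand <- function(m) {
    m <- matrix(m, G, N)
    m[rep(seq_len(G), each = ch), , drop = FALSE]
  }
  mu_g <- fold_gn(st$s[mp$idx2, , drop = FALSE]) / cnt
  va_g <- fold_gn(st$q[mp$idx2, , drop = FALSE]) / cnt - mu_g^2
  istd_g <- 1 / sqrt(pmax(va_g, 0) + p$eps)
  mu <- matrix(0, C, N); istd <- matrix(0, C, N)
  mu[mp$idx2, ] <- expand(mu_g); istd[mp$idx2, ] <- expand(istd_g)
  wc <- numeric(C); bc <- numeric(C)
  wc[mp$idx2] <- rep(p$w2, G); bc[mp$idx2] <- rep(p$b2, G)
  out <- sa_apply_fw_cpp(x, d, mp$src, mp$br, g1, mu, istd, wc, bc)
  list(out = out,
       cache = list(x = x, mp = mp, g1 = g1, s1 = s1, mu = mu, istd = istd,
                    wc = wc, bc = bc, w1 = p$w1, d = d))
}

sa_bw <- function(cache, dy) {
  d <- cache$d; C <- d[3L]; N <- d[4L]; HW <- d[1L] * d[2L]
  mp <- cache$mp; ch <- mp$ch; G <- mp$G; cnt <- ch * HW
  fold_gn <- function(m) colSums(array(m, c(ch, G, N)), dims = 1L)
  expand <- function(m) {
    m <- matrix(m, G, N)
    m[rep(seq_len(G), each = ch), , drop = FALSE]
  }
  fold_par <- function(m) rowSums(matrix(rowSums(m), nrow = ch))
  st <- sa_bw1_cpp(dy, cache$x, d, mp$src, mp$br, cache$mu, cache$istd,
                   cache$wc, cache$bc)
  # channel branch: dz through the sigmoid gate and the pooling
  g1h <- cache$g1[mp$idx1, , drop = FALSE]
  dz1 <- st$A1[mp$idx1, , drop = FALSE] * g1h * (1 - g1h)
  dw1 <- fold_par(dz1 * cache$s1)
  db1 <- fold_par(dz1)
  add1 <- matrix(0, C, N)
  add1[mp$idx1, ] <- (dz1 * cache$w1) / HW      # w1 recycles within groups
  # spatial branch: gate-parameter gradients and group-norm closure terms
  A1s <- st$A1[mp$idx2, , drop = FALSE]
  A2s <- st$A2[mp$idx2, , drop = FALSE]
  dw2 <- fold_par(A1s)
  db2 <- fold_par(A2s)
  w2f <- cache$wc[mp$idx2]
  m1 <- matrix(0, C, N); m2 <- matrix(0, C, N)
  m1[mp$idx2, ] <- expand(fold_gn(A2s * w2f) / cnt)
  m2[mp$idx2, ] <- expand(fold_gn(A1s * w2f) / cnt)
  dx <- sa_bw2_cpp(dy, cache$x, d, mp$src, mp$br, cache$g1, cache$mu,
                   cache$istd, cache$wc, cache$bc, add1, m1, m2)
  list(dx = dx, dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

# 1-D same-padded cross-channel convolution of a (C x N) descriptor
conv1d_chan <- function(s, w) {
  k <- length(w); pad <- (k - 1L) %/% 2L
  C <- nrow(s); N <- ncol(s)
  t <- matrix(0, C, N)
  for (j in seq_len(k)) {
    o <- j - 1L - pad                         # source offset
    src <- seq_len(C) + o
    keep <- src >= 1L & src <= C
    t[keep, ] <- t[keep, ] + w[j] * s[src[keep], , drop = FALSE]
  }
  t
}

eca_fw <- function(x, p) {
  d <- tdim(x); H <- d[1L]; W <- d[2L]
  s <- cn_sum_cpp(x, d) / (H * W)
  g <- sigmoid(conv1d_chan(s, p$w))
  list(out = cn_scale_cpp(x, d, g),
       cache = list(x = x, s = s, g = g, w = p$w))
}

eca_bw <- function(cache, dy) {
  x <- cache$x; g <- cache$g; s <- cache$s; w <- cache$w
  d <- tdim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]
  k <- length(w); pad <- (k - 1L) %/% 2L
  dg <- cn_dot_cpp(dy, x, d)
  dt <- dg * g * (1 - g)
  dw <- numeric(k)
  for (j in seq_len(k)) {
    o <- j - 1L - pad
    src <- seq_len(C) + o
    keep <- src >= 1L & src <= C
    dw[j] <- sum(dt[keep, , drop = FALSE] * s[src[keep], , drop = FALSE])
  }
  ds <- conv1d_chan(dt, rev(w))               # correlation transpose
  dx <- cn_scale_add_cpp(dy, d, g, ds / (H * W))
  list(dx = dx, dw = dw)
}
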