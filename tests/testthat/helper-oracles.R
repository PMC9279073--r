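# Independent scalar-loop oracles.  Everything here is written with explicit
# elementwise loops over (batch, channel, height, width) arrays and shares no
# code with the package internals.

oracle_sigmoid <- function(z) 1 / (1 + exp(-z))

oracle_gap <- function(x) {
  d <- dim(x)
  out <- matrix(0, d[1], d[2])
  for (n in seq_len(d[1])) for (c in seq_len(d[2]))
    out[n, c] <- mean(x[n, c, , ])
  out
}

oracle_channel_branch <- function(x, w1, b1) {
  d <- dim(x)
  s <- oracle_gap(x)
  y <- array(0, d)
  for (n in seq_len(d[1])) for (c in seq_len(d[2])) {
    g <- oracle_sigmoid(w1[c] * s[n, c] + b1[c])
    for (h in seq_len(d[3])) for (w in seq_len(d[4]))
      y[n, c, h, w] <- g * x[n, c, h, w]
  }
  y
}

# group norm over the whole half-group (all channels + pixels, per sample)
oracle_spatial_branch <- function(x, w2, b2, eps = 1e-5) {
  d <- dim(x)
  y <- array(0, d)
  for (n in seq_len(d[1])) {
    v <- as.vector(x[n, , , ])
    mu <- mean(v)
    va <- mean((v - mu)^2)
    for (c in seq_len(d[2])) for (h in seq_len(d[3])) for (w in seq_len(d[4])) {
      xn <- (x[n, c, h, w] - mu) / sqrt(va + eps)
      y[n, c, h, w] <- oracle_sigmoid(w2[c] * xn + b2[c]) * x[n, c, h, w]
    }
  }
  y
}

oracle_shuffle_attention <- function(x, G, w1, b1, w2, b2, eps = 1e-5,
                                     shuffle = TRUE) {
  d <- dim(x)
  C <- d[2]
  cg <- C / G; ch <- cg / 2
  y <- array(0, d)
  for (k in seq_len(G)) {
    chans <- (k - 1) * cg + seq_len(cg)
    half1 <- chans[seq_len(ch)]
    half2 <- chans[ch + seq_len(ch)]
    y[, half1, , ] <- oracle_channel_branch(x[, half1, , , drop = FALSE],
                                            w1, b1)
    y[, half2, , ] <- oracle_spatial_branch(x[, half2, , , drop = FALSE],
                                            w2, b2, eps)
  }
  if (shuffle && G > 1) {
    # reshape (G, C/G), transpose, flatten
    perm <- as.vector(matrix(seq_len(C), nrow = G, byrow = TRUE))
    y <- y[, perm, , , drop = FALSE]
  }
  y
}

oracle_eca <- function(x, w) {
  d <- dim(x)
  C <- d[2]
  k <- length(w); pad <- (k - 1) / 2
  s <- oracle_gap(x)
  y <- array(0, d)
  for (n in seq_len(d[1])) for (c in seq_len(C)) {
    t <- 0
    for (j in seq_len(k)) {
      src <- c + j - 1 - pad
      if (src >= 1 && src <= C) t <- t + w[j] * s[n, src]
    }
    g <- oracle_sigmoid(t)
    for (h in seq_len(d[3])) for (wd in seq_len(d[4]))
      y[n, c, h, wd] <- g * x[n, c, h, wd]
  }
  y
}

# same-padded 2-D convolution; w dims (kh, kw, c_in, f)
oracle_conv2d <- function(x, w, stride = 1) {
  d <- dim(x)
  kh <- dim(w)[1]; kw <- dim(w)[2]; f <- dim(w)[4]
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  ho <- ceiling(d[3] / stride); wo <- ceiling(d[4] / stride)
  y <- array(0, c(d[1], f, ho, wo))
  for (n in seq_len(d[1])) for (fo in seq_len(f))
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      acc <- 0
      for (c in seq_len(d[2])) for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
        hi <- (i - 1) * stride - ph + ki
        wi <- (j - 1) * stride - pw + kj
        if (hi >= 1 && hi <= d[3] && wi >= 1 && wi <= d[4])
          acc <- acc + x[n, c, hi, wi] * w[ki, kj, c, fo]
      }
      y[n, fo, i, j] <- acc
    }
  y
}

# batch norm with batch statistics (biased variance)
oracle_bn <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  y <- array(0, d)
  for (c in seq_len(d[2])) {
    v <- as.vector(x[, c, , ])
    mu <- mean(v)
    va <- mean((v - mu)^2)
    y[, c, , ] <- (x[, c, , ] - mu) / sqrt(va + eps) * gamma[c] + beta[c]
  }
  y
}

oracle_relu <- function(x) pmax(x, 0)

# the residual unit: y = relu(x) + eca(bn(conv1(relu(bn(conv3(x))))))
oracle_block1 <- function(x, p, eps = 1e-5) {
  h <- oracle_conv2d(x, p$conv3$w, 1)
  h <- oracle_bn(h, p$bn1$gamma, p$bn1$beta, eps)
  h <- oracle_relu(h)
  h <- oracle_conv2d(h, p$conv1$w, 1)
  h <- oracle_bn(h, p$bn2$gamma, p$bn2$beta, eps)
  h <- oracle_eca(h, p$eca$w)
  r <- oracle_relu(x)
  dim(r) <- dim(x)
  r + h
}

# per-pixel accumulation oracle for tile stitching
oracle_stitch <- function(tiles, full_shape) {
  acc <- matrix(0, full_shape[1], full_shape[2])
  cnt <- matrix(0, full_shape[1], full_shape[2])
  for (tl in tiles) {
    for (i in seq_len(nrow(tl$prob))) for (j in seq_len(ncol(tl$prob))) {
      r <- tl$row + i; c <- tl$col + j
      acc[r, c] <- acc[r, c] + tl$prob[i, j]
      cnt[r, c] <- cnt[r, c] + 1
    }
  }
  out <- acc / cnt
  out[cnt == 0] <- NA
  out
}
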