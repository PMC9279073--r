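# Feature-map convention
#
# A feature map is a real 4-D array indexed (batch, channel, height, width);
# this is the single user-facing layout for every function in the package.
# Internally the engine stores activations with physical dim (H, W, C, N) --
# byte-identical to a row-major NCHW tensor -- so that convolution columns
# are contiguous; conversion happens once at engine entry and exit.

#' Construct or validate a feature map
#'
#' A feature map is a numeric 4-D array in `(batch, channel, height, width)`
#' layout, the convention used throughout the package.
#'
#' @param x A numeric 4-D array, or a numeric vector together with `dim`.
#' @param dim Optional integer vector `c(batch, channel, height, width)`.
#' @return A numeric 4-D array of class feature map (plain array).
#' @examples
#' fm <- feature_map(rnorm(2 * 3 * 4 * 4), dim = c(2, 3, 4, 4))
#' dim(fm)
#' @export
feature_map <- function(x, dim = NULL) {
  if (!is.null(dim)) {
    stopifnot(length(dim) == 4L)
    x <- array(as.numeric(x), dim = as.integer(dim))
  }
  check_feature_map(x)
  x
}

check_feature_map <- function(x) {
  if (!is.numeric(x) || length(dim(x)) != 4L)
    stop("feature map must be a numeric 4-D array in (batch, channel, height, width) layout")
  if (any(dim(x) < 1L)) stop("all feature-map dimensions must be >= 1")
  invisible(x)
}

# (N,C,H,W) api layout -> (H,W,C,N) engine layout
nchw_to_hwcn <- function(x) aperm(x, c(3L, 4L, 2L, 1L))
# (H,W,C,N) engine layout -> (N,C,H,W) api layout
hwcn_to_nchw <- function(x) aperm(x, c(4L, 3L, 1L, 2L))

# logical dims of an engine tensor: double arrays carry them in `dim`,
# single-precision raw tensors in attribute `fdim`
tdim <- function(x) {
  d <- attr(x, "fdim", exact = TRUE)
  if (is.null(d)) dim(x) else d
}

to_float <- function(x) to_float_cpp(x, tdim(x))
from_float <- function(x) from_float_cpp(x, tdim(x))

# shape of an engine tensor reported in the api convention
hwcn_shape <- function(x) {
  d <- tdim(x)
  c(batch = d[4L], channel = d[3L], height = d[1L], width = d[2L])
}

# ---- broadcast helpers on (H,W,C,N) tensors -------------------------------

# multiply/add a per-channel vector v (length C) across all (h,w,n)
bc_chan <- function(v, H, W) rep(v, each = H * W)
# broadcast a (C x N) matrix across spatial positions
bc_cn <- function(g, H, W) rep(as.vector(g), each = H * W)

# per-channel sums over (H, W, N): returns length-C vector
csum <- function(x) {
  d <- dim(x)
  rowSums(colSums(x, dims = 2L))
}

# per-(channel, sample) sums over (H, W): returns C x N matrix
cnsum <- function(x) {
  s <- colSums(x, dims = 2L)
  if (is.null(dim(s))) s <- matrix(s, ncol = dim(x)[4L])
  s
}

sigmoid <- function(x) 1 / (1 + exp(-x))
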