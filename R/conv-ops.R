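# Thin R wrappers around the compiled convolution / pooling kernels, plus the
# layer-parameter constructors used by every block.

# 2-D convolution layer: kernel as a (k*k*in) x out matrix (row index runs
# kernel-row fastest, then kernel-col, then input channel), bias per output
# channel.  pad defaults to "same" for stride-1 dilated kernels.
conv2d_new <- function(in_channels, out_channels, k = 3L, dilation = 1L,
                       pad = dilation * (k - 1L) %/% 2L) {
  list(w = kaiming_uniform(k * k * in_channels, out_channels),
       b = numeric(out_channels),
       k = as.integer(k), pad = as.integer(pad), dil = as.integer(dilation),
       in_channels = as.integer(in_channels),
       out_channels = as.integer(out_channels))
}

conv2d_fwd <- function(p, x) {
  if (fm_channels(x) != p$in_channels)
    stop(sprintf("convolution expects %d input channels, got %d",
                 p$in_channels, fm_channels(x)), call. = FALSE)
  cpp_conv2d_fwd(x, p$w, p$b, p$k, p$pad, p$dil)
}

conv2d_bwd <- function(p, x, dy) {
  g <- cpp_conv2d_bwd(x, p$w, dy, p$k, p$pad, p$dil)
  list(dx = g$dx, grads = list(w = g$dw, b = as.numeric(g$db)))
}

# 1x1 convolution as a plain matrix product over the pixel lattice
conv1x1_new <- function(in_channels, out_channels) {
  list(w = kaiming_uniform(in_channels, out_channels),
       b = numeric(out_channels),
       in_channels = as.integer(in_channels),
       out_channels = as.integer(out_channels))
}

conv1x1_fwd <- function(p, x) {
  d <- dim(x)
  y <- matrix(x, d[1] * d[2], d[3]) %*% p$w
  y <- sweep(y, 2L, p$b, "+")
  array(y, c(d[1], d[2], ncol(p$w)))
}

conv1x1_bwd <- function(p, x, dy) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  dym <- matrix(dy, d[1] * d[2], dim(dy)[3])
  list(dx = array(dym %*% t(p$w), d),
       grads = list(w = crossprod(xm, dym), b = colSums(dym)))
}

#' Downsample a feature map with 2x2 max pooling
#'
#' Non-overlapping 2x2 windows, stride 2: spatial dimensions halve, the
#' channel count is unchanged. This is the downsampling step between encoder
#' stages.
#'
#' @param x Numeric 3-D array `(H, W, C)` with even `H` and `W`.
#' @return Array of dim `(H/2, W/2, C)`.
#' @export
max_pool_downsample <- function(x) {
  check_feature_map(x)
  cpp_maxpool2_fwd(x)$y
}

max_pool_fwd <- function(x) {
  r <- cpp_maxpool2_fwd(x)
  list(y = r$y, cache = r$idx)
}

max_pool_bwd <- function(cache, dy) cpp_maxpool2_bwd(dy, cache)

#' Upsample a feature map by nearest-neighbour interpolation
#'
#' Output pixel `(i, j)` (0-based) takes the value of source pixel
#' `(floor(i/scale), floor(j/scale))`; for integer scales this replicates each
#' source pixel into a `scale x scale` block. Channels are unchanged.
#'
#' @param x Numeric 3-D array `(H, W, C)`.
#' @param scale Positive integer magnification factor.
#' @return Array of dim `(H*scale, W*scale, C)`.
#' @export
nearest_upsample <- function(x, scale) {
  check_feature_map(x)
  if (length(scale) != 1L || scale < 1 || scale != round(scale))
    stop("`scale` must be a positive integer", call. = FALSE)
  scale <- as.integer(scale)
  if (scale == 1L) return(x)
  d <- dim(x)
  x[rep(seq_len(d[1]), each = scale), rep(seq_len(d[2]), each = scale), , drop = FALSE]
}

# adjoint: sum gradient over each scale x scale block
nearest_upsample_bwd <- function(dy, scale) {
  if (scale == 1L) return(dy)
  d <- dim(dy)
  H <- d[1] %/% scale; W <- d[2] %/% scale
  dx <- array(0, c(H, W, d[3]))
  for (oi in seq_len(scale)) for (oj in seq_len(scale)) {
    dx <- dx + dy[seq(oi, d[1], by = scale), seq(oj, d[2], by = scale), , drop = FALSE]
  }
  dx
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(x_pre, dy) dy * (x_pre > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

global_avg_pool <- function(x) apply(x, 3L, mean)
global_avg_pool_bwd <- function(dvec, H, W, C) {
  array(rep(dvec / (H * W), each = H * W), c(H, W, C))
}
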