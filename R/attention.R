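# Dual attention gate on the skip connections: a per-pixel spatial coefficient
# alpha and a squeeze-excitation style per-channel coefficient beta, both in
# (0,1), multiply the skip feature map before concatenation with the decoder
# feature.

#' Attention-gate parameters
#'
#' The gate combines two branches. The spatial branch computes a one-channel
#' coefficient map `alpha = sigmoid(W2(relu(Wx x + Wg g)))` from 1x1
#' convolutions `Wx: F_l -> F_int`, `Wg: F_g -> F_int`, `W2: F_int -> 1`. The
#' channel branch global-average-pools both inputs and computes a per-channel
#' vector `beta = sigmoid(W1(W0(relu(pool(x) + pool(g)))))` through a
#' bottleneck of width `F_g / reduction`. Here the gating signal `g` is the
#' decoder feature after up-convolution, so `F_l == F_g` and both inputs share
#' the same resolution.
#'
#' By default the channel branch applies the operators in the order written
#' above (ReLU on the pooled sum, then the two linear maps back to back);
#' `se_order = TRUE` switches to the conventional squeeze-excitation ordering
#' `W1(relu(W0(.)))`.
#'
#' @param channels Channels of both the skip feature and the gating feature.
#' @param reduction Channel-branch bottleneck divisor (default 16); capped at
#'   `channels` for narrow test-scale networks and required to divide it.
#' @param f_int Intermediate width of the spatial branch; default
#'   `max(channels / 2, 1)`.
#' @param se_order Use the squeeze-excitation operator ordering in the channel
#'   branch instead of the default.
#' @return Parameter list for [attention_gate_forward()].
#' @export
attention_gate_params <- function(channels, reduction = 16L, f_int = NULL,
                                  se_order = FALSE) {
  channels <- as.integer(channels)
  reduction <- min(as.integer(reduction), channels)
  if (channels %% reduction != 0L)
    stop(sprintf("channels (%d) not divisible by reduction (%d)",
                 channels, reduction), call. = FALSE)
  f_int <- as.integer(f_int %||% max(channels %/% 2L, 1L))
  list(Wx = conv1x1_new(channels, f_int),
       Wg = conv1x1_new(channels, f_int),
       W2 = conv1x1_new(f_int, 1L),
       W0 = conv1x1_new(channels, channels %/% reduction),
       W1 = conv1x1_new(channels %/% reduction, channels),
       channels = channels, f_int = f_int, reduction = reduction,
       se_order = isTRUE(se_order))
}

check_gate_inputs <- function(x, g, p) {
  check_feature_map(x, "x"); check_feature_map(g, "g")
  if (!all(dim(x)[1:2] == dim(g)[1:2]))
    stop(sprintf("x (%dx%d) and g (%dx%d) must share spatial dimensions",
                 dim(x)[1], dim(x)[2], dim(g)[1], dim(g)[2]), call. = FALSE)
  if (fm_channels(x) != p$channels || fm_channels(g) != p$channels)
    stop(sprintf("gate built for %d channels; got x: %d, g: %d",
                 p$channels, fm_channels(x), fm_channels(g)), call. = FALSE)
}

#' Spatial attention coefficient
#'
#' @param x Skip feature map `(H, W, C)`.
#' @param g Gating feature map, same shape.
#' @param p Parameters from [attention_gate_params()].
#' @return One-channel array `(H, W, 1)` of coefficients in (0, 1).
#' @export
spatial_attention <- function(x, g, p) {
  check_gate_inputs(x, g, p)
  spatial_attention_fwd(x, g, p)$alpha
}

spatial_attention_fwd <- function(x, g, p) {
  s <- conv1x1_fwd(p$Wx, x) + conv1x1_fwd(p$Wg, g)
  q <- relu_fwd(s)
  logit <- conv1x1_fwd(p$W2, q)
  alpha <- sigmoid(logit)
  list(alpha = alpha, cache = list(x = x, g = g, s = s, q = q, alpha = alpha))
}

spatial_attention_bwd <- function(p, cache, dalpha) {
  dlogit <- dalpha * cache$alpha * (1 - cache$alpha)
  w2 <- conv1x1_bwd(p$W2, cache$q, dlogit)
  dq <- relu_bwd(cache$s, w2$dx)
  wx <- conv1x1_bwd(p$Wx, cache$x, dq)
  wg <- conv1x1_bwd(p$Wg, cache$g, dq)
  list(dx = wx$dx, dg = wg$dx,
       grads = list(Wx = wx$grads, Wg = wg$grads, W2 = w2$grads))
}

#' Channel attention coefficient
#'
#' @inheritParams spatial_attention
#' @return Numeric vector of length `C` with entries in (0, 1).
#' @export
channel_attention <- function(x, g, p) {
  check_gate_inputs(x, g, p)
  channel_attention_fwd(x, g, p)$beta
}

channel_attention_fwd <- function(x, g, p) {
  pooled <- global_avg_pool(x) + global_avg_pool(g)
  if (p$se_order) {
    z0pre <- as.numeric(crossprod(p$W0$w, pooled)) + p$W0$b
    h <- relu_fwd(z0pre)
    z1 <- as.numeric(crossprod(p$W1$w, h)) + p$W1$b
    cache <- list(x = x, g = g, pooled = pooled, z0pre = z0pre, h = h)
  } else {
    h <- relu_fwd(pooled)
    z0 <- as.numeric(crossprod(p$W0$w, h)) + p$W0$b
    z1 <- as.numeric(crossprod(p$W1$w, z0)) + p$W1$b
    cache <- list(x = x, g = g, pooled = pooled, h = h, z0 = z0)
  }
  beta <- sigmoid(z1)
  cache$beta <- beta
  list(beta = beta, cache = cache)
}

channel_attention_bwd <- function(p, cache, dbeta) {
  dz1 <- dbeta * cache$beta * (1 - cache$beta)
  d <- dim(cache$x)
  if (p$se_order) {
    dW1 <- list(w = outer(cache$h, dz1), b = dz1)
    dh <- as.numeric(p$W1$w %*% dz1)
    dz0pre <- relu_bwd(cache$z0pre, dh)
    dW0 <- list(w = outer(cache$pooled, dz0pre), b = dz0pre)
    dpool <- as.numeric(p$W0$w %*% dz0pre)
  } else {
    dW1 <- list(w = outer(cache$z0, dz1), b = dz1)
    dz0 <- as.numeric(p$W1$w %*% dz1)
    dW0 <- list(w = outer(cache$h, dz0), b = dz0)
    dh <- as.numeric(p$W0$w %*% dz0)
    dpool <- relu_bwd(cache$pooled, dh)
  }
  dmap <- global_avg_pool_bwd(dpool, d[1], d[2], d[3])
  list(dx = dmap, dg = dmap, grads = list(W0 = dW0, W1 = dW1))
}

#' Apply the dual attention gate
#'
#' The gated skip feature is `alpha * beta * x`: the spatial map `alpha`
#' broadcast over channels and the channel vector `beta` broadcast over
#' pixels, so every output entry is bounded by the corresponding `|x|`.
#'
#' @inheritParams spatial_attention
#' @return Feature map of the same shape as `x`.
#' @export
attention_gate_forward <- function(x, g, p) {
  check_gate_inputs(x, g, p)
  attention_gate_fwd(x, g, p)$y
}

attention_gate_fwd <- function(x, g, p) {
  sa <- spatial_attention_fwd(x, g, p)
  ca <- channel_attention_fwd(x, g, p)
  d <- dim(x)
  npix <- d[1] * d[2]
  coef <- array(as.vector(sa$alpha) * rep(ca$beta, each = npix), d)
  y <- x * coef
  list(y = y,
       cache = list(x = x, sa = sa$cache, ca = ca$cache,
                    alpha = sa$alpha, beta = ca$beta, coef = coef))
}

attention_gate_bwd <- function(p, cache, dy) {
  d <- dim(cache$x)
  npix <- d[1] * d[2]
  dx_direct <- dy * cache$coef
  # d/dalpha: sum over channels of dy * beta * x
  weighted <- dy * cache$x
  dalpha_map <- array(0, c(d[1], d[2], 1L))
  for (c in seq_len(d[3]))
    dalpha_map[, , 1L] <- dalpha_map[, , 1L] + weighted[, , c] * cache$beta[c]
  # d/dbeta_c: sum over pixels of dy * alpha * x
  alph <- cache$alpha[, , 1L]
  dbeta <- vapply(seq_len(d[3]),
                  function(c) sum(weighted[, , c] * alph), numeric(1))
  sb <- spatial_attention_bwd(p, cache$sa, dalpha_map)
  cb <- channel_attention_bwd(p, cache$ca, dbeta)
  list(dx = dx_direct + sb$dx + cb$dx,
       dg = sb$dg + cb$dg,
       grads = list(Wx = sb$grads$Wx, Wg = sb$grads$Wg, W2 = sb$grads$W2,
                    W0 = cb$grads$W0, W1 = cb$grads$W1))
}

# saturate the gate open: alpha ~ 1, beta ~ 1 regardless of input
open_gate_params <- function(p, bias = 20) {
  p$W2$w[] <- 0; p$W2$b[] <- bias
  p$W1$w[] <- 0; p$W1$b[] <- bias
  p
}
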