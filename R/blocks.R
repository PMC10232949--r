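# Building blocks of the network: group normalization, the two-conv GN/ReLU
# block (with optional channel dropout in the bottleneck variant), the
# nearest-neighbour up-convolution block, and the ASPP bottleneck.

#' Group-normalization parameters
#'
#' Group normalization divides the channels of one sample into groups and
#' standardizes each group by its own mean and variance, so the statistics do
#' not depend on the batch — the reason it behaves well at the small batch
#' sizes typical of segmentation training.
#'
#' When `num_groups` is `NULL` the default of 8 groups is used, falling back
#' to a single group (layer normalization over channels) when there are fewer
#' than 8 channels.
#'
#' @param channels Number of channels the layer normalizes.
#' @param num_groups Number of channel groups; must divide `channels`.
#' @param epsilon Variance floor added before the square root.
#' @param gamma,beta Per-channel scale and shift (learnable); default 1 and 0.
#' @return A parameter list usable with [group_normalize()].
#' @export
gn_params <- function(channels, num_groups = NULL, epsilon = 1e-5,
                      gamma = rep(1, channels), beta = rep(0, channels)) {
  if (is.null(num_groups)) num_groups <- if (channels < 8L) 1L else 8L
  num_groups <- as.integer(num_groups)
  if (channels %% num_groups != 0L)
    stop(sprintf("channels (%d) not divisible by num_groups (%d)",
                 channels, num_groups), call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)
  stopifnot(length(gamma) == channels, length(beta) == channels)
  list(num_groups = num_groups, gamma = as.numeric(gamma),
       beta = as.numeric(beta), epsilon = epsilon,
       channels = as.integer(channels))
}

# pick a valid group count for a given width (default policy, see gn_params)
gn_groups_for <- function(channels, requested = 8L) {
  if (channels < requested) return(1L)
  g <- as.integer(requested)
  while (channels %% g != 0L) g <- g - 1L
  g
}

#' Apply group normalization to a feature map
#'
#' Per channel group, the output is
#' `(x - mean) / sqrt(var + epsilon) * gamma + beta`, with mean and (population)
#' variance computed over all pixels and channels of the group for this single
#' sample.
#'
#' @param x Numeric 3-D array `(H, W, C)`.
#' @param p Parameters from [gn_params()]; `p$channels` must equal `dim(x)[3]`.
#' @return Array of the same shape as `x`.
#' @export
group_normalize <- function(x, p) {
  gn_fwd(x, p)$y
}

gn_fwd <- function(x, p) {
  check_feature_map(x)
  d <- dim(x)
  C <- d[3]
  if (C %% p$num_groups != 0L)
    stop(sprintf("channels (%d) not divisible by num_groups (%d)",
                 C, p$num_groups), call. = FALSE)
  gsize <- C %/% p$num_groups
  xhat <- x
  sds <- numeric(p$num_groups)
  for (g in seq_len(p$num_groups)) {
    ch <- ((g - 1L) * gsize + 1L):(g * gsize)
    v <- x[, , ch, drop = FALSE]
    mu <- mean(v)
    va <- mean((v - mu)^2)          # population variance
    sds[g] <- sqrt(va + p$epsilon)
    xhat[, , ch] <- (v - mu) / sds[g]
  }
  scale <- rep(p$gamma, each = d[1] * d[2])
  shift <- rep(p$beta, each = d[1] * d[2])
  y <- array(as.vector(xhat) * scale + shift, d)
  list(y = y, cache = list(xhat = xhat, sds = sds, gsize = gsize, p = p))
}

gn_bwd <- function(cache, dy) {
  p <- cache$p
  xhat <- cache$xhat
  d <- dim(xhat)
  npix <- d[1] * d[2]
  dgamma <- numeric(p$channels)
  dbeta <- numeric(p$channels)
  for (c in seq_len(p$channels)) {
    dgamma[c] <- sum(dy[, , c] * xhat[, , c])
    dbeta[c] <- sum(dy[, , c])
  }
  dxhat <- array(as.vector(dy) * rep(p$gamma, each = npix), d)
  dx <- dxhat
  for (g in seq_len(p$num_groups)) {
    ch <- ((g - 1L) * cache$gsize + 1L):(g * cache$gsize)
    dh <- dxhat[, , ch, drop = FALSE]
    xh <- xhat[, , ch, drop = FALSE]
    m1 <- mean(dh)
    m2 <- mean(dh * xh)
    dx[, , ch] <- (dh - m1 - xh * m2) / cache$sds[g]
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

#' Convolution-block parameters
#'
#' A block is two rounds of (3x3 convolution, same padding, then group
#' normalization, then ReLU). The bottleneck variant (`with_dropout = TRUE`)
#' appends channel dropout with `dropout_p = 0.5` after the second activation
#' to curb overfitting in the deepest encoder stage.
#'
#' @param in_channels,out_channels Channel widths.
#' @param with_dropout Append channel dropout after the second ReLU?
#' @param dropout_p Dropout probability (0.5 for the bottleneck block).
#' @param gn_groups Requested group count for the block's GN layers.
#' @return Parameter list for [conv_block_forward()].
#' @export
conv_block_params <- function(in_channels, out_channels, with_dropout = FALSE,
                              dropout_p = 0.5, gn_groups = 8L) {
  list(conv1 = conv2d_new(in_channels, out_channels),
       gn1 = gn_params(out_channels, gn_groups_for(out_channels, gn_groups)),
       conv2 = conv2d_new(out_channels, out_channels),
       gn2 = gn_params(out_channels, gn_groups_for(out_channels, gn_groups)),
       with_dropout = isTRUE(with_dropout),
       dropout_p = dropout_p,
       in_channels = as.integer(in_channels),
       out_channels = as.integer(out_channels))
}

#' Run a convolution block
#'
#' @param x Feature map `(H, W, C)` with `C == p$in_channels`.
#' @param p Parameters from [conv_block_params()].
#' @param training When `TRUE` and the block carries dropout, channel dropout
#'   is sampled (inverted scaling); otherwise dropout is the identity.
#' @return Feature map `(H, W, out_channels)`.
#' @export
conv_block_forward <- function(x, p, training = FALSE) {
  conv_block_fwd(x, p, training)$y
}

conv_block_fwd <- function(x, p, training = FALSE) {
  check_feature_map(x)
  pre1 <- conv2d_fwd(p$conv1, x)
  g1 <- gn_fwd(pre1, p$gn1)
  a1 <- relu_fwd(g1$y)
  pre2 <- conv2d_fwd(p$conv2, a1)
  g2 <- gn_fwd(pre2, p$gn2)
  a2 <- relu_fwd(g2$y)
  mask <- NULL
  y <- a2
  if (p$with_dropout && training) {
    # channel (spatial) dropout with inverted scaling
    keep <- stats::runif(dim(a2)[3]) >= p$dropout_p
    mask <- as.numeric(keep) / (1 - p$dropout_p)
    y <- array(as.vector(a2) * rep(mask, each = dim(a2)[1] * dim(a2)[2]), dim(a2))
  }
  list(y = y,
       cache = list(x = x, a1 = a1, g1y = g1$y, g2y = g2$y,
                    gn1 = g1$cache, gn2 = g2$cache, mask = mask))
}

conv_block_bwd <- function(p, cache, dy) {
  if (!is.null(cache$mask)) {
    d <- dim(dy)
    dy <- array(as.vector(dy) * rep(cache$mask, each = d[1] * d[2]), d)
  }
  dy <- relu_bwd(cache$g2y, dy)
  b2 <- gn_bwd(cache$gn2, dy)
  c2 <- conv2d_bwd(p$conv2, cache$a1, b2$dx)
  dy1 <- relu_bwd(cache$g1y, c2$dx)
  b1 <- gn_bwd(cache$gn1, dy1)
  c1 <- conv2d_bwd(p$conv1, cache$x, b1$dx)
  list(dx = c1$dx,
       grads = list(conv1 = c1$grads, gn1 = b1$grads,
                    conv2 = c2$grads, gn2 = b2$grads))
}

#' Up-convolution block parameters
#'
#' Nearest-neighbour 2x upsampling followed by one (3x3 conv, GN, ReLU) that
#' halves the channel count, so the result matches the width of the skip
#' connection at that decoder scale.
#'
#' @param in_channels Incoming channels; must be even.
#' @param gn_groups Requested GN group count.
#' @return Parameter list for [upconv_block_forward()].
#' @export
upconv_block_params <- function(in_channels, gn_groups = 8L) {
  if (in_channels %% 2L != 0L)
    stop(sprintf("up-conv block needs an even channel count, got %d", in_channels),
         call. = FALSE)
  out <- in_channels %/% 2L
  list(conv = conv2d_new(in_channels, out),
       gn = gn_params(out, gn_groups_for(out, gn_groups)),
       in_channels = as.integer(in_channels), out_channels = out)
}

#' Run an up-convolution block
#'
#' @param x Feature map `(H, W, C)`, `C` even.
#' @param p Parameters from [upconv_block_params()].
#' @return Feature map `(2H, 2W, C/2)`.
#' @export
upconv_block_forward <- function(x, p) {
  upconv_block_fwd(x, p)$y
}

upconv_block_fwd <- function(x, p) {
  check_feature_map(x)
  up <- nearest_upsample(x, 2L)
  pre <- conv2d_fwd(p$conv, up)
  g <- gn_fwd(pre, p$gn)
  y <- relu_fwd(g$y)
  list(y = y, cache = list(up = up, gy = g$y, gn = g$cache))
}

upconv_block_bwd <- function(p, cache, dy) {
  dy <- relu_bwd(cache$gy, dy)
  b <- gn_bwd(cache$gn, dy)
  cv <- conv2d_bwd(p$conv, cache$up, b$dx)
  list(dx = nearest_upsample_bwd(cv$dx, 2L),
       grads = list(conv = cv$grads, gn = b$grads))
}

#' ASPP configuration
#'
#' Atrous spatial pyramid pooling: parallel 3x3 convolutions with different
#' dilation rates see the same input at several receptive-field sizes without
#' losing resolution; their outputs are concatenated and fused by a 1x1
#' convolution.
#'
#' @param in_channels,out_channels Channel widths (defaults keep the width).
#' @param dilation_rates Ordered dilation rates, default `c(1, 6, 12, 18)`.
#' @param gn_groups Requested GN group count for the branch normalizations.
#' @return An `aspp_config` list.
#' @export
aspp_config <- function(in_channels, out_channels = in_channels,
                        dilation_rates = c(1L, 6L, 12L, 18L), gn_groups = 8L) {
  if (any(dilation_rates < 1)) stop("dilation rates must be positive", call. = FALSE)
  if (in_channels %% length(dilation_rates) != 0L)
    stop(sprintf("in_channels (%d) must be divisible by the branch count (%d)",
                 in_channels, length(dilation_rates)), call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 dilation_rates = as.integer(dilation_rates),
                 branch_channels = as.integer(in_channels %/% length(dilation_rates)),
                 gn_groups = as.integer(gn_groups)),
            class = "aspp_config")
}

#' ASPP parameters
#'
#' One 3x3 dilated convolution (padding = rate, so spatial size is preserved)
#' plus GN + ReLU per branch, then a 1x1 fusion convolution from the
#' concatenated branches to `out_channels`.
#'
#' @param cfg An [aspp_config()].
#' @return Parameter list for [aspp_forward()].
#' @export
aspp_params <- function(cfg) {
  stopifnot(inherits(cfg, "aspp_config"))
  branches <- lapply(cfg$dilation_rates, function(r) {
    list(conv = conv2d_new(cfg$in_channels, cfg$branch_channels, dilation = r),
         gn = gn_params(cfg$branch_channels,
                        gn_groups_for(cfg$branch_channels, cfg$gn_groups)))
  })
  list(branches = branches,
       fuse = conv1x1_new(cfg$branch_channels * length(cfg$dilation_rates),
                          cfg$out_channels),
       cfg = cfg)
}

#' Run the ASPP module
#'
#' @param x Feature map `(H, W, C)` with `C == cfg$in_channels`.
#' @param p Parameters from [aspp_params()].
#' @return Feature map `(H, W, cfg$out_channels)`.
#' @export
aspp_forward <- function(x, p) {
  aspp_fwd(x, p)$y
}

aspp_fwd <- function(x, p) {
  check_feature_map(x)
  if (fm_channels(x) != p$cfg$in_channels)
    stop(sprintf("ASPP expects %d channels, got %d",
                 p$cfg$in_channels, fm_channels(x)), call. = FALSE)
  bcaches <- vector("list", length(p$branches))
  outs <- vector("list", length(p$branches))
  for (i in seq_along(p$branches)) {
    br <- p$branches[[i]]
    pre <- conv2d_fwd(br$conv, x)
    g <- gn_fwd(pre, br$gn)
    outs[[i]] <- relu_fwd(g$y)
    bcaches[[i]] <- list(gy = g$y, gn = g$cache)
  }
  cat_map <- array(unlist(outs), c(dim(x)[1], dim(x)[2],
                                   p$cfg$branch_channels * length(outs)))
  y <- conv1x1_fwd(p$fuse, cat_map)
  list(y = y, cache = list(x = x, bcaches = bcaches, cat_map = cat_map))
}

aspp_bwd <- function(p, cache, dy) {
  fu <- conv1x1_bwd(p$fuse, cache$cat_map, dy)
  bc <- p$cfg$branch_channels
  dx <- array(0, dim(cache$x))
  bgrads <- vector("list", length(p$branches))
  for (i in seq_along(p$branches)) {
    ch <- ((i - 1L) * bc + 1L):(i * bc)
    dyi <- relu_bwd(cache$bcaches[[i]]$gy, fu$dx[, , ch, drop = FALSE])
    g <- gn_bwd(cache$bcaches[[i]]$gn, dyi)
    cv <- conv2d_bwd(p$branches[[i]]$conv, cache$x, g$dx)
    dx <- dx + cv$dx
    bgrads[[i]] <- list(conv = cv$grads, gn = g$grads)
  }
  list(dx = dx, grads = list(branches = bgrads, fuse = fu$grads))
}
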