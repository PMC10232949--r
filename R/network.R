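# The full encoder-decoder network: five GN conv blocks and four max-pools
# down, an ASPP bottleneck, then four (up-conv, attention gate, concatenate)
# scales up, with conv blocks after the first three concatenations and a 1x1
# output convolution after the last.

#' Network configuration
#'
#' Encoder widths double per stage: `base, 2b, 4b, 8b, 16b` with four 2x
#' downsamplings, so inputs must have height and width divisible by 16. The
#' output has one channel per zone (peripheral zone then transition zone by
#' default), trained with per-channel sigmoid + BCE-dice rather than a softmax
#' over classes.
#'
#' @param in_channels Image channels (1 = T2-only, 2 = T2 + ADC).
#' @param num_classes Output channels, one per zone.
#' @param base_channels Width of the first encoder stage (64 at full scale;
#'   8 is convenient for CPU-scale work).
#' @param gn_groups Requested GN group count (per-layer fallback for narrow
#'   layers, see [gn_params()]).
#' @param aspp_rates Dilation rates of the ASPP bottleneck.
#' @param dropout_p Dropout probability of the fifth (bottleneck) conv block.
#' @param reduction Attention-gate channel-bottleneck divisor.
#' @param se_order Use squeeze-excitation operator order in the channel
#'   attention branch (see [attention_gate_params()]).
#' @return A `masunet_config` object.
#' @export
masunet_config <- function(in_channels = 1L, num_classes = 2L,
                           base_channels = 64L, gn_groups = 8L,
                           aspp_rates = c(1L, 6L, 12L, 18L), dropout_p = 0.5,
                           reduction = 16L, se_order = FALSE) {
  stopifnot(in_channels >= 1, num_classes >= 1, base_channels >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 base_channels = as.integer(base_channels),
                 depth = 4L,
                 gn_groups = as.integer(gn_groups),
                 aspp_rates = as.integer(aspp_rates),
                 dropout_p = dropout_p,
                 reduction = as.integer(reduction),
                 se_order = isTRUE(se_order)),
            class = "masunet_config")
}

#' Build the network
#'
#' Parameter initialization (Kaiming-uniform kernels, GN gamma = 1, beta = 0)
#' is fully determined by `seed`: the same configuration and seed always give
#' bitwise-identical parameters.
#'
#' @param cfg A [masunet_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `masunet` object.
#' @export
build_masunet <- function(cfg = masunet_config(), seed = 1L) {
  stopifnot(inherits(cfg, "masunet_config"))
  b <- cfg$base_channels
  widths <- b * c(1L, 2L, 4L, 8L, 16L)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  g <- cfg$gn_groups
  enc <- list(
    conv_block_params(cfg$in_channels, widths[1], gn_groups = g),
    conv_block_params(widths[1], widths[2], gn_groups = g),
    conv_block_params(widths[2], widths[3], gn_groups = g),
    conv_block_params(widths[3], widths[4], gn_groups = g),
    conv_block_params(widths[4], widths[5], with_dropout = TRUE,
                      dropout_p = cfg$dropout_p, gn_groups = g))
  aspp <- aspp_params(aspp_config(widths[5], widths[5],
                                  dilation_rates = cfg$aspp_rates, gn_groups = g))
  up <- list(); ag <- list(); dec <- list()
  for (s in 1:4) {
    up[[s]] <- upconv_block_params(widths[6 - s], gn_groups = g)   # -> widths[5-s]
    ag[[s]] <- attention_gate_params(widths[5 - s], reduction = cfg$reduction,
                                     se_order = cfg$se_order)
    if (s <= 3)
      dec[[s]] <- conv_block_params(2L * widths[5 - s], widths[5 - s], gn_groups = g)
  }
  out <- conv1x1_new(2L * widths[1], cfg$num_classes)
  structure(list(cfg = cfg, seed = as.integer(seed),
                 params = list(enc = enc, aspp = aspp, up = up, ag = ag,
                               dec = dec, out = out)),
            class = "masunet")
}

#' @export
print.masunet <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("<masunet> base %d, in %d, classes %d, ",
                     "ASPP rates %s, %s parameters (seed %d)\n"),
              cfg$base_channels, cfg$in_channels, cfg$num_classes,
              paste(cfg$aspp_rates, collapse = "/"),
              format(n_parameters(x), big.mark = ","), x$seed))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param net A `masunet` object.
#' @return Total number of trainable scalars (kernels, biases, GN gamma/beta).
#' @export
n_parameters <- function(net) {
  param_reduce(length, net$params)
}

check_forward_input <- function(net, x) {
  check_feature_map(x)
  d <- dim(x)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop(sprintf("input height/width must be divisible by 16 (four 2x poolings); got %dx%d",
                 d[1], d[2]), call. = FALSE)
  if (d[3] != net$cfg$in_channels)
    stop(sprintf("network expects %d input channels, got %d",
                 net$cfg$in_channels, d[3]), call. = FALSE)
}

concat_channels <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

#' Forward pass
#'
#' Runs the encoder (conv blocks with max-pool downsampling, then ASPP), and
#' the decoder (up-conv, attention-gated skip, concatenation, conv block at
#' the first three scales; 1x1 output convolution at the last). Returns raw
#' per-class logits; apply `sigmoid` (or [predict_masks()]) for probabilities.
#'
#' @param net A `masunet` object.
#' @param x Input feature map `(H, W, in_channels)`, `H`, `W` divisible by 16.
#' @param training Sample bottleneck dropout? (`FALSE` = deterministic eval).
#' @param gate_mode `"attention"` (default) applies the attention gates;
#'   `"identity"` passes skip features through untouched, giving the plain
#'   gate-free U-Net with otherwise identical weights.
#' @return Logit map `(H, W, num_classes)`.
#' @export
masunet_forward <- function(net, x, training = FALSE,
                            gate_mode = c("attention", "identity")) {
  masunet_fwd(net, x, training, match.arg(gate_mode))$y
}

masunet_fwd <- function(net, x, training = FALSE, gate_mode = "attention") {
  check_forward_input(net, x)
  p <- net$params
  skips <- list(); ecaches <- list(); pcaches <- list()
  h <- x
  for (s in 1:5) {
    cb <- conv_block_fwd(h, p$enc[[s]], training = training)
    ecaches[[s]] <- cb$cache
    if (s < 5) {
      skips[[s]] <- cb$y
      mp <- max_pool_fwd(cb$y)
      pcaches[[s]] <- mp$cache
      h <- mp$y
    } else h <- cb$y
  }
  asp <- aspp_fwd(h, p$aspp)
  h <- asp$y
  dcaches <- list()
  for (s in 1:4) {
    uc <- upconv_block_fwd(h, p$up[[s]])
    g <- uc$y
    skip <- skips[[5 - s]]
    if (gate_mode == "attention") {
      agf <- attention_gate_fwd(skip, g, p$ag[[s]])
      gated <- agf$y
      agc <- agf$cache
    } else {
      gated <- skip
      agc <- NULL
    }
    cc <- concat_channels(gated, g)
    if (s <= 3) {
      db <- conv_block_fwd(cc, p$dec[[s]], training = training)
      h <- db$y
      dcaches[[s]] <- list(up = uc$cache, ag = agc, cat = cc, dec = db$cache,
                           nch = dim(gated)[3])
    } else {
      y <- conv1x1_fwd(p$out, cc)
      dcaches[[s]] <- list(up = uc$cache, ag = agc, cat = cc,
                           nch = dim(gated)[3])
      return(list(y = y,
                  cache = list(ecaches = ecaches, pcaches = pcaches,
                               aspp = asp$cache, dcaches = dcaches,
                               gate_mode = gate_mode)))
    }
  }
}

# Full backward pass; returns gradients mirroring net$params (dx is discarded
# at the input). dy: gradient of the loss w.r.t. the logits.
masunet_bwd <- function(net, cache, dy) {
  p <- net$params
  gmode <- cache$gate_mode
  genc <- vector("list", 5); gdec <- vector("list", 3)
  gup <- vector("list", 4); gag <- vector("list", 4)
  dskip_acc <- vector("list", 4)   # gradients flowing back into skips[s]

  # scale 4: output conv
  d4 <- cache$dcaches[[4]]
  oc <- conv1x1_bwd(p$out, d4$cat, dy)
  gout <- oc$grads
  dcat <- oc$dx
  for (s in 4:1) {
    dc <- cache$dcaches[[s]]
    if (s < 4) {
      db <- conv_block_bwd(p$dec[[s]], dc$dec, dcat_next)
      gdec[[s]] <- db$grads
      dcat <- db$dx
    }
    nch <- dc$nch
    dgated <- dcat[, , seq_len(nch), drop = FALSE]
    dg <- dcat[, , nch + seq_len(dim(dcat)[3] - nch), drop = FALSE]
    if (gmode == "attention") {
      ab <- attention_gate_bwd(p$ag[[s]], dc$ag, dgated)
      gag[[s]] <- ab$grads
      dskip <- ab$dx
      dg <- dg + ab$dg
    } else {
      gag[[s]] <- zero_grads(p$ag[[s]])
      dskip <- dgated
    }
    dskip_acc[[5 - s]] <- dskip
    ub <- upconv_block_bwd(p$up[[s]], dc$up, dg)
    gup[[s]] <- ub$grads
    if (s > 1) dcat_next <- ub$dx else dbot <- ub$dx
  }
  ab <- aspp_bwd(p$aspp, cache$aspp, dbot)
  gaspp <- ab$grads
  dh <- ab$dx
  for (s in 5:1) {
    cb <- conv_block_bwd(p$enc[[s]], cache$ecaches[[s]], dh)
    genc[[s]] <- cb$grads
    if (s > 1) {
      dpool <- max_pool_bwd(cache$pcaches[[s - 1]], cb$dx)
      dh <- dpool + dskip_acc[[s - 1]]
    }
  }
  list(enc = genc, aspp = gaspp, up = gup, ag = gag, dec = gdec, out = gout)
}

# gradient tree of zeros shaped like a parameter tree (used for ungated passes)
zero_grads <- function(p) {
  if (!is.list(p)) return(NULL)
  nms <- names(p) %||% rep("", length(p))
  out <- list()
  for (i in seq_along(p)) {
    if (nms[i] %in% PARAM_LEAVES && is.numeric(p[[i]])) {
      z <- p[[i]]; z[] <- 0
      out[[nms[i]]] <- z
    } else if (is.list(p[[i]])) {
      sub <- zero_grads(p[[i]])
      if (length(sub)) {
        if (nzchar(nms[i])) out[[nms[i]]] <- sub else out[[length(out) + 1L]] <- sub
      }
    }
  }
  out
}

#' Predict per-class masks for one slice
#'
#' Applies the network in eval mode, sigmoid-transforms the logits, and
#' thresholds each class channel. Because the channels are independent
#' sigmoids the raw masks may overlap; the returned `label` map resolves
#' overlaps by assigning the class with the higher probability (codes: 0
#' background, 1 first class/PZ, 2 second class/TZ).
#'
#' @param net A `masunet` object.
#' @param x Input feature map `(H, W, in_channels)`.
#' @param threshold Probability threshold in (0, 1), default 0.5.
#' @return List with `probs` `(H, W, K)`, binary `masks` `(H, W, K)`, and the
#'   overlap-resolved integer `label` matrix.
#' @export
predict_masks <- function(net, x, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  probs <- sigmoid(masunet_forward(net, x, training = FALSE))
  masks <- (probs > threshold) * 1
  d <- dim(probs)
  best <- apply(probs, c(1, 2), which.max)
  any_on <- apply(masks, c(1, 2), max) > 0
  label <- matrix(0L, d[1], d[2])
  label[any_on] <- best[any_on]
  list(probs = probs, masks = masks, label = label)
}
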