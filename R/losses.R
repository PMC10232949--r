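# Training losses: the pixel-wise softmax field with weighted cross-entropy
# (the classic U-Net energy), and the BCE + soft-dice compound loss actually
# used for training the two sigmoid zone channels.

#' Pixel-wise softmax field
#'
#' Converts per-class activation maps into per-class probability maps with a
#' numerically stable (max-subtracted) softmax at each pixel, so the
#' probabilities sum to one at every position.
#'
#' @param a Numeric 3-D array `(H, W, K)` of per-class activations.
#' @return Array of the same shape with `sum over K == 1` at each pixel.
#' @export
softmax_field <- function(a) {
  check_feature_map(a, "a")
  if (any(!is.finite(a))) stop("activations must be finite", call. = FALSE)
  d <- dim(a)
  m <- matrix(a, d[1] * d[2], d[3])
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  array(e / rowSums(e), d)
}

#' Weighted cross-entropy over a softmax field
#'
#' `E = -sum_x w(x) * log p_{l(x)}(x)`: at every pixel the probability the
#' field assigns to the true label is penalized, optionally re-weighted by a
#' per-pixel weight map. Probabilities are floored at 1e-12 so the loss is
#' never infinite.
#'
#' @param p Probability array `(H, W, K)` (e.g. from [softmax_field()]).
#' @param labels Integer matrix `(H, W)` of true labels in `1..K`.
#' @param weights Optional nonnegative matrix `(H, W)`; default all ones.
#' @return Nonnegative scalar loss.
#' @export
weighted_cross_entropy <- function(p, labels, weights = NULL) {
  check_feature_map(p, "p")
  d <- dim(p)
  K <- d[3]
  if (!all(dim(labels) == d[1:2]))
    stop("`labels` must match the spatial dimensions of `p`", call. = FALSE)
  if (any(labels < 1 | labels > K | labels != round(labels)))
    stop(sprintf("labels must be integers in 1..%d", K), call. = FALSE)
  if (is.null(weights)) weights <- matrix(1, d[1], d[2])
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  idx <- cbind(as.vector(row(labels)), as.vector(col(labels)), as.vector(labels))
  ptrue <- pmax(p[idx], 1e-12)
  -sum(as.vector(weights) * log(ptrue))
}

#' Soft dice loss
#'
#' Differentiable surrogate for the Dice overlap: per class,
#' `dice_c = (2*sum(p*t) + smooth) / (sum(p) + sum(t) + smooth)` and the loss
#' is `1 - mean_c dice_c`.
#'
#' @param probabilities Array of per-class probability maps in `[0, 1]`.
#' @param targets Binary array of the same shape.
#' @param smooth Smoothing constant (default 1), keeps empty classes finite.
#' @return Scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(probabilities, targets, smooth = 1) {
  if (!all(dim(probabilities) == dim(targets)))
    stop("probability and target shapes differ", call. = FALSE)
  1 - mean(soft_dice_per_class(probabilities, targets, smooth))
}

soft_dice_per_class <- function(probabilities, targets, smooth) {
  d <- dim(probabilities)
  K <- if (length(d) >= 3L) d[length(d)] else 1L
  pm <- matrix(probabilities, ncol = K)
  tm <- matrix(targets, ncol = K)
  (2 * colSums(pm * tm) + smooth) / (colSums(pm) + colSums(tm) + smooth)
}

#' BCE + soft-dice compound loss
#'
#' Mean per-pixel, per-class binary cross-entropy on `sigmoid(logits)` plus
#' the soft dice loss, weighted `bce_weight : dice_weight` (default 1:1).
#'
#' @param logits Raw network outputs, same shape as `targets`.
#' @param targets Binary masks, one channel per class.
#' @param bce_weight,dice_weight Term weights.
#' @param smooth Dice smoothing constant.
#' @return Nonnegative scalar loss.
#' @export
bce_dice_loss <- function(logits, targets, bce_weight = 1, dice_weight = 1,
                          smooth = 1) {
  if (!all(dim(logits) == dim(targets)))
    stop("logit and target shapes differ", call. = FALSE)
  if (!all(targets %in% c(0, 1))) stop("targets must be binary", call. = FALSE)
  # stable BCE on logits: log(1 + exp(-|z|)) + max(z, 0) - z*t
  z <- logits
  bce <- mean(log1p(exp(-abs(z))) + pmax(z, 0) - z * targets)
  p <- sigmoid(z)
  bce_weight * bce + dice_weight * soft_dice_loss(p, targets, smooth)
}

# gradient of bce_dice_loss w.r.t. logits (same weighting)
bce_dice_grad <- function(logits, targets, bce_weight = 1, dice_weight = 1,
                          smooth = 1) {
  d <- dim(logits)
  K <- d[length(d)]
  n <- length(logits)
  p <- sigmoid(logits)
  g_bce <- (p - targets) / n
  pm <- matrix(p, ncol = K)
  tm <- matrix(targets, ncol = K)
  num <- 2 * colSums(pm * tm) + smooth
  den <- colSums(pm) + colSums(tm) + smooth
  # d(1 - mean dice)/dp per class: -(2*t*den - num) / den^2 / K
  gd <- -(sweep(2 * tm, 2L, den, "*") - matrix(num, nrow(tm), K, byrow = TRUE)) /
    matrix(den^2, nrow(tm), K, byrow = TRUE) / K
  g_dice <- array(gd, d) * p * (1 - p)
  bce_weight * g_bce + dice_weight * g_dice
}
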