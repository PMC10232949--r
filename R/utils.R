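# Internal helpers: feature-map validation, parameter-tree arithmetic, RNG.

# A FeatureMap is a numeric 3-D array indexed (row, col, channel).
check_feature_map <- function(x, name = "x") {
  if (!is.array(x) || length(dim(x)) != 3L || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric 3-D array (H, W, C)", name), call. = FALSE)
  if (any(dim(x) < 1L))
    stop(sprintf("`%s` has a zero-length axis", name), call. = FALSE)
  invisible(x)
}

fm_channels <- function(x) dim(x)[3L]

# recursively apply f to every numeric leaf of a parameter tree
tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(el) tree_map(f, el)))
  f(a)
}

# combine two parameter trees leaf-by-leaf (shapes must match)
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    return(out)
  }
  f(a, b)
}

# sum of f applied to every leaf (used for gradient norms, parameter counts)
tree_reduce <- function(f, a) {
  if (is.list(a)) return(sum(vapply(a, function(el) tree_reduce(f, el), numeric(1))))
  f(a)
}

# numeric leaves only: GN/conv parameter trees also carry integer metadata
# (kernel size, group counts); is_param marks trainable leaves by name "w","b",
# "gamma","beta".
PARAM_LEAVES <- c("w", "b", "gamma", "beta")

# map over trainable leaves of a layer-parameter tree, leaving metadata intact;
# iterates by index so unnamed sublists (e.g. ASPP branches) are traversed too
param_map <- function(f, p) {
  if (!is.list(p)) return(p)
  nms <- names(p) %||% rep("", length(p))
  out <- p
  for (i in seq_along(p)) {
    if (nms[i] %in% PARAM_LEAVES && is.numeric(p[[i]])) {
      out[[i]] <- f(p[[i]])
    } else if (is.list(p[[i]])) {
      out[[i]] <- param_map(f, p[[i]])
    }
  }
  out
}

param_map2 <- function(f, p, q) {
  if (!is.list(p)) return(p)
  nms <- names(p) %||% rep("", length(p))
  out <- p
  for (i in seq_along(p)) {
    key <- if (nzchar(nms[i])) nms[i] else i
    if (nms[i] %in% PARAM_LEAVES && is.numeric(p[[i]])) {
      out[[i]] <- f(p[[i]], q[[key]])
    } else if (is.list(p[[i]])) {
      out[[i]] <- param_map2(f, p[[i]], q[[key]])
    }
  }
  out
}

param_reduce <- function(f, p) {
  if (!is.list(p)) return(0)
  nms <- names(p) %||% rep("", length(p))
  acc <- 0
  for (i in seq_along(p)) {
    if (nms[i] %in% PARAM_LEAVES && is.numeric(p[[i]])) {
      acc <- acc + f(p[[i]])
    } else if (is.list(p[[i]])) {
      acc <- acc + param_reduce(f, p[[i]])
    }
  }
  acc
}

# Kaiming-uniform initialisation for a convolution kernel stored as a
# (k*k*cin) x cout matrix; fan-in = k*k*cin, gain for ReLU.
kaiming_uniform <- function(fan_in, n_out) {
  bound <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * n_out, -bound, bound), fan_in, n_out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
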