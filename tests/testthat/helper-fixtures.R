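# Shared fixtures: small random feature maps and a tiny network configuration
# that exercises every layer on a CPU budget.

rand_fm <- function(H, W, C, seed = NULL, sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(H * W * C, sd = sd), c(H, W, C))
}

tiny_net <- function(base = 2L, seed = 7L) {
  build_masunet(masunet_config(base_channels = base, gn_groups = 2L,
                               reduction = 2L), seed = seed)
}

# one slice sample with simple nested square masks (PZ ring around TZ core)
toy_sample <- function(H = 16L) {
  img <- array(stats::runif(H * H), c(H, H, 1L))
  masks <- array(0, c(H, H, 2L))
  q <- H %/% 4L
  masks[(q + 1L):(3L * q), (q + 1L):(3L * q), 1L] <- 1
  core <- (H %/% 2L - 1L):(H %/% 2L + 1L)
  masks[core, core, 2L] <- 1
  masks[, , 1L] <- masks[, , 1L] * (1 - masks[, , 2L])
  img[, , 1L] <- img[, , 1L] + masks[, , 1L] + 2 * masks[, , 2L]
  list(image = img, masks = masks, volume_id = "toy", slice = 1L, aug = "orig")
}

# brute-force central-difference derivative of f at x[i]
num_deriv <- function(f, x, i, eps = 1e-6) {
  xp <- x; xp[i] <- xp[i] + eps
  xm <- x; xm[i] <- xm[i] - eps
  (f(xp) - f(xm)) / (2 * eps)
}

random_mask <- function(H, W, p = 0.3) {
  matrix(as.numeric(stats::runif(H * W) < p), H, W)
}
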