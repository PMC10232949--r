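# Group normalization, conv blocks, pooling, upsampling, ASPP.

test_that("group normalization matches its definition on hand cases", {
  p <- gn_params(2, num_groups = 1)
  const <- array(7, c(3, 3, 2))
  expect_lt(max(abs(group_normalize(const, p))), 1e-2)  # zero variance -> ~0

  p0 <- gn_params(2, num_groups = 1, gamma = c(0, 0), beta = c(3, 3))
  x <- rand_fm(4, 4, 2, seed = 1)
  expect_equal(as.vector(group_normalize(x, p0)), rep(3, 32))
})

test_that("group normalization agrees with a per-group loop oracle", {
  set.seed(2)
  x <- rand_fm(5, 6, 4)
  gamma <- stats::rnorm(4); beta <- stats::rnorm(4)
  p <- gn_params(4, num_groups = 2, gamma = gamma, beta = beta)
  got <- group_normalize(x, p)
  # oracle: loop over the two groups computing mean/variance directly
  want <- x
  for (g in 1:2) {
    ch <- ((g - 1) * 2 + 1):(g * 2)
    v <- x[, , ch]
    xh <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + p$epsilon)
    for (k in seq_along(ch)) want[, , ch[k]] <- xh[, , k] * gamma[ch[k]] + beta[ch[k]]
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("normalized groups have mean ~0 and variance ~1 before scale/shift", {
  set.seed(3)
  for (rep in 1:5) {
    x <- rand_fm(8, 8, 8, sd = runif(1, 0.5, 4))
    p <- gn_params(8, num_groups = 4)
    y <- group_normalize(x, p)
    for (g in 1:4) {
      v <- y[, , ((g - 1) * 2 + 1):(g * 2)]
      expect_lt(abs(mean(v)), 1e-4)
      expect_lt(abs(mean((v - mean(v))^2) - 1), 1e-4)
    }
  }
})

test_that("one group per channel equals instance normalization", {
  set.seed(4)
  x <- rand_fm(6, 6, 3)
  p <- gn_params(3, num_groups = 3)
  got <- group_normalize(x, p)
  for (c in 1:3) {
    v <- x[, , c]
    expect_equal(got[, , c], (v - mean(v)) / sqrt(mean((v - mean(v))^2) + p$epsilon),
                 tolerance = 1e-12)
  }
})

test_that("group normalization rejects indivisible group counts", {
  expect_error(gn_params(6, num_groups = 4), "6.*4|4.*6")
  expect_error(group_normalize(rand_fm(4, 4, 6, seed = 1), gn_params(8, num_groups = 4)),
               "divisible")
})

test_that("conv block contract: shape, nonnegativity, eval-mode dropout identity", {
  set.seed(5)
  p <- conv_block_params(8, 16, gn_groups = 8)
  x <- rand_fm(16, 16, 8)
  y <- conv_block_forward(x, p)
  expect_identical(dim(y), c(16L, 16L, 16L))
  expect_true(all(y >= 0))
  expect_true(all(is.finite(y)))
  # dropout block in eval mode equals the same weights without dropout
  pd <- p; pd$with_dropout <- TRUE
  expect_identical(conv_block_forward(x, pd, training = FALSE),
                   conv_block_forward(x, p, training = FALSE))
  expect_error(conv_block_forward(rand_fm(8, 8, 4, seed = 1), p), "channels")
})

test_that("max pooling equals a window-loop oracle and halves the lattice", {
  m <- array(c(1, 3, 2, 4), c(2, 2, 1))
  expect_equal(as.vector(max_pool_downsample(m)), 4)

  set.seed(6)
  x <- rand_fm(8, 6, 3)
  y <- max_pool_downsample(x)
  expect_identical(dim(y), c(4L, 3L, 3L))
  for (c in 1:3) for (i in 1:4) for (j in 1:3)
    expect_equal(y[i, j, c], max(x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c]))

  expect_error(max_pool_downsample(rand_fm(5, 6, 1, seed = 1)), "multiple of 16")
})

test_that("nearest upsampling reproduces the floor-index map exactly", {
  x <- array(c(1, 3, 2, 4), c(2, 2, 1))
  y <- nearest_upsample(x, 2)
  expect_equal(y[, , 1],
               matrix(c(1, 1, 3, 3,
                        1, 1, 3, 3,
                        2, 2, 4, 4,
                        2, 2, 4, 4), 4, 4))
  # upsampling 4 -> 8 columns: output column with 0-based index 5 reads
  # source column floor(4/8 * 5) = 2 (0-based)
  x2 <- array(seq_len(4), c(1, 4, 1))
  y2 <- nearest_upsample(x2, 2)
  expect_equal(y2[1, 6, 1], x2[1, 3, 1])
  expect_identical(nearest_upsample(x, 1), x)
  expect_error(nearest_upsample(x, 0), "positive integer")
})

test_that("nearest upsampling composes multiplicatively", {
  set.seed(7)
  x <- rand_fm(3, 5, 2)
  expect_equal(nearest_upsample(nearest_upsample(x, 2), 3),
               nearest_upsample(x, 6))
})

test_that("pooling then upsampling restores block-constant inputs", {
  set.seed(8)
  coarse <- rand_fm(4, 4, 2)
  fine <- nearest_upsample(coarse, 2)
  expect_equal(nearest_upsample(max_pool_downsample(fine), 2), fine)
})

test_that("up-conv block doubles resolution and halves channels", {
  set.seed(9)
  p <- upconv_block_params(8)
  x <- rand_fm(4, 4, 8)
  y <- upconv_block_forward(x, p)
  expect_identical(dim(y), c(8L, 8L, 4L))
  expect_true(all(is.finite(y)))
  expect_error(upconv_block_params(7), "even")
})

test_that("up-conv with a delta kernel and neutralized GN is nearest upsampling", {
  # one channel in, delta kernel, gamma = sd, beta = mean restores the layout
  p <- upconv_block_params(2)
  p$conv$w[] <- 0
  p$conv$w[5, 1] <- 1      # center tap of the 3x3 kernel, channel 1 -> out 1
  set.seed(10)
  x <- array(abs(rnorm(4 * 4 * 2)) + 1, c(4, 4, 2))
  up <- nearest_upsample(x, 2)[, , 1]
  mu <- mean(up); s <- sqrt(mean((up - mu)^2) + p$gn$epsilon)
  p$gn$gamma <- c(s, 1); p$gn$beta <- c(mu, 0)
  y <- upconv_block_forward(x, p)
  expect_equal(y[, , 1], up, tolerance = 1e-6)
})

test_that("ASPP preserves spatial size, concatenates 4 branches, reduces channels", {
  set.seed(11)
  cfg <- aspp_config(8, 8)
  expect_identical(cfg$dilation_rates, c(1L, 6L, 12L, 18L))
  expect_identical(cfg$branch_channels * length(cfg$dilation_rates), 8L)
  p <- aspp_params(cfg)
  x <- rand_fm(16, 16, 8)
  y <- aspp_forward(x, p)
  expect_identical(dim(y), c(16L, 16L, 8L))
  # spatial preservation across sizes, including smaller than the largest rate
  for (sz in c(1L, 3L, 7L)) {
    xs <- rand_fm(sz, sz, 8)
    expect_identical(dim(aspp_forward(xs, p))[1:2], c(sz, sz))
  }
})

test_that("ASPP with zero branch kernels outputs the fusion bias", {
  cfg <- aspp_config(4, 3, gn_groups = 1)
  p <- aspp_params(cfg)
  for (i in seq_along(p$branches)) {
    p$branches[[i]]$conv$w[] <- 0
    p$branches[[i]]$conv$b[] <- 0
  }
  p$fuse$b <- c(-1, 0, 2.5)
  y <- aspp_forward(rand_fm(5, 5, 4, seed = 12), p)
  for (k in 1:3) expect_equal(unname(y[, , k]), matrix(p$fuse$b[k], 5, 5))
})

test_that("block backward passes match finite differences", {
  set.seed(13)
  # conv2d
  p <- masunet:::conv2d_new(2, 3)
  x <- rand_fm(5, 5, 2); dy <- rand_fm(5, 5, 3)
  g <- masunet:::conv2d_bwd(p, x, dy)
  f <- function(xx) sum(masunet:::conv2d_fwd(p, xx) * dy)
  for (i in sample(length(x), 8))
    expect_equal(num_deriv(f, x, i), g$dx[i], tolerance = 1e-5)
  fw <- function(ww) { q <- p; q$w <- ww; sum(masunet:::conv2d_fwd(q, x) * dy) }
  for (i in sample(length(p$w), 8))
    expect_equal(num_deriv(fw, p$w, i), g$grads$w[i], tolerance = 1e-5)
  # group norm
  gp <- gn_params(4, 2, gamma = rnorm(4), beta = rnorm(4))
  x <- rand_fm(4, 4, 4); dy <- rand_fm(4, 4, 4)
  bg <- masunet:::gn_bwd(masunet:::gn_fwd(x, gp)$cache, dy)
  fg <- function(xx) sum(masunet:::gn_fwd(xx, gp)$y * dy)
  for (i in sample(length(x), 8))
    expect_equal(num_deriv(fg, x, i), bg$dx[i], tolerance = 1e-4)
  # max pool
  x <- rand_fm(6, 6, 2); dy <- rand_fm(3, 3, 2)
  mp <- masunet:::max_pool_fwd(x)
  dx <- masunet:::max_pool_bwd(mp$cache, dy)
  fm <- function(xx) sum(masunet:::max_pool_fwd(xx)$y * dy)
  for (i in sample(length(x), 8))
    expect_equal(num_deriv(fm, x, i), dx[i], tolerance = 1e-5)
})
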