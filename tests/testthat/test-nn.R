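# The layer library's hand-written backward passes are validated against
# central finite differences on small random instances.

ns <- asNamespace("mrisynth")

test_that("convolution forward/backward matches finite differences (plain and strided)", {
  set.seed(1)
  par <- ns$conv_par(3L, 2L, 3L)
  x <- array(rnorm(72), dim = c(6, 6, 2))
  eps <- 1e-6
  for (stride in c(1L, 2L)) {
    plan <- ns$conv_plan(6L, 6L, 3L, stride = stride, pad = 1L)
    fw <- ns$conv_fwd(x, par, plan)
    ct <- array(rnorm(length(fw$y)), dim = dim(fw$y))
    loss <- function(xx, pp) sum(ct * ns$conv_fwd(xx, pp, plan)$y)
    bw <- ns$conv_bwd(ct, par, fw$cache)
    gx <- array(0, dim = dim(x))
    for (i in seq_along(x)) {
      x1 <- x; x1[i] <- x1[i] + eps
      x2 <- x; x2[i] <- x2[i] - eps
      gx[i] <- (loss(x1, par) - loss(x2, par)) / (2 * eps)
    }
    expect_lt(max(abs(gx - bw$dx)), 1e-7)
    gW <- par$W * 0
    for (i in seq_along(par$W)) {
      p1 <- par; p1$W[i] <- p1$W[i] + eps
      p2 <- par; p2$W[i] <- p2$W[i] - eps
      gW[i] <- (loss(x, p1) - loss(x, p2)) / (2 * eps)
    }
    expect_lt(max(abs(gW - bw$dW)), 1e-7)
    expect_equal(bw$db, apply(ct, 3, sum), tolerance = 1e-12)
  }
})

test_that("dense and upsampling backward passes match finite differences", {
  set.seed(2)
  par <- ns$dense_par(5L, 3L)
  x <- rnorm(5)
  ct <- rnorm(3)
  fw <- ns$dense_fwd(x, par)
  bw <- ns$dense_bwd(ct, par, x)
  eps <- 1e-6
  gx <- numeric(5)
  for (i in 1:5) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    gx[i] <- (sum(ct * ns$dense_fwd(x1, par)$y) -
              sum(ct * ns$dense_fwd(x2, par)$y)) / (2 * eps)
  }
  expect_lt(max(abs(gx - bw$dx)), 1e-8)
  # nearest-neighbour upsampling adjoint sums 2x2 blocks
  u <- array(rnorm(8), dim = c(2, 2, 2))
  up <- ns$upsample2_fwd(u)
  expect_identical(dim(up), c(4L, 4L, 2L))
  ct2 <- array(rnorm(32), dim = c(4, 4, 2))
  expect_equal(sum(ct2 * up), sum(ns$upsample2_bwd(ct2) * u), tolerance = 1e-12)
})

test_that("the SSIM training loss gradient matches finite differences", {
  set.seed(3)
  x <- matrix(runif(144), 12, 12)
  y <- matrix(runif(144), 12, 12)
  sg <- ns$ssim_loss_grad(x, y, data_range = 1)
  eps <- 1e-6
  g <- matrix(0, 12, 12)
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (ns$ssim_loss_grad(x1, y, 1)$value -
             ns$ssim_loss_grad(x2, y, 1)$value) / (2 * eps)
  }
  expect_lt(max(abs(g - sg$grad)), 1e-7)
})

test_that("Adam leaves parameters untouched under zero gradients", {
  set.seed(4)
  params <- list(a = list(W = matrix(rnorm(6), 2, 3), b = numeric(3)), s = 1)
  st <- ns$adam_init(params)
  zz <- ns$grad_zero_like(params)
  up <- ns$adam_update(params, zz, st, lr = 1e-2)
  expect_identical(up$params$a$W, params$a$W)
  expect_identical(up$params$s, params$s)
})

test_that("block-mean downsampling matches the brute-force loop and paper geometry", {
  set.seed(5)
  x <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16, 16)
  d <- downsample_map(x, 4L)
  oracle <- matrix(0 + 0i, 4, 4)
  for (i in 1:4) for (j in 1:4)
    oracle[i, j] <- mean(x[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j)])
  expect_equal(d, oracle, tolerance = 1e-12)
  # constant maps stay constant; 320 -> 80 at the default factor
  cst <- downsample_map(matrix(3 + 2i, 8, 8), 4L)
  expect_lt(max(abs(cst - (3 + 2i))), 1e-12)
  big <- downsample_map(matrix(0.5, 320, 320), 4L)
  expect_identical(dim(big), c(80L, 80L))
  expect_error(downsample_map(matrix(1, 10, 10), 4L), "divisible")
})

test_that("bilinear upsampling preserves constants and hits the requested grid", {
  u <- array(2, dim = c(4, 4, 1))
  up <- ns$bilinear_upsample(u, 4L)
  expect_identical(dim(up), c(16L, 16L, 1L))
  expect_lt(max(abs(up - 2)), 1e-12)
})
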