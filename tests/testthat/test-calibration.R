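test_that("estimated CSMs agree with ground truth up to a global phase on noiseless phantoms", {
  # constant object phase isolates the coil phase: the decomposition into
  # object and coil phase is only defined up to a shared smooth field
  spec <- phantom_spec(noise_sigma = 0, poly_coef_max = 0, sin_amp_max = 0)
  for (sd in c(3L, 9L, 21L)) {
    sc <- make_scan(spec, 1L, seed = sd)
    gt <- sc$ground_truth[[1]]
    est <- estimate_csm(sc$kspace[[1]], 26L)
    sup <- est$support & gt$magnitude > 0.05
    align <- 0 + 0i
    for (j in 1:4)
      align <- align + sum(Conj(gt$csm$data[j, , ][sup]) * est$data[j, , ][sup])
    g <- align / abs(align)
    num <- den <- 0
    for (j in 1:4) {
      num <- num + sum(abs(est$data[j, , ][sup] / g - gt$csm$data[j, , ][sup])^2)
      den <- den + sum(abs(gt$csm$data[j, , ][sup])^2)
    }
    expect_lt(sqrt(num / den), 0.05)
  }
})

test_that("estimate_csm enforces unit RSS on support and handles degenerate input", {
  sc <- make_scan(fx_spec(), 1L, seed = 55L)
  est <- estimate_csm(sc$kspace[[1]], 26L)
  expect_lt(max(abs(rss_combine(est$data)[est$support] - 1)), 1e-6)
  expect_true(all(rss_combine(est$data)[!est$support] == 0))
  expect_error(estimate_csm(array(0 + 0i, dim = c(2, 64, 64)), 26L), "degenerate")
  expect_error(estimate_csm(sc$kspace[[1]], 4L), "calib_lines")
  # single uniform coil: estimated map is 1 inside the support
  m <- make_magnitude(fx_spec(), 2L)
  k <- array(fft2c(matrix(complex(real = m), 64, 64)), dim = c(1, 64, 64))
  one <- estimate_csm(k, 26L)
  expect_lt(max(abs(one$data[1, , ][one$support] - 1)), 0.05)
})

test_that("phase-sensitive combination reproduces RSS magnitude and object phase", {
  spec <- phantom_spec(noise_sigma = 0)
  sc <- make_scan(spec, 1L, seed = 6L)
  gt <- sc$ground_truth[[1]]
  imgs <- coil_ifft2c(sc$kspace[[1]])
  # with the exact (unit-RSS) maps, |combined| equals RSS exactly and the
  # phase is the object phase
  comb <- phase_sensitive_combine(imgs, gt$csm)
  rss <- rss_combine(imgs)
  sup <- gt$magnitude > 0.05
  expect_lt(max(abs(abs(comb)[sup] - rss[sup]) / rss[sup]), 1e-6)
  dphi <- Arg(comb[sup] * Conj(gt$phase[sup]))
  align <- Arg(mean(exp(1i * dphi)))
  expect_lt(max(abs(Arg(exp(1i * (dphi - align))))), 1e-3)
  # single coil with csm = 1 returns the coil image unchanged
  ones <- csm_maps(array(1 + 0i, dim = c(1, 64, 64)), matrix(TRUE, 64, 64))
  img1 <- imgs[1, , , drop = FALSE]
  expect_equal(phase_sensitive_combine(img1, ones), imgs[1, , ],
               tolerance = 1e-14)
  expect_error(phase_sensitive_combine(imgs[, 1:32, , drop = FALSE], gt$csm),
               "mismatch")
})

test_that("CSM phase normalization zeroes the first-coil mean phase, idempotently", {
  sc <- make_scan(fx_spec(), 1L, seed = 14L)
  est <- estimate_csm(sc$kspace[[1]], 26L)
  nz <- normalize_csm_phase(est)
  c0 <- nz$data[1, , ]
  sel <- nz$support & abs(c0) > 0
  expect_lt(abs(Arg(mean(c0[sel] / abs(c0[sel])))), 1e-6)
  expect_equal(abs(nz$data), abs(est$data), tolerance = 1e-12)
  nz2 <- normalize_csm_phase(nz)
  expect_lt(max(abs(nz2$data - nz$data)), 1e-12)
  # constant 0.7 rad phase on one uniform coil goes to 0
  cs <- csm_maps(array(exp(0.7i), dim = c(1, 16, 16)), matrix(TRUE, 16, 16))
  out <- normalize_csm_phase(cs)
  expect_lt(max(abs(Arg(out$data))), 1e-12)
})

test_that("background noise covariance estimation recovers known covariances", {
  nc <- 4L; n <- 64L
  set.seed(1)
  imgs <- array(complex(real = rnorm(nc * n * n),
                        imaginary = rnorm(nc * n * n)) / sqrt(2),
                dim = c(nc, n, n))
  est <- estimate_noise_cov(imgs, region = c(1L, 1L), size = 20L)
  frob <- function(A) sqrt(sum(Mod(A)^2))
  expect_lt(frob(est$matrix - diag(nc)), 0.25)
  # zero region gives the zero matrix
  z <- estimate_noise_cov(array(0 + 0i, dim = c(2, 32, 32)), c(1L, 1L), 20L)
  expect_true(all(z$matrix == 0))
  expect_error(estimate_noise_cov(imgs, c(60L, 60L), 20L), "bounds")
})

test_that("off-diagonal noise correlation is recovered within Monte-Carlo bounds", {
  # 2 coils, correlation 0.5; oracle standard error from repeated simulation
  phi <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  L <- chol(phi)
  draws <- replicate(60, {
    set.seed(sample.int(1e6, 1))
    Z <- matrix(complex(real = rnorm(800), imaginary = rnorm(800)) / sqrt(2), 2, 400)
    X <- t(L) %*% Z
    Xc <- X - rowMeans(X)
    Re((Xc %*% Conj(t(Xc)))[1, 2] / 399)
  })
  se <- sd(draws)
  set.seed(77)
  Z <- matrix(complex(real = rnorm(2 * 32 * 32),
                      imaginary = rnorm(2 * 32 * 32)) / sqrt(2), 2, 32 * 32)
  imgs <- array(0 + 0i, dim = c(2, 32, 32))
  X <- t(L) %*% Z
  imgs[1, , ] <- matrix(X[1, ], 32, 32)
  imgs[2, , ] <- matrix(X[2, ], 32, 32)
  est <- estimate_noise_cov(imgs, region = c(1L, 1L), size = 20L)
  off <- est$matrix[1, 2]
  expect_gt(Re(off), 0)                      # sign recovered
  expect_lt(abs(Re(off) - 0.5), 3 * se)      # magnitude within 3 SE
})

test_that("noise covariance estimates tighten as the background region grows", {
  nc <- 4L
  frob <- function(A) sqrt(sum(Mod(A)^2))
  e10 <- e40 <- numeric(50)
  for (s in 1:50) {
    set.seed(s)
    imgs <- array(complex(real = rnorm(nc * 64 * 64),
                          imaginary = rnorm(nc * 64 * 64)) / sqrt(2),
                  dim = c(nc, 64, 64))
    e10[s] <- frob(estimate_noise_cov(imgs, c(1L, 1L), 10L)$matrix - diag(nc))
    e40[s] <- frob(estimate_noise_cov(imgs, c(1L, 1L), 40L)$matrix - diag(nc))
  }
  expect_lt(mean(e40), mean(e10))
})

test_that("decompose_scan is deterministic and yields valid triplets", {
  sc <- make_scan(fx_spec(), 1L, seed = 33L)
  t1 <- decompose_scan(sc)
  t2 <- decompose_scan(sc)
  expect_identical(t1[[1]]$magnitude, t2[[1]]$magnitude)
  expect_identical(t1[[1]]$csm$data, t2[[1]]$csm$data)
  expect_true(all(t1[[1]]$magnitude >= 0))
  expect_s3_class(t1[[1]]$noise_cov, "noise_cov")
  # estimated noise covariance is near the injected one (scale check)
  inj <- sc$ground_truth[[1]]$noise_cov$matrix
  est <- t1[[1]]$noise_cov$matrix
  expect_lt(abs(mean(Re(diag(est))) / mean(Re(diag(inj))) - 1), 0.5)
})

test_that("decompose then noiseless resynthesis reproduces the original raw data", {
  spec <- phantom_spec(noise_sigma = 0)
  for (sd in c(2L, 8L)) {
    sc <- make_scan(spec, 1L, seed = sd)
    tr <- decompose_scan(sc)[[1]]
    k2 <- synthesize_raw(tr$magnitude, tr$phase, tr$csm,
                         matrix(0 + 0i, 4, 4))
    sup <- tr$csm$support
    rss0 <- sc$magnitude[[1]]
    rss2 <- rss_combine(coil_ifft2c(k2))
    expect_lt(rel_l2(rss2[sup], rss0[sup]), 0.02)
    # magnitude-weighted RMS coil-image phase error
    i1 <- coil_ifft2c(sc$kspace[[1]]); i2 <- coil_ifft2c(k2)
    w <- abs(i1); dphi <- Arg(i2 * Conj(i1))
    expect_lt(sqrt(sum(w^2 * dphi^2) / sum(w^2)), 0.05)
  }
})
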