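test_that("the 320-line mask has a contiguous 26-line calibration block and stride-4 gaps", {
  mask <- make_mask(320L)
  lines <- mask$lines
  # contiguous central fully sampled run has exactly width 26
  runs <- rle(lines)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  centre <- 161L  # 0-based 160
  central <- which(runs$values & starts <= centre & ends >= centre)
  expect_identical(runs$lengths[central], 26L)
  expect_identical(starts[central], 148L)  # 0-based 147 = 160 - 13
  # outside the calibration block consecutive sampled lines are 4 apart
  calib <- 148:173
  outside <- setdiff(which(lines), calib)
  expect_true(all(diff(outside[outside < 148]) == 4L))
  expect_true(all(diff(outside[outside > 173]) == 4L))
  expect_true(all((outside - 1L) %% 4L == 0L))
  # acceleration between 3 and 4
  acc <- 320 / sum(lines)
  expect_gt(acc, 3); expect_lt(acc, 4)
  # stride 1 samples everything; oversized calibration block rejected
  expect_true(all(make_mask(64L, stride = 1L, calib_width = 8L)$lines))
  expect_error(make_mask(16L, calib_width = 26L), "exceeds")
})

test_that("retrospective undersampling copies sampled lines and zeroes the rest", {
  set.seed(10)
  k <- array(complex(real = rnorm(4 * 32 * 32), imaginary = rnorm(4 * 32 * 32)),
             dim = c(4, 32, 32))
  full <- make_mask(32L, stride = 1L, calib_width = 8L)
  expect_identical(apply_undersampling(k, full), k)
  mask <- make_mask(32L, stride = 4L, calib_width = 8L)
  u <- apply_undersampling(k, mask)
  expect_identical(u[, mask$lines, ], k[, mask$lines, ])
  expect_true(all(u[, !mask$lines, ] == 0))
  expect_lt(sum(abs(u)^2), sum(abs(k)^2))
  expect_error(apply_undersampling(k, make_mask(16L, calib_width = 8L)), "ky")
})

test_that("discrete augmentations satisfy their group identities and commute with RSS", {
  set.seed(11)
  img <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16, 16)
  r <- img
  for (i in 1:4) r <- rotate90(r, 1L)
  expect_identical(r, img)
  expect_identical(mirror_image(mirror_image(img, "x"), "x"), img)
  expect_identical(mirror_image(mirror_image(img, "both"), "both"), img)
  # shift then unshift restores the interior (borders are zero-filled)
  back <- shift_image(shift_image(img, 3L, -2L), -3L, 2L)
  expect_identical(back[1:13, 3:16], img[1:13, 3:16])
  expect_true(all(back[14:16, ] == 0))
  # RSS of transformed coils equals transformed RSS, exactly
  stack <- array(complex(real = rnorm(4 * 256), imaginary = rnorm(4 * 256)),
                 dim = c(4, 16, 16))
  rssm <- rss_combine(stack)
  tstack <- stack
  for (j in 1:4) tstack[j, , ] <- rotate90(mirror_image(stack[j, , ], "y"), 2L)
  expect_equal(rss_combine(tstack), rotate90(mirror_image(rssm, "y"), 2L),
               tolerance = 1e-14)
})

test_that("augment is the identity at probability zero and reproducible per seed", {
  real <- fx_real_pool()
  smp <- real$slices[[1]][c("kspace", "target")]
  off <- augmentation_config(prob = 0)
  expect_identical(augment(smp, off, seed = 1L)$kspace, smp$kspace)
  on <- augmentation_config(prob = 1)
  a1 <- augment(smp, on, seed = 2L)
  a2 <- augment(smp, on, seed = 2L)
  expect_identical(a1$kspace, a2$kspace)
  expect_false(identical(a1$kspace, augment(smp, on, seed = 3L)$kspace))
  # the same spatial transform is applied to coils and target: RSS of the
  # augmented k-space approximates the augmented target (bilinear resampling
  # of coil images vs of the combined magnitude differ only slightly)
  expect_lt(mean(abs(rss_combine(coil_ifft2c(a1$kspace)) - a1$target)),
            0.05 * max(a1$target))
})

test_that("a zero-epoch schedule returns the freshly initialised network untouched", {
  real <- fx_real_pool()
  sampler <- function(s) draw_training_sample(NULL, real, mix_fraction = 0,
                                              mode = "real", seed = s)
  cfg <- recon_config(epochs = 0L, seed = 21L)
  m0 <- train_recon(sampler, fx_mask64(), cfg)
  expect_false(isTRUE(m0$trained))
  ref <- recon_model(c(64L, 64L), cfg)
  expect_identical(m0$params, ref$params)
})

test_that("reconstruction is deterministic, non-negative, and shape-checked", {
  model <- fx_recon()
  sc <- fx_test_scans()[[1]]
  und <- apply_undersampling(sc$kspace[[1]], fx_mask64())
  r1 <- reconstruct(model, und, fx_mask64())
  r2 <- reconstruct(model, und, fx_mask64())
  expect_identical(r1, r2)
  expect_true(all(r1 >= 0))
  expect_identical(dim(r1), c(64L, 64L))
  bad <- array(0 + 1i, dim = c(4, 32, 32))
  expect_error(reconstruct(model, bad, fx_mask64()))
})

test_that("the trained variational network beats the zero-filled baseline on held-out slices", {
  model <- fx_recon()
  expect_lt(mean(tail(model$losses$loss, 50)), mean(head(model$losses$loss, 10)))
  mask <- fx_mask64()
  recs <- zfs <- c()
  for (sc in fx_test_scans()) for (s in 1:2) {
    und <- apply_undersampling(sc$kspace[[s]], mask)
    recs <- c(recs, mae(reconstruct(model, und, mask), sc$magnitude[[s]]))
    zfs <- c(zfs, mae(zero_filled(und), sc$magnitude[[s]]))
  }
  expect_lt(mean(recs), mean(zfs))
})
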