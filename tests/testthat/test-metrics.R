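test_that("MAE and RMSE match their loop oracles and shift identities", {
  set.seed(20)
  x <- matrix(runif(64), 8, 8)
  y <- matrix(runif(64), 8, 8)
  o_mae <- 0; o_rmse <- 0
  for (i in 1:8) for (j in 1:8) {
    o_mae <- o_mae + abs(x[i, j] - y[i, j])
    o_rmse <- o_rmse + (x[i, j] - y[i, j])^2
  }
  expect_equal(mae(x, y), o_mae / 64, tolerance = 1e-14)
  expect_equal(rmse(x, y), sqrt(o_rmse / 64), tolerance = 1e-14)
  expect_identical(mae(x, x), 0)
  expect_identical(rmse(x, x), 0)
  expect_equal(mae(x, x + 0.3), 0.3, tolerance = 1e-12)
  expect_equal(rmse(x, x + 0.3), 0.3, tolerance = 1e-12)
  expect_error(mae(x, matrix(0, 4, 4)), "mismatch")
})

test_that("RMSE dominates MAE on random image pairs", {
  set.seed(21)
  for (i in 1:100) {
    x <- matrix(rnorm(64), 8, 8)
    y <- matrix(rnorm(64), 8, 8)
    expect_gte(rmse(x, y), mae(x, y))
  }
})

test_that("mSSIM equals 1 at identity, is symmetric, and matches the reference implementation", {
  set.seed(42)
  x <- matrix(runif(64 * 64), 64, 64)
  y <- pmax(pmin(x + matrix(rnorm(64 * 64, 0, 0.1), 64, 64), 1), 0)
  expect_equal(mssim(x, x, data_range = 1), 1, tolerance = 1e-12)
  expect_equal(mssim(x, y), mssim(y, x), tolerance = 1e-12)
  # frozen oracle: skimage structural_similarity (gaussian_weights=TRUE,
  # sigma=1.5, use_sample_covariance=FALSE, data_range=1) on these exact
  # fixed-seed inputs
  expect_equal(mssim(x, y, data_range = 1), 0.9451202470, tolerance = 1e-6)
  set.seed(7)
  a <- matrix(runif(32 * 48), 32, 48)
  b <- matrix(runif(32 * 48), 32, 48)
  expect_equal(mssim(a, b, data_range = 1), -0.0525997933, tolerance = 1e-6)
  expect_error(mssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("paired t-test matches the closed-form statistic and flags degeneracy", {
  set.seed(22)
  a <- rnorm(20); b <- rnorm(20)
  out <- paired_ttest(a, b)
  d <- a - b
  t_ref <- mean(d) / (sd(d) / sqrt(20))
  p_ref <- 2 * pt(-abs(t_ref), df = 19)
  expect_equal(out$statistic, t_ref, tolerance = 1e-10)
  expect_equal(out$p_value, p_ref, tolerance = 1e-10)
  expect_false(out$degenerate)
  # identical vectors and constant shifts have zero difference variance
  expect_true(paired_ttest(a, a)$degenerate)
  expect_true(paired_ttest(a + 1, a)$degenerate)
  expect_error(paired_ttest(a, b[1:10]), "length")
})

test_that("best-run selection maximises validation mSSIM with lowest-id tie-break", {
  mk <- function(id, v) experiment_result(
    data.frame(subject = 1:3, mae = 0.01, rmse = 0.02, mssim = 0.9),
    run_id = id, mode = "real", train_size = 5, augmented = FALSE,
    validation_mssim = v)
  expect_identical(select_best_run(list(mk(1, 0.9)))$run_id, 1)
  expect_identical(select_best_run(list(mk(1, 0.90), mk(2, 0.95), mk(3, 0.93)))$run_id, 2)
  expect_identical(select_best_run(list(mk(2, 0.95), mk(1, 0.95)))$run_id, 1)
  expect_error(select_best_run(list()), "empty")
})

test_that("experiment configs round-trip through YAML", {
  cfg <- experiment_config(train_size = 10L, mode = "real",
                           use_augmentation = TRUE, synthetic_fraction = 0.6,
                           epochs = 2L, batches_per_epoch = 50L, seed = 9L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg, f)
  cfg2 <- read_experiment_config(f)
  expect_equal(cfg2$train_size, cfg$train_size)
  expect_equal(cfg2$synthetic_fraction, 0.6)
  expect_identical(cfg2$mode, "real")
  expect_true(cfg2$use_augmentation)
})

test_that("a small experiment grid runs, summarises correctly, and is reproducible", {
  spec <- phantom_spec(grid = 32L)
  train <- lapply(1:3, function(i) make_scan(spec, 1L, seed = 300 + i))
  test <- lapply(1:3, function(i) make_scan(spec, 1L, seed = 400 + i, split = "test"))
  val <- list(make_scan(spec, 1L, seed = 500L, split = "validation"))
  real <- real_pool(train)
  mask <- make_mask(32L, stride = 4L, calib_width = 8L)
  cfg <- recon_config(cascades = 1L, filters = 4L, epochs = 1L,
                      batches_per_epoch = 3L)
  grid <- run_experiment_grid(modes = "real", train_sizes = 3L,
                              repetitions = 2L, synth = NULL, real = real,
                              test_scans = test, validation_scans = val,
                              mask = mask, recon_cfg = cfg, seed = 42L)
  expect_length(grid$results, 2L)
  # summary means equal hand-computed means of the recorded per-run values
  per_run <- vapply(grid$results, function(r) mean(r$subject_metrics$mae),
                    numeric(1))
  expect_equal(grid$summary$mae_mean, mean(per_run), tolerance = 1e-12)
  expect_identical(grid$summary$runs, 2L)
  # bitwise reproducibility from the master seed
  grid2 <- run_experiment_grid(modes = "real", train_sizes = 3L,
                               repetitions = 2L, synth = NULL, real = real,
                               test_scans = test, validation_scans = val,
                               mask = mask, recon_cfg = cfg, seed = 42L)
  expect_identical(grid$results[[1]]$subject_metrics,
                   grid2$results[[1]]$subject_metrics)
})
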