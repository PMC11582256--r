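# Shared fixtures, generated in code and memoised so expensive training runs
# happen once per test session. All seeds are fixed; everything is
# reproducible from this file alone.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

dseed <- mrisynth:::derive_seed

fx_spec <- function() phantom_spec()

# 40 (magnitude, phase-map) pairs at 64x64 with their 16x16 reductions
fx_phase_slices <- function() fixture("phase_slices", function() {
  spec <- fx_spec()
  lapply(1:40, function(i) {
    m <- make_magnitude(spec, dseed(99, "mag", i))
    p <- make_phase(spec, dseed(99, "ph", i))
    list(magnitude = m, map = p,
         mag_lr = downsample_map(m, 4L), map_lr = downsample_map(p, 4L))
  })
})

fx_lowset <- function() lapply(fx_phase_slices(), function(s)
  list(magnitude = s$mag_lr, map = s$map_lr))

# the 500-step fixed-seed phase AAE smoke run
fx_phase_aae <- function() fixture("phase_aae", function() {
  train_aae(fx_lowset(), aae_train_config(steps = 500L, seed = 5L))
})

# super-resolution model trained on the first 30 phase slices
fx_phase_sr <- function() fixture("phase_sr", function() {
  pairs <- lapply(fx_phase_slices()[1:30], function(s)
    list(lowres = s$map_lr, magnitude = s$magnitude, hires = s$map))
  train_superres(pairs, sr_train_config(steps = 400L, batch = 2L, seed = 3L))
})

fx_train_scans <- function() fixture("train_scans", function() {
  spec <- fx_spec()
  lapply(1:6, function(i) make_scan(spec, 2L, seed = 100 + i, split = "train"))
})

fx_test_scans <- function() fixture("test_scans", function() {
  spec <- fx_spec()
  lapply(1:2, function(i) make_scan(spec, 2L, seed = 200 + i, split = "test"))
})

fx_real_pool <- function() fixture("real_pool_", function() real_pool(fx_train_scans()))

fx_mask64 <- function() make_mask(64L, stride = 4L, calib_width = 16L)

# the 300-step fixed-seed scaled-down variational-network smoke run
fx_recon <- function() fixture("recon", function() {
  real <- fx_real_pool()
  sampler <- function(s) draw_training_sample(NULL, real, mix_fraction = 0,
                                              mode = "real", seed = s)
  train_recon(sampler, fx_mask64(),
              recon_config(epochs = 1L, batches_per_epoch = 300L, seed = 11L))
})

rel_l2 <- function(a, b) sqrt(sum(abs(a - b)^2) / sum(abs(b)^2))
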