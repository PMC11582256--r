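# Conditional super-resolution: upsample a low-resolution synthesized map to
# full resolution using the high-resolution magnitude image as guidance. The
# network predicts a residual on top of a fixed bilinear upsampling, so an
# untrained model already reduces to the bilinear baseline plus noise.

#' Training configuration for the super-resolution network
#'
#' @param filters convolutional channel width.
#' @param lr Adam learning rate.
#' @param weight_decay decoupled per-step shrink rate on the convolution
#'   weights (`W <- (1 - weight_decay) * W` after each update); keeps the
#'   residual path from overfitting when the bilinear base is already a
#'   strong predictor.
#' @param steps,batch optimisation steps and minibatch size.
#' @param seed master seed.
#' @return list of class `sr_train_config`.
#' @export
sr_train_config <- function(filters = 12L, lr = 1e-3, weight_decay = 3e-4,
                            steps = 500L, batch = 4L, seed = 1L) {
  structure(as.list(environment()), class = "sr_train_config")
}

#' Construct an (untrained) conditional super-resolution model
#'
#' @param hi_res full-resolution grid size.
#' @param scale_factor integer upsampling factor (default 4, e.g. 80 -> 320).
#' @param channels map channel count (2 for phase, `2*coils` for CSM).
#' @param config an [sr_train_config()].
#' @return object of class `sr_model`.
#' @export
sr_model <- function(hi_res, scale_factor = 4L, channels = 2L,
                     config = sr_train_config()) {
  stopifnot(hi_res %% scale_factor == 0L)
  n <- as.integer(hi_res); f <- as.integer(config$filters)
  cm <- as.integer(channels)
  # 5x5 kernels: two layers span 9x9, wide enough to deconvolve the blockwise
  # downsampling footprint
  plan <- conv_plan(n, n, 5L, stride = 1L, pad = 2L)
  params <- with_seed(derive_seed(config$seed, "srinit"), list(
    c1 = conv_par(5L, cm + 1L, f), c2 = conv_par(5L, f, f),
    c3 = conv_par(5L, f, cm)))
  params$c3$W[] <- 0  # zero-init the head: the untrained model is exactly bilinear
  structure(list(params = params, plan = plan, hi_res = n,
                 scale_factor = as.integer(scale_factor), channels = cm,
                 filters = f, config = config, trained = FALSE,
                 losses = NULL), class = "sr_model")
}

#' @export
print.sr_model <- function(x, ...) {
  cat(sprintf("<sr_model> %dx upsampling to %dx%d, %d channels, %s\n",
              x$scale_factor, x$hi_res, x$hi_res, x$channels,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

sr_forward <- function(sr, lowch, mag) {
  base <- bilinear_upsample(lowch, sr$scale_factor)
  x0 <- array(c(base, mag), dim = c(dim(mag), sr$channels + 1L))
  f1 <- conv_fwd(x0, sr$params$c1, sr$plan); r1 <- lrelu_fwd(f1$y)
  f2 <- conv_fwd(r1$y, sr$params$c2, sr$plan); r2 <- lrelu_fwd(f2$y)
  f3 <- conv_fwd(r2$y, sr$params$c3, sr$plan)
  list(y = base + f3$y, cache = list(f1 = f1, r1 = r1, f2 = f2, r2 = r2,
                                     f3 = f3))
}

sr_backward <- function(sr, dy, cache) {
  b3 <- conv_bwd(dy, sr$params$c3, cache$f3$cache)
  dh2 <- lrelu_bwd(b3$dx, cache$r2$cache)
  b2 <- conv_bwd(dh2, sr$params$c2, cache$f2$cache)
  dh1 <- lrelu_bwd(b2$dx, cache$r1$cache)
  b1 <- conv_bwd(dh1, sr$params$c1, cache$f1$cache)
  list(c1 = list(W = b1$dW, b = b1$db), c2 = list(W = b2$dW, b = b2$db),
       c3 = list(W = b3$dW, b = b3$db))
}

#' Apply the super-resolution model to a low-resolution map
#'
#' @param sr an [sr_model()].
#' @param lowres_map complex low-resolution map (matrix or `coils x h x w`).
#' @param magnitude full-resolution magnitude matrix.
#' @return full-resolution complex map of the same kind as the input.
#' @export
sr_apply <- function(sr, lowres_map, magnitude) {
  stopifnot(inherits(sr, "sr_model"))
  lowch <- map_to_channels(lowres_map)
  if (dim(lowch)[3L] != sr$channels) stop("map channel count mismatch")
  if (!all(dim(magnitude) == sr$hi_res)) stop("magnitude resolution mismatch")
  if (dim(lowch)[1L] * sr$scale_factor != sr$hi_res)
    stop("low-res grid times scale_factor must equal the full resolution")
  y <- sr_forward(sr, lowch, magnitude)$y
  channels_to_map(y, if (sr$channels == 2L) "phase" else "csm")
}

#' Train the conditional super-resolution network
#'
#' Minimises the L1 reconstruction error of the upsampled map against the
#' ground-truth full-resolution map.
#'
#' @param pairs nonempty list of `list(lowres =, magnitude =, hires =)`
#'   entries (complex maps; magnitude at full resolution).
#' @param config an [sr_train_config()].
#' @return trained [sr_model()] with a `$losses` data frame.
#' @export
train_superres <- function(pairs, config = sr_train_config()) {
  if (length(pairs) < 1L) stop("need at least one training pair")
  low1 <- map_to_channels(pairs[[1L]]$lowres)
  n <- nrow(pairs[[1L]]$magnitude)
  factor <- n %/% dim(low1)[1L]
  if (dim(low1)[1L] * factor != n) stop("inconsistent scale factor")
  for (p in pairs) {
    if (nrow(map_to_channels(p$lowres)) * factor != nrow(p$magnitude))
      stop("inconsistent scale factor across pairs")
  }
  sr <- sr_model(hi_res = n, scale_factor = factor,
                 channels = dim(low1)[3L], config = config)
  lows <- lapply(pairs, function(p) map_to_channels(p$lowres))
  his <- lapply(pairs, function(p) map_to_channels(p$hires))
  mags <- lapply(pairs, function(p) p$magnitude)
  state <- adam_init(sr$params)
  hist <- numeric(config$steps)
  with_seed(derive_seed(config$seed, "srtrain"), {
    for (step in seq_len(config$steps)) {
      idx <- sample.int(length(pairs), min(config$batch, length(pairs)),
                        replace = TRUE)
      gg <- NULL; loss <- 0
      for (b in idx) {
        fw <- sr_forward(sr, lows[[b]], mags[[b]])
        resid <- fw$y - his[[b]]
        loss <- loss + mean(abs(resid))
        gg <- grad_add(gg, sr_backward(sr, sign(resid) / length(resid),
                                       fw$cache))
      }
      loss <- loss / length(idx)
      if (!is.finite(loss)) stop("NaN/Inf loss at step ", step)
      hist[step] <- loss
      up <- adam_update(sr$params, grad_scale(gg, 1 / length(idx)), state,
                        lr = config$lr)
      sr$params <- up$params
      if (config$weight_decay > 0) {
        shrink <- 1 - config$weight_decay
        for (nm in names(sr$params)) sr$params[[nm]]$W <- sr$params[[nm]]$W * shrink
      }
      state <- up$state
    }
  })
  sr$trained <- TRUE
  sr$losses <- data.frame(step = seq_len(config$steps), rec = hist)
  sr
}

#' Sample a new full-resolution map for a magnitude image
#'
#' Draws a latent vector from the standard normal prior, decodes it at low
#' resolution conditioned on the (block-averaged) magnitude, and upsamples
#' with the super-resolution network conditioned on the full-resolution
#' magnitude. Reproducible per seed.
#'
#' @param model a trained [aae_model()].
#' @param sr a trained [sr_model()] (its scale factor links the two
#'   resolutions).
#' @param magnitude full-resolution magnitude matrix.
#' @param seed integer seed for the latent draw.
#' @return full-resolution complex map (matrix for phase, `coils x H x W`
#'   for CSM).
#' @export
sample_map <- function(model, sr, magnitude, seed = 1L) {
  stopifnot(inherits(model, "aae_model"), inherits(sr, "sr_model"))
  if (!isTRUE(model$trained) || !isTRUE(sr$trained))
    stop("sample_map requires trained models")
  z <- with_seed(derive_seed(seed, "z"), stats::rnorm(model$latent_dim))
  maglr <- downsample_map(magnitude, sr$scale_factor)
  low <- decode(model, maglr, z)
  sr_apply(sr, low, magnitude)
}

#' Train a full map generator (AAE plus super-resolution) from slices
#'
#' Convenience wrapper for the two-stage generative pipeline: block-average
#' the full-resolution training maps to the operating resolution, train the
#' adversarial auto-encoder there, then train the super-resolution network on
#' (low-res map, full-res magnitude, full-res map) triples.
#'
#' @param slices list of `list(magnitude =, map =)` pairs at full resolution.
#' @param factor downsampling factor between full and operating resolution
#'   (default 4).
#' @param aae_config an [aae_train_config()].
#' @param sr_config an [sr_train_config()].
#' @return list with elements `aae` and `sr` (a generator bundle, as used by
#'   [synthetic_pool()]).
#' @export
train_map_generator <- function(slices, factor = 4L,
                                aae_config = aae_train_config(),
                                sr_config = sr_train_config()) {
  lowset <- lapply(slices, function(s) list(
    magnitude = downsample_map(s$magnitude, factor),
    map = downsample_map(s$map, factor)))
  aae <- train_aae(lowset, aae_config)
  pairs <- lapply(seq_along(slices), function(i) list(
    lowres = lowset[[i]]$map, magnitude = slices[[i]]$magnitude,
    hires = slices[[i]]$map))
  sr <- train_superres(pairs, sr_config)
  list(aae = aae, sr = sr)
}
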