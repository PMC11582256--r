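# Compact unrolled variational network for undersampled Cartesian
# reconstruction: cascades alternate a learned image-space convolutional
# regulariser with a data-consistency gradient step through the acquisition
# operator A x = mask * F (CSM_j * x). Coil sensitivity maps are estimated
# classically from the calibration lines of the undersampled input. The
# network is trained to maximise mSSIM against the RSS ground truth; all
# backward passes are hand-derived (the data-consistency step is self-adjoint
# as a real-linear operator, so its adjoint is itself).

#' Configuration for the reconstruction network and its training
#'
#' The paper-scale protocol (batch size 1, 200 batches per epoch, 1000
#' epochs) is configurable; tests and examples use far smaller schedules.
#'
#' @param cascades number of unrolled refinement blocks.
#' @param filters regulariser channel width.
#' @param epochs,batches_per_epoch,batch_size training schedule.
#' @param lr Adam learning rate.
#' @param augment optional [augmentation_config()]; `NULL` disables
#'   augmentation.
#' @param seed master seed for weight initialisation and the sampling stream.
#' @return list of class `recon_config`.
#' @export
recon_config <- function(cascades = 4L, filters = 16L, epochs = 1L,
                         batches_per_epoch = 300L, batch_size = 1L,
                         lr = 1e-3, augment = NULL, seed = 1L) {
  stopifnot(cascades >= 1L, epochs >= 0L)
  structure(as.list(environment()), class = "recon_config")
}

#' Construct an (untrained) unrolled variational reconstruction network
#'
#' @param shape `c(ky, kx)` image size the network operates on.
#' @param config a [recon_config()].
#' @return object of class `recon_model`.
#' @export
recon_model <- function(shape, config = recon_config()) {
  n <- as.integer(shape[1L]); m <- as.integer(shape[2L])
  f <- as.integer(config$filters)
  plan <- conv_plan(n, m, 3L, stride = 1L, pad = 1L)
  params <- with_seed(derive_seed(config$seed, "reconinit"), {
    casc <- lapply(seq_len(config$cascades), function(i) list(
      c1 = conv_par(3L, 2L, f), c2 = conv_par(3L, f, f),
      c3 = conv_par(3L, f, 2L), eta = 1))
    names(casc) <- paste0("cascade", seq_len(config$cascades))
    casc
  })
  structure(list(params = params, plan = plan, shape = c(n, m),
                 cascades = as.integer(config$cascades), filters = f,
                 config = config, trained = FALSE, losses = NULL),
            class = "recon_model")
}

#' @export
print.recon_model <- function(x, ...) {
  cat(sprintf("<recon_model> %d cascades, %d filters, %dx%d, %s\n",
              x$cascades, x$filters, x$shape[1L], x$shape[2L],
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# acquisition operator and its adjoint, fixed (mask, csm)
op_A <- function(x, masklines, csmdat) {
  d <- dim(csmdat)
  k <- array(0 + 0i, dim = d)
  for (j in seq_len(d[1L])) {
    kj <- fft2c(csmdat[j, , ] * x)
    kj[!masklines, ] <- 0 + 0i
    k[j, , ] <- kj
  }
  k
}

op_At <- function(k, masklines, csmdat) {
  d <- dim(csmdat)
  acc <- matrix(0 + 0i, d[2L], d[3L])
  for (j in seq_len(d[1L])) {
    kj <- k[j, , ]
    kj[!masklines, ] <- 0 + 0i
    acc <- acc + Conj(csmdat[j, , ]) * ifft2c(kj)
  }
  acc
}

cplx_to_ch <- function(x) array(c(Re(x), Im(x)), dim = c(dim(x), 2L))
ch_to_cplx <- function(ch) matrix(complex(real = ch[, , 1L], imaginary = ch[, , 2L]),
                                  dim(ch)[1L], dim(ch)[2L])

reg_forward <- function(par, plan, x) {
  ch <- cplx_to_ch(x)
  f1 <- conv_fwd(ch, par$c1, plan); r1 <- lrelu_fwd(f1$y)
  f2 <- conv_fwd(r1$y, par$c2, plan); r2 <- lrelu_fwd(f2$y)
  f3 <- conv_fwd(r2$y, par$c3, plan)
  list(y = ch_to_cplx(f3$y), cache = list(f1 = f1, r1 = r1, f2 = f2,
                                          r2 = r2, f3 = f3))
}

reg_backward <- function(par, gbar, cache) {
  dy <- cplx_to_ch(gbar)
  b3 <- conv_bwd(dy, par$c3, cache$f3$cache)
  dh2 <- lrelu_bwd(b3$dx, cache$r2$cache)
  b2 <- conv_bwd(dh2, par$c2, cache$f2$cache)
  dh1 <- lrelu_bwd(b2$dx, cache$r1$cache)
  b1 <- conv_bwd(dh1, par$c1, cache$f1$cache)
  list(grads = list(c1 = list(W = b1$dW, b = b1$db),
                    c2 = list(W = b2$dW, b = b2$db),
                    c3 = list(W = b3$dW, b = b3$db)),
       dx = ch_to_cplx(b1$dx))
}

recon_forward <- function(model, y, masklines, csmdat) {
  aty <- op_At(y, masklines, csmdat)
  x <- aty  # zero-filled, coil-combined start
  caches <- vector("list", model$cascades)
  for (i in seq_len(model$cascades)) {
    par <- model$params[[i]]
    dc <- op_At(op_A(x, masklines, csmdat), masklines, csmdat) - aty
    rg <- reg_forward(par, model$plan, x)
    caches[[i]] <- list(x = x, dc = dc, reg = rg$cache)
    x <- x - par$eta * dc + rg$y
  }
  list(x = x, mag = abs(x), caches = caches)
}

# backward through the cascades; dmag is d(loss)/d|x|
recon_backward <- function(model, fw, dmag, masklines, csmdat) {
  x <- fw$x
  ax <- abs(x)
  safe <- pmax(ax, 1e-12)
  gbar <- complex(real = dmag * Re(x) / safe, imaginary = dmag * Im(x) / safe)
  gbar <- matrix(gbar, nrow(x), ncol(x))
  grads <- vector("list", model$cascades)
  for (i in rev(seq_len(model$cascades))) {
    par <- model$params[[i]]
    cc <- fw$caches[[i]]
    deta <- -sum(Re(gbar) * Re(cc$dc) + Im(gbar) * Im(cc$dc))
    rb <- reg_backward(par, gbar, cc$reg)
    # adjoint of (I - eta A^H A): self-adjoint real-linear operator
    aha <- op_At(op_A(gbar, masklines, csmdat), masklines, csmdat)
    gbar <- gbar - par$eta * aha + rb$dx
    grads[[i]] <- c(rb$grads, list(eta = deta))
  }
  names(grads) <- names(model$params)
  grads
}

#' Reconstruct a magnitude image from undersampled k-space
#'
#' Estimates coil sensitivity maps from the calibration lines of the input,
#' then runs the unrolled network. Deterministic for fixed weights.
#'
#' @param model a [recon_model()] (trained or freshly initialised).
#' @param undersampled complex array `coils x ky x kx` with unsampled lines
#'   zeroed.
#' @param mask the [make_mask()] used for undersampling.
#' @return non-negative magnitude matrix `ky x kx`.
#' @export
reconstruct <- function(model, undersampled, mask) {
  stopifnot(inherits(model, "recon_model"), inherits(mask, "undersampling_mask"))
  if (!all(dim(undersampled)[2:3] == model$shape))
    stop("input shape does not match the model's training configuration")
  csm <- estimate_csm(undersampled, calib_lines = mask$calib_width)
  recon_forward(model, undersampled, mask$lines, csm$data)$mag
}

#' Zero-filled baseline reconstruction
#'
#' Root-sum-of-squares of the inverse Fourier transform of the undersampled
#' k-space — the no-learning baseline every trained model must beat.
#'
#' @inheritParams reconstruct
#' @return magnitude matrix.
#' @export
zero_filled <- function(undersampled) rss_combine(coil_ifft2c(undersampled))

#' Train the reconstruction network
#'
#' Per step: draw a fully sampled training sample (real or synthetic) from
#' the sampler, optionally augment it, undersample it with the mask, run the
#' forward model, and take an Adam step on `1 - mSSIM` between the
#' reconstruction and the RSS ground truth.
#'
#' @param sampler function of one integer argument (the draw seed) returning
#'   `list(kspace =, target =)` with fully sampled raw data; typically a
#'   closure over [draw_training_sample()].
#' @param mask an [make_mask()].
#' @param config a [recon_config()]; `epochs = 0` returns the initialised
#'   model untouched.
#' @return trained [recon_model()] with `$losses` (per-step `1 - mSSIM`).
#' @export
train_recon <- function(sampler, mask, config = recon_config()) {
  probe <- sampler(derive_seed(config$seed, "probe"))
  model <- recon_model(dim(probe$kspace)[2:3], config)
  steps <- config$epochs * config$batches_per_epoch
  if (steps == 0L) return(model)
  state <- adam_init(model$params)
  hist <- numeric(steps)
  for (step in seq_len(steps)) {
    gg <- NULL; loss <- 0
    for (b in seq_len(config$batch_size)) {
      sseed <- derive_seed(config$seed, "draw", (step - 1L) * config$batch_size + b)
      smp <- sampler(sseed)
      if (!is.null(config$augment))
        smp <- augment(smp, config$augment, seed = derive_seed(sseed, "aug"))
      y <- apply_undersampling(smp$kspace, mask)
      csm <- estimate_csm(y, calib_lines = mask$calib_width)
      fw <- recon_forward(model, y, mask$lines, csm$data)
      sg <- ssim_loss_grad(fw$mag, smp$target,
                           data_range = max(smp$target))
      loss <- loss + sg$value
      gg <- grad_add(gg, recon_backward(model, fw, sg$grad, mask$lines,
                                        csm$data))
    }
    loss <- loss / config$batch_size
    if (!is.finite(loss)) stop("NaN/Inf loss at step ", step)
    hist[step] <- loss
    up <- adam_update(model$params, grad_scale(gg, 1 / config$batch_size),
                      state, lr = config$lr)
    model$params <- up$params
    state <- up$state
  }
  model$trained <- TRUE
  model$losses <- data.frame(step = seq_len(steps), loss = hist)
  model
}
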