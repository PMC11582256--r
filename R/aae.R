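# Bi-directional conditional adversarial auto-encoder for complex-valued
# maps (phase or coil sensitivities), conditioned on a magnitude image.
# Complex maps are handled as interleaved (Re, Im) real channels to avoid
# angle-wrapping discontinuities: 2 channels for a phase map, 2*coils for
# sensitivity maps.

map_to_channels <- function(map) {
  if (is.matrix(map)) {
    array(c(Re(map), Im(map)), dim = c(dim(map), 2L))
  } else if (length(dim(map)) == 3L) {
    d <- dim(map)  # coils x H x W
    ch <- array(0, dim = c(d[2L], d[3L], 2L * d[1L]))
    for (j in seq_len(d[1L])) {
      ch[, , 2L * j - 1L] <- Re(map[j, , ])
      ch[, , 2L * j] <- Im(map[j, , ])
    }
    ch
  } else stop("map must be a complex matrix or coils x H x W array")
}

channels_to_map <- function(ch, target) {
  d <- dim(ch)
  if (target == "phase") {
    matrix(complex(real = ch[, , 1L], imaginary = ch[, , 2L]), d[1L], d[2L])
  } else {
    nc <- d[3L] %/% 2L
    out <- array(0 + 0i, dim = c(nc, d[1L], d[2L]))
    for (j in seq_len(nc))
      out[j, , ] <- matrix(complex(real = ch[, , 2L * j - 1L],
                                   imaginary = ch[, , 2L * j]), d[1L], d[2L])
    out
  }
}

#' Anti-aliased downsampling of maps by block averaging
#'
#' Reduces a map to the low resolution the auto-encoder operates at (default
#' fourfold, e.g. 320 -> 80) by averaging non-overlapping `factor x factor`
#' blocks of the real and imaginary parts.
#'
#' @param map real or complex matrix, or complex `coils x H x W` array.
#' @param factor integer downsampling factor; the grid must be divisible by
#'   it.
#' @return the reduced map, same type as the input.
#' @export
downsample_map <- function(map, factor = 4L) {
  block_mean <- function(x) {
    n <- nrow(x); m <- ncol(x)
    if (n %% factor != 0L || m %% factor != 0L)
      stop("grid is not divisible by the downsampling factor")
    B1 <- matrix(0, n, n %/% factor)
    B1[cbind(seq_len(n), rep(seq_len(n %/% factor), each = factor))] <- 1 / factor
    B2 <- matrix(0, m, m %/% factor)
    B2[cbind(seq_len(m), rep(seq_len(m %/% factor), each = factor))] <- 1 / factor
    t(B1) %*% x %*% B2
  }
  if (is.matrix(map)) {
    if (is.complex(map)) block_mean(Re(map)) + 1i * block_mean(Im(map))
    else block_mean(map)
  } else if (length(dim(map)) == 3L) {
    d <- dim(map)
    out <- array(0 + 0i, dim = c(d[1L], d[2L] %/% factor, d[3L] %/% factor))
    for (j in seq_len(d[1L]))
      out[j, , ] <- block_mean(Re(map[j, , ])) + 1i * block_mean(Im(map[j, , ]))
    out
  } else stop("unsupported map shape")
}

#' Training configuration for the adversarial auto-encoder
#'
#' @param latent_dim latent vector length (default 4).
#' @param filters base convolutional channel width.
#' @param w_rec,w_adv,w_rev loss weights for the forward (L1) reconstruction,
#'   the non-saturating adversarial loss on encoded latents, and the reverse
#'   latent-consistency (L2) loss.
#' @param lr,disc_lr Adam learning rates for the auto-encoder and the latent
#'   discriminator.
#' @param steps,batch optimisation steps and minibatch size.
#' @param seed master seed; weight initialisation, data order, and latent
#'   draws are derived from it.
#' @return list of class `aae_train_config`.
#' @export
aae_train_config <- function(latent_dim = 4L, filters = 16L,
                             w_rec = 1, w_adv = 0.05, w_rev = 0.5,
                             lr = 2e-3, disc_lr = 2e-3,
                             steps = 500L, batch = 8L, seed = 1L) {
  stopifnot(latent_dim >= 1L, w_rec >= 0, w_adv >= 0, w_rev >= 0)
  structure(as.list(environment()), class = "aae_train_config")
}

#' Construct an (untrained) conditional adversarial auto-encoder
#'
#' Encoder: strided convolutional stack on the channel-concatenated
#' (magnitude, map) input ending in a dense layer of size `latent_dim`.
#' Decoder: strided convolutional stack on the magnitude with the latent
#' vector broadcast and concatenated at the bottleneck, followed by
#' upsampling convolutions back to the map channels. Latent discriminator: a
#' 3-layer dense network on the latent vector alone.
#'
#' @param resolution operating (low-res) grid size; must be divisible by 4.
#' @param target `"phase"` (2 channels) or `"csm"` (`2*n_coils` channels).
#' @param n_coils coil count, required for `target = "csm"`.
#' @param config an [aae_train_config()].
#' @return object of class `aae_model` with `$trained = FALSE`.
#' @export
aae_model <- function(resolution = 80L, target = c("phase", "csm"),
                      n_coils = NULL, config = aae_train_config()) {
  target <- match.arg(target)
  stopifnot(resolution %% 4L == 0L, resolution >= 8L)
  cm <- if (target == "phase") 2L else {
    if (is.null(n_coils)) stop("n_coils required for csm target")
    2L * as.integer(n_coils)
  }
  n <- as.integer(resolution); f <- as.integer(config$filters)
  L <- as.integer(config$latent_dim)
  plans <- list(
    e1 = conv_plan(n, n, 3L, stride = 2L, pad = 1L),
    e2 = conv_plan(n %/% 2L, n %/% 2L, 3L, stride = 2L, pad = 1L),
    d3 = conv_plan(n %/% 4L, n %/% 4L, 3L, stride = 1L, pad = 1L),
    d4 = conv_plan(n %/% 2L, n %/% 2L, 3L, stride = 1L, pad = 1L),
    d5 = conv_plan(n, n, 3L, stride = 1L, pad = 1L))
  nb <- (n %/% 4L)^2
  params <- with_seed(derive_seed(config$seed, "init"), list(
    enc = list(c1 = conv_par(3L, 1L + cm, f), c2 = conv_par(3L, f, 2L * f),
               fc = dense_par(nb * 2L * f, L)),
    dec = list(c1 = conv_par(3L, 1L, f), c2 = conv_par(3L, f, 2L * f),
               c3 = conv_par(3L, 2L * f + L, 2L * f),
               c4 = conv_par(3L, 2L * f, f), c5 = conv_par(3L, f, cm)),
    disc = list(d1 = dense_par(L, 32L), d2 = dense_par(32L, 32L),
                d3 = dense_par(32L, 1L))))
  structure(list(params = params, plans = plans, latent_dim = L, target = target,
                 channels = cm, resolution = n, filters = f, config = config,
                 trained = FALSE, losses = NULL), class = "aae_model")
}

#' @export
print.aae_model <- function(x, ...) {
  cat(sprintf("<aae_model> target=%s, %d channels, %dx%d, latent %d, %s\n",
              x$target, x$channels, x$resolution, x$resolution, x$latent_dim,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- forward / backward graphs ---------------------------------------------

enc_forward <- function(model, mag, mapch) {
  p <- model$params$enc; pl <- model$plans
  x0 <- array(c(mag, mapch), dim = c(dim(mag), 1L + model$channels))
  f1 <- conv_fwd(x0, p$c1, pl$e1); r1 <- lrelu_fwd(f1$y)
  f2 <- conv_fwd(r1$y, p$c2, pl$e2); r2 <- lrelu_fwd(f2$y)
  flat <- as.vector(r2$y)
  fz <- dense_fwd(flat, p$fc)
  list(z = fz$y, cache = list(f1 = f1, r1 = r1, f2 = f2, r2 = r2,
                              flat = flat, hdim = dim(r2$y)))
}

enc_backward <- function(model, dz, cache) {
  p <- model$params$enc
  bz <- dense_bwd(dz, p$fc, cache$flat)
  dh2 <- array(bz$dx, dim = cache$hdim)
  dh2 <- lrelu_bwd(dh2, cache$r2$cache)
  b2 <- conv_bwd(dh2, p$c2, cache$f2$cache)
  dh1 <- lrelu_bwd(b2$dx, cache$r1$cache)
  b1 <- conv_bwd(dh1, p$c1, cache$f1$cache)
  dmap <- b1$dx[, , -1L, drop = FALSE]
  list(grads = list(c1 = list(W = b1$dW, b = b1$db),
                    c2 = list(W = b2$dW, b = b2$db),
                    fc = list(W = bz$dW, b = bz$db)),
       dmap = dmap)
}

dec_forward <- function(model, mag, z) {
  p <- model$params$dec; pl <- model$plans
  m0 <- array(mag, dim = c(dim(mag), 1L))
  f1 <- conv_fwd(m0, p$c1, pl$e1); r1 <- lrelu_fwd(f1$y)
  f2 <- conv_fwd(r1$y, p$c2, pl$e2); r2 <- lrelu_fwd(f2$y)
  nb <- dim(r2$y)[1L]
  zb <- array(rep(z, each = nb * nb), dim = c(nb, nb, length(z)))
  x3 <- array(c(r2$y, zb), dim = c(nb, nb, dim(r2$y)[3L] + length(z)))
  f3 <- conv_fwd(x3, p$c3, pl$d3); r3 <- lrelu_fwd(f3$y)
  u4 <- upsample2_fwd(r3$y)
  f4 <- conv_fwd(u4, p$c4, pl$d4); r4 <- lrelu_fwd(f4$y)
  u5 <- upsample2_fwd(r4$y)
  f5 <- conv_fwd(u5, p$c5, pl$d5)
  list(y = f5$y, cache = list(f1 = f1, r1 = r1, f2 = f2, r2 = r2,
                              f3 = f3, r3 = r3, f4 = f4, r4 = r4, f5 = f5,
                              nb = nb, nch2 = dim(r2$y)[3L], L = length(z)))
}

dec_backward <- function(model, dy, cache) {
  p <- model$params$dec
  b5 <- conv_bwd(dy, p$c5, cache$f5$cache)
  du4b <- upsample2_bwd(b5$dx)
  dh4 <- lrelu_bwd(du4b, cache$r4$cache)
  b4 <- conv_bwd(dh4, p$c4, cache$f4$cache)
  du3b <- upsample2_bwd(b4$dx)
  dh3 <- lrelu_bwd(du3b, cache$r3$cache)
  b3 <- conv_bwd(dh3, p$c3, cache$f3$cache)
  nch2 <- cache$nch2
  dh2 <- b3$dx[, , seq_len(nch2), drop = FALSE]
  dzb <- b3$dx[, , nch2 + seq_len(cache$L), drop = FALSE]
  dz <- apply(dzb, 3L, sum)
  dh2 <- lrelu_bwd(dh2, cache$r2$cache)
  b2 <- conv_bwd(dh2, p$c2, cache$f2$cache)
  dh1 <- lrelu_bwd(b2$dx, cache$r1$cache)
  b1 <- conv_bwd(dh1, p$c1, cache$f1$cache)
  list(grads = list(c1 = list(W = b1$dW, b = b1$db),
                    c2 = list(W = b2$dW, b = b2$db),
                    c3 = list(W = b3$dW, b = b3$db),
                    c4 = list(W = b4$dW, b = b4$db),
                    c5 = list(W = b5$dW, b = b5$db)),
       dz = dz)
}

disc_forward <- function(model, z) {
  p <- model$params$disc
  f1 <- dense_fwd(z, p$d1); r1 <- lrelu_fwd(f1$y)
  f2 <- dense_fwd(r1$y, p$d2); r2 <- lrelu_fwd(f2$y)
  f3 <- dense_fwd(r2$y, p$d3)
  list(s = f3$y, cache = list(z = z, f1 = f1, r1 = r1, f2 = f2, r2 = r2))
}

disc_backward <- function(model, ds, cache) {
  p <- model$params$disc
  b3 <- dense_bwd(ds, p$d3, cache$r2$y)
  dh2 <- lrelu_bwd(b3$dx, cache$r2$cache)
  b2 <- dense_bwd(dh2, p$d2, cache$r1$y)
  dh1 <- lrelu_bwd(b2$dx, cache$r1$cache)
  b1 <- dense_bwd(dh1, p$d1, cache$z)
  list(grads = list(d1 = list(W = b1$dW, b = b1$db),
                    d2 = list(W = b2$dW, b = b2$db),
                    d3 = list(W = b3$dW, b = b3$db)),
       dz = b1$dx)
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- public operations ------------------------------------------------------

check_res <- function(model, mag) {
  if (!all(dim(mag) == model$resolution))
    stop("input resolution ", paste(dim(mag), collapse = "x"),
         " does not match the model's operating resolution ", model$resolution)
}

#' Encode a (magnitude, map) pair into a latent vector
#'
#' Deterministic for fixed weights and inputs; the latent length equals the
#' configured latent dimensionality (default 4).
#'
#' @param model an [aae_model()].
#' @param magnitude magnitude matrix at the model's operating resolution.
#' @param map complex map (matrix for phase, `coils x H x W` for CSM) at the
#'   same resolution.
#' @return numeric latent vector.
#' @export
encode <- function(model, magnitude, map) {
  stopifnot(inherits(model, "aae_model"))
  check_res(model, magnitude)
  ch <- map_to_channels(map)
  if (dim(ch)[3L] != model$channels) stop("map channel count mismatch")
  enc_forward(model, magnitude, ch)$z
}

#' Decode a latent vector into a map
#'
#' Deterministic for fixed weights; the output has 2 channels (one complex
#' map) for a phase model and `2 * n_coils` channels for a CSM model.
#'
#' @inheritParams encode
#' @param z numeric latent vector of length `latent_dim`.
#' @return complex map (matrix for phase, `coils x H x W` array for CSM).
#' @export
decode <- function(model, magnitude, z) {
  stopifnot(inherits(model, "aae_model"))
  check_res(model, magnitude)
  if (length(z) != model$latent_dim)
    stop("latent vector length ", length(z), " != latent_dim ", model$latent_dim)
  channels_to_map(dec_forward(model, magnitude, z)$y, model$target)
}

#' Regenerate a map through the full auto-encoder
#'
#' Applies `decode(encode(map))`; for a trained model the output should be a
#' close reconstruction of the input map. The relative L2 error against the
#' input is attached as attribute `"rel_l2"`.
#'
#' @inheritParams encode
#' @param map ground-truth map at operating resolution.
#' @return regenerated map with attribute `rel_l2`.
#' @export
regenerate <- function(model, magnitude, map) {
  if (!isTRUE(model$trained))
    warning("regenerating through an untrained model")
  out <- decode(model, magnitude, encode(model, magnitude, map))
  rel <- sqrt(sum(abs(out - map)^2) / max(sum(abs(map)^2), 1e-30))
  attr(out, "rel_l2") <- rel
  out
}

#' Train the bi-directional conditional adversarial auto-encoder
#'
#' Jointly optimises (a) the forward L1 reconstruction of the map, (b) a
#' non-saturating adversarial loss pushing encoded latents toward a standard
#' normal (the discriminator acts on latents only and its adversarial
#' gradient reaches the encoder only), and (c) the reverse-path latent
#' consistency `encode(decode(z)) ~ z` for latents sampled from the prior,
#' which promotes a one-to-one latent-to-map relationship.
#'
#' @param dataset nonempty list of `list(magnitude =, map =)` pairs at the
#'   operating (low) resolution.
#' @param config an [aae_train_config()].
#' @param target `"phase"` or `"csm"` (inferred from the first map when
#'   missing).
#' @return trained [aae_model()] with a `$losses` data frame (per-step
#'   forward reconstruction, adversarial, reverse-consistency, and
#'   discriminator losses).
#' @export
train_aae <- function(dataset, config = aae_train_config(), target = NULL) {
  if (length(dataset) < 2L) stop("need at least 2 training pairs")
  first <- dataset[[1L]]
  if (is.null(target))
    target <- if (is.matrix(first$map)) "phase" else "csm"
  n_coils <- if (target == "csm") dim(first$map)[1L] else NULL
  n <- nrow(first$magnitude)
  model <- aae_model(resolution = n, target = target, n_coils = n_coils,
                     config = config)
  if (config$w_rec == 0 && config$w_adv == 0 && config$w_rev == 0) {
    model$trained <- TRUE
    model$losses <- data.frame(step = integer(), rec = numeric(),
                               adv = numeric(), rev = numeric(),
                               disc = numeric())
    return(model)
  }
  chans <- lapply(dataset, function(d) map_to_channels(d$map))
  mags <- lapply(dataset, function(d) d$magnitude)
  L <- model$latent_dim
  gen_state <- adam_init(model$params[c("enc", "dec")])
  disc_state <- adam_init(model$params$disc)
  hist <- matrix(0, config$steps, 4L)
  with_seed(derive_seed(config$seed, "train"), {
    for (step in seq_len(config$steps)) {
      idx <- sample.int(length(dataset), config$batch, replace = TRUE)
      gg <- NULL; dg <- NULL
      lrec <- ladv <- lrev <- ldisc <- 0
      for (b in idx) {
        mag <- mags[[b]]; x <- chans[[b]]
        ef <- enc_forward(model, mag, x)
        df <- dec_forward(model, mag, ef$z)
        resid <- df$y - x
        lrec <- lrec + mean(abs(resid))
        dxhat <- config$w_rec * sign(resid) / length(resid)
        bd1 <- dec_backward(model, dxhat, df$cache)
        dz <- bd1$dz
        if (config$w_adv > 0) {
          sf <- disc_forward(model, ef$z)
          ladv <- ladv + softplus(-sf$s)
          badv <- disc_backward(model, -sigmoid(-sf$s) * config$w_adv, sf$cache)
          dz <- dz + badv$dz
        }
        be1 <- enc_backward(model, dz, ef$cache)
        encg <- be1$grads; decg <- bd1$grads
        if (config$w_rev > 0) {
          zs <- stats::rnorm(L)
          dg2 <- dec_forward(model, mag, zs)
          eg2 <- enc_forward(model, mag, dg2$y)
          lrev <- lrev + mean((eg2$z - zs)^2)
          dzr <- config$w_rev * 2 * (eg2$z - zs) / L
          be2 <- enc_backward(model, dzr, eg2$cache)
          bd2 <- dec_backward(model, be2$dmap, dg2$cache)
          encg <- grad_add(encg, be2$grads)
          decg <- grad_add(decg, bd2$grads)
        }
        gg <- grad_add(gg, list(enc = encg, dec = decg))
        if (config$w_adv > 0) {
          zp <- stats::rnorm(L)
          sp <- disc_forward(model, zp)
          sfx <- disc_forward(model, ef$z)
          ldisc <- ldisc + softplus(-sp$s) + softplus(sfx$s)
          bp <- disc_backward(model, -sigmoid(-sp$s), sp$cache)
          bf <- disc_backward(model, sigmoid(sfx$s), sfx$cache)
          dg <- grad_add(dg, grad_add(bp$grads, bf$grads))
        }
      }
      nb <- length(idx)
      losses <- c(lrec, ladv, lrev, ldisc) / nb
      if (any(!is.finite(losses)))
        stop("NaN/Inf loss at step ", step, ": ",
             paste(round(losses, 4), collapse = ", "))
      hist[step, ] <- losses
      up <- adam_update(model$params[c("enc", "dec")], grad_scale(gg, 1 / nb),
                        gen_state, lr = config$lr)
      model$params$enc <- up$params$enc
      model$params$dec <- up$params$dec
      gen_state <- up$state
      if (config$w_adv > 0) {
        upd <- adam_update(model$params$disc, grad_scale(dg, 1 / nb),
                           disc_state, lr = config$disc_lr)
        model$params$disc <- upd$params
        disc_state <- upd$state
      }
    }
  })
  model$trained <- TRUE
  model$losses <- data.frame(step = seq_len(config$steps), rec = hist[, 1L],
                             adv = hist[, 2L], rev = hist[, 3L],
                             disc = hist[, 4L])
  model
}
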