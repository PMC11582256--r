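as_csm_array <- function(csm) {
  if (inherits(csm, "csm")) csm$data
  else { assert_multicoil(csm, "CSM"); csm }
}

as_cov_matrix <- function(phi) {
  if (inherits(phi, "noise_cov")) phi$matrix else noise_cov(phi)$matrix
}

# phi = F F^H factor via eigen-decomposition (works for PSD Hermitian input)
cov_factor <- function(phi) {
  e <- eigen((phi + Conj(t(phi))) / 2)
  if (min(Re(e$values)) < -1e-10) stop("noise covariance is not PSD")
  e$vectors %*% diag(sqrt(pmax(Re(e$values), 0)), nrow(phi))
}

#' Synthesize multi-coil raw k-space data
#'
#' The central synthesis equation: per-coil images are formed as
#' `M * (P/|P|) * CSM_j`, transformed to k-space with the orthonormal centered
#' FFT, and complex Gaussian noise with coil covariance `phi` — independent
#' across k-space samples, correlated across coils — is added. With the
#' orthonormal transform this is statistically identical to adding the same
#' noise in the image domain. `P/|P|` is defined as 1 where `|P| < 1e-12`.
#' Real and imaginary noise parts each have covariance `phi/2`, so the total
#' complex variance per coil equals `diag(phi)`.
#'
#' @param M non-negative magnitude matrix.
#' @param P complex phase map (any magnitude; unit-normalized internally).
#' @param csm a [csm_maps()] object or a plain complex `coils x ky x kx`
#'   array (generated maps need not have exactly unit RSS).
#' @param phi a [noise_cov()] object or Hermitian PSD matrix; use a zero
#'   matrix for noiseless synthesis.
#' @param seed integer seed for the noise draw (required when `phi` is
#'   nonzero).
#' @return complex array `coils x ky x kx` of raw k-space data.
#' @export
synthesize_raw <- function(M, P, csm, phi, seed = NULL) {
  assert_magnitude(M)
  cs <- as_csm_array(csm)
  phim <- as_cov_matrix(phi)
  d <- dim(cs)
  if (!all(dim(M) == d[2:3]) || !all(dim(P) == d[2:3]))
    stop("shape mismatch among M, P, and CSM")
  if (nrow(phim) != d[1L]) stop("noise covariance dimension must equal coil count")
  ap <- abs(P)
  unitP <- ifelse(ap < 1e-12, 1 + 0i, P / ap)
  obj <- M * unitP
  coil_imgs <- array(0 + 0i, dim = d)
  for (j in seq_len(d[1L])) coil_imgs[j, , ] <- obj * cs[j, , ]
  k <- coil_fft2c(coil_imgs)
  if (any(phim != 0)) {
    if (is.null(seed)) stop("a seed is required for the noise draw")
    L <- cov_factor(phim)
    npix <- d[2L] * d[3L]
    noise <- with_seed(seed, {
      Z <- matrix(complex(real = stats::rnorm(d[1L] * npix),
                          imaginary = stats::rnorm(d[1L] * npix)) / sqrt(2),
                  d[1L], npix)
      L %*% Z
    })
    k <- k + array(aperm(array(t(noise), dim = c(d[2L], d[3L], d[1L])),
                         c(3L, 1L, 2L)), dim = d)
  }
  k
}

#' Sinusoidal phase map baseline
#'
#' The classical non-learned alternative to generated phase maps: a
#' unit-magnitude complex map with phase `A * sin(2*pi*(fx*x + fy*y) + psi)`,
#' where `x`, `y` are pixel coordinates in units of the field of view and the
#' parameters are drawn uniformly from the configured ranges.
#'
#' @param shape `c(ky, kx)` grid size.
#' @param amp_range amplitude range in radians (default 0 to `2*pi`).
#' @param freq_range spatial frequency range in cycles per FOV (default 0-2).
#' @param seed integer seed.
#' @return complex matrix with `|map| == 1` everywhere; the drawn parameters
#'   are attached as attribute `"params"`.
#' @export
sinusoidal_phase <- function(shape, amp_range = c(0, 2 * pi),
                             freq_range = c(0, 2), seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  with_seed(seed, {
    A <- stats::runif(1, amp_range[1L], amp_range[2L])
    fx <- stats::runif(1, freq_range[1L], freq_range[2L])
    fy <- stats::runif(1, freq_range[1L], freq_range[2L])
    psi <- stats::runif(1, 0, 2 * pi)
    y <- matrix((seq_len(shape[1L]) - 1L) / shape[1L], shape[1L], shape[2L])
    x <- matrix((seq_len(shape[2L]) - 1L) / shape[2L], shape[1L], shape[2L],
                byrow = TRUE)
    theta <- A * sin(2 * pi * (fx * x + fy * y) + psi)
    structure(exp(1i * theta), params = list(A = A, fx = fx, fy = fy, psi = psi))
  })
}

#' Sample a noise covariance from a pool
#'
#' Uniform, seed-reproducible draw of one element from a pool of noise
#' covariances taken from real training slices.
#'
#' @param pool nonempty list of [noise_cov()] objects.
#' @param seed integer seed.
#' @return one element of `pool`.
#' @export
sample_noise_cov <- function(pool, seed) {
  if (length(pool) == 0L) stop("empty noise covariance pool")
  pool[[with_seed(seed, sample.int(length(pool), 1L))]]
}

#' Pools of synthetic and real raw training data
#'
#' A `synthetic_pool` holds everything needed to generate raw data on the fly:
#' magnitude images, trained phase and CSM generator bundles (see
#' [train_map_generator()]), and a pool of noise covariances from real
#' training slices. A `real_pool` holds stored fully sampled raw slices with
#' their RSS targets and (for the ablation modes) their decomposed map
#' triplets.
#'
#' @param magnitudes list of magnitude matrices.
#' @param phase_model,csm_model generator bundles with elements `aae` and
#'   `sr` (see [train_map_generator()]).
#' @param noise_cov_pool list of [noise_cov()] objects.
#' @return object of class `synthetic_pool`.
#' @export
synthetic_pool <- function(magnitudes, phase_model, csm_model, noise_cov_pool) {
  stopifnot(length(magnitudes) > 0L, length(noise_cov_pool) > 0L)
  structure(list(magnitudes = magnitudes, phase_model = phase_model,
                 csm_model = csm_model, noise_cov_pool = noise_cov_pool),
            class = "synthetic_pool")
}

#' @rdname synthetic_pool
#' @param scans list of [scan_record()]s whose slices populate the pool.
#' @param triplets optional list (per scan) of lists (per slice) of
#'   [map_triplet()]s; computed via [decompose_scan()] when absent and ground
#'   truth is unavailable.
#' @export
real_pool <- function(scans, triplets = NULL) {
  entries <- list()
  for (i in seq_along(scans)) {
    sc <- scans[[i]]
    tr <- if (!is.null(triplets)) triplets[[i]]
          else if (!is.null(sc$ground_truth)) sc$ground_truth
          else decompose_scan(sc)
    for (s in seq_len(n_slices(sc))) {
      entries[[length(entries) + 1L]] <- list(
        kspace = sc$kspace[[s]],
        target = if (!is.null(sc$magnitude)) sc$magnitude[[s]]
                 else rss_combine(coil_ifft2c(sc$kspace[[s]])),
        triplet = tr[[s]])
    }
  }
  if (length(entries) == 0L) stop("real pool is empty")
  structure(list(slices = entries), class = "real_pool")
}

#' Draw the pool choice for one training sample
#'
#' Bernoulli(`mix_fraction`) choice between the synthetic and real raw-data
#' pools, reproducible per seed. [draw_training_sample()] uses this draw to
#' pick its branch; exposing it separately allows the sampling fraction to be
#' audited over many seeds without synthesizing data.
#'
#' @param mix_fraction probability of the synthetic pool.
#' @param seed integer seed.
#' @return `"synthetic"` or `"real"`.
#' @export
sample_pool_choice <- function(mix_fraction, seed) {
  stopifnot(mix_fraction >= 0, mix_fraction <= 1)
  if (with_seed(derive_seed(seed, "branch"), stats::runif(1) < mix_fraction))
    "synthetic" else "real"
}

training_modes <- function() {
  c("real", "synthetic-mix", "real-phase-real-csm", "real-phase-synth-csm",
    "sinusoidal-phase-synth-csm", "synth-phase-real-csm")
}

#' Draw one training sample from the synthetic/real mixture
#'
#' With probability `mix_fraction` (default 0.75) the sample is generated on
#' the fly from the synthetic pool: a magnitude image is drawn, phase and CSM
#' maps are sampled from the trained generators (or substituted by real /
#' sinusoidal maps in the ablation modes), a noise covariance is drawn from
#' the real-slice pool, and raw data are synthesized. Otherwise a stored real
#' raw slice is returned. Mode `"real"` always returns real data.
#'
#' @param synth a [synthetic_pool()] (ignored in mode `"real"`).
#' @param real a [real_pool()].
#' @param mix_fraction probability of the synthetic branch.
#' @param mode one of `r paste0('"', training_modes(), '"', collapse = ", ")`.
#' @param seed integer seed; the full stream is reproducible from
#'   (pools, seed).
#' @return list with `kspace` (fully sampled raw slice), `target` (RSS ground
#'   truth) and `source` (`"real"` or `"synthetic"`).
#' @export
draw_training_sample <- function(synth, real, mix_fraction = 0.75,
                                 mode = "synthetic-mix", seed = 1L) {
  mode <- match.arg(mode, training_modes())
  if (mode == "real") mix_fraction <- 0
  if (mix_fraction > 0 && is.null(synth)) stop("synthetic pool required")
  if (mix_fraction < 1 && (is.null(real) || length(real$slices) == 0L))
    stop("real pool required")
  use_synth <- sample_pool_choice(mix_fraction, seed) == "synthetic"
  if (!use_synth) {
    idx <- with_seed(derive_seed(seed, "realidx"),
                     sample.int(length(real$slices), 1L))
    e <- real$slices[[idx]]
    return(list(kspace = e$kspace, target = e$target, source = "real"))
  }
  im <- with_seed(derive_seed(seed, "magidx"),
                  sample.int(length(synth$magnitudes), 1L))
  M <- synth$magnitudes[[im]]
  # ablation modes substitute maps from a decomposed real slice
  ref <- NULL
  if (mode %in% c("real-phase-real-csm", "real-phase-synth-csm",
                  "synth-phase-real-csm")) {
    ridx <- with_seed(derive_seed(seed, "refidx"),
                      sample.int(length(real$slices), 1L))
    ref <- real$slices[[ridx]]$triplet
    M <- ref$magnitude
  }
  P <- switch(mode,
    "real-phase-real-csm" = , "real-phase-synth-csm" = ref$phase,
    "sinusoidal-phase-synth-csm" =
      sinusoidal_phase(dim(M), seed = derive_seed(seed, "sin")),
    sample_map(synth$phase_model$aae, synth$phase_model$sr, M,
               seed = derive_seed(seed, "pmap")))
  if (mode %in% c("sinusoidal-phase-synth-csm")) {
    CS <- sample_map(synth$csm_model$aae, synth$csm_model$sr, M,
                     seed = derive_seed(seed, "cmap"))
  } else {
    CS <- switch(mode,
      "real-phase-real-csm" = , "synth-phase-real-csm" = ref$csm$data,
      sample_map(synth$csm_model$aae, synth$csm_model$sr, M,
                 seed = derive_seed(seed, "cmap")))
  }
  if (is.matrix(P) && !is.complex(P)) storage.mode(P) <- "complex"
  phi <- sample_noise_cov(synth$noise_cov_pool, derive_seed(seed, "ncov"))
  k <- synthesize_raw(M, P, CS, phi, seed = derive_seed(seed, "noise"))
  list(kspace = k, target = rss_combine(coil_ifft2c(k)), source = "synthetic")
}
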