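#' Phantom specification
#'
#' Describes the family of synthetic multi-coil scans used throughout the test
#' suite and examples: piecewise-smooth elliptical "head" magnitude images,
#' spatially smooth complex phase maps (low-order polynomial plus a
#' low-frequency sinusoid), smooth coil sensitivity lobes placed around the
#' object with linear phase gradients and exactly unit root-sum-of-squares,
#' and coil-correlated Gaussian noise with a known covariance. The defaults
#' (64x64 grid, 4 coils, ~1% noise) keep full property sweeps and smoke
#' training runs fast on one CPU; paper-scale geometry (320x320, 16 coils) is
#' a parameter change.
#'
#' @param grid image size (square), at least 16.
#' @param n_coils number of receive coils.
#' @param n_ellipses range (min, max) of interior ellipses.
#' @param intensity range of interior ellipse intensity offsets.
#' @param poly_coef_max largest magnitude of the polynomial phase
#'   coefficients (radians over the field of view).
#' @param sin_amp_max largest sinusoidal phase amplitude (radians).
#' @param sin_freq_max largest sinusoidal spatial frequency (cycles / FOV).
#' @param phase_grad_max bound on the per-pixel phase step (radians) the
#'   generated maps must respect.
#' @param csm_width Gaussian width of the coil lobes (FOV units).
#' @param csm_phase_max largest per-coil linear phase ramp (radians / FOV).
#' @param noise_sigma per-coil noise standard deviation (complex, total).
#' @param noise_rho neighbour-coil noise correlation (AR(1) profile).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = 64L, n_coils = 4L,
                         n_ellipses = c(3L, 6L), intensity = c(-0.35, 0.45),
                         poly_coef_max = 2.5, sin_amp_max = 1.0,
                         sin_freq_max = 1.5, phase_grad_max = 1.0,
                         csm_width = 0.9, csm_phase_max = 2.5,
                         noise_sigma = 0.01, noise_rho = 0.2) {
  stopifnot(grid >= 16L, n_coils >= 1L, noise_sigma >= 0,
            noise_rho >= 0, noise_rho < 1)
  structure(as.list(environment()), class = "phantom_spec")
}

# run expr under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# deterministic seed fan-out: one master seed, distinct child per (tag, index)
derive_seed <- function(master, tag, index = 0L) {
  tagv <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(master) * 48271 + tagv * 7919 + index) %% 2147483647)
}

# pixel-centre coordinates in [-1, 1]
grid_coords <- function(n) {
  v <- seq(-1, 1, length.out = n)
  list(y = matrix(v, n, n), x = matrix(v, n, n, byrow = TRUE))
}

#' Generate a phantom magnitude image
#'
#' A large centred "skull" ellipse with several overlapping interior ellipses
#' of varying intensity, on an exactly zero background (so the image corners
#' are signal-free, as the background noise-estimation contract requires).
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; the same seed reproduces the image bitwise.
#' @return non-negative `grid x grid` matrix.
#' @export
make_magnitude <- function(spec, seed) {
  with_seed(seed, {
    n <- spec$grid
    g <- grid_coords(n)
    ax <- stats::runif(1, 0.42, 0.52); ay <- stats::runif(1, 0.42, 0.52)
    base <- stats::runif(1, 0.6, 0.9)
    inside <- (g$x / ax)^2 + (g$y / ay)^2 <= 1
    m <- matrix(0, n, n)
    m[inside] <- base
    ne <- sample(spec$n_ellipses[1L]:spec$n_ellipses[2L], 1L)
    for (i in seq_len(ne)) {
      cx <- stats::runif(1, -0.25, 0.25); cy <- stats::runif(1, -0.25, 0.25)
      ea <- stats::runif(1, 0.05, 0.22); eb <- stats::runif(1, 0.05, 0.22)
      th <- stats::runif(1, 0, pi)
      dv <- stats::runif(1, spec$intensity[1L], spec$intensity[2L])
      xr <- (g$x - cx) * cos(th) + (g$y - cy) * sin(th)
      yr <- -(g$x - cx) * sin(th) + (g$y - cy) * cos(th)
      e <- (xr / ea)^2 + (yr / eb)^2 <= 1
      m[e & inside] <- m[e & inside] + dv
    }
    pmax(m, 0)
  })
}

#' Generate a smooth phantom phase map
#'
#' Unit-magnitude complex map whose phase is a low-order 2D polynomial plus a
#' single low-frequency sinusoid, with coefficients scaled so the per-pixel
#' phase step stays below `spec$phase_grad_max`.
#'
#' @inheritParams make_magnitude
#' @return complex `grid x grid` matrix with `|map| == 1` everywhere.
#' @export
make_phase <- function(spec, seed) {
  with_seed(seed, {
    n <- spec$grid
    g <- grid_coords(n)
    cmax <- spec$poly_coef_max
    co <- stats::runif(6, -cmax, cmax)
    theta <- co[1] + co[2] * g$x + co[3] * g$y + co[4] * g$x * g$y +
      0.5 * co[5] * g$x^2 + 0.5 * co[6] * g$y^2
    amp <- stats::runif(1, 0, spec$sin_amp_max)
    fx <- stats::runif(1, -spec$sin_freq_max, spec$sin_freq_max)
    fy <- stats::runif(1, -spec$sin_freq_max, spec$sin_freq_max)
    psi <- stats::runif(1, 0, 2 * pi)
    theta <- theta + amp * sin(pi * (fx * g$x + fy * g$y) + psi)
    # rescale if the finite-difference bound is exceeded
    gmax <- max(abs(diff(theta)), abs(t(diff(t(theta)))))
    if (gmax > spec$phase_grad_max) theta <- theta * (spec$phase_grad_max / gmax)
    exp(1i * theta)
  })
}

#' Generate smooth phantom coil sensitivity maps
#'
#' One Gaussian sensitivity lobe per coil, centred just outside the object
#' perimeter at equally spaced angles (with jitter), each with a linear phase
#' ramp pointing at its coil. The stack is normalized so the
#' root-sum-of-squares across coils is exactly 1 at every pixel.
#'
#' @inheritParams make_magnitude
#' @return a [csm_maps()] object with full support.
#' @export
make_csms <- function(spec, seed) {
  with_seed(seed, {
    n <- spec$grid; nc <- spec$n_coils
    g <- grid_coords(n)
    data <- array(0 + 0i, dim = c(nc, n, n))
    angles <- 2 * pi * (seq_len(nc) - 1L) / nc + stats::runif(nc, -0.2, 0.2)
    for (j in seq_len(nc)) {
      r <- stats::runif(1, 1.1, 1.3)
      cx <- r * cos(angles[j]); cy <- r * sin(angles[j])
      w <- spec$csm_width * stats::runif(1, 0.85, 1.15)
      mag <- exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * w^2))
      ramp <- stats::runif(1, 0.2, 1) * spec$csm_phase_max
      ph <- ramp * (g$x * cos(angles[j]) + g$y * sin(angles[j])) +
        stats::runif(1, 0, 2 * pi)
      data[j, , ] <- mag * exp(1i * ph)
    }
    rss <- rss_combine(data)
    for (j in seq_len(nc)) data[j, , ] <- data[j, , ] / rss
    csm_maps(data, support = matrix(TRUE, n, n))
  })
}

# AR(1)-correlated coil noise covariance, scaled per coil
phantom_noise_cov <- function(spec, seed) {
  with_seed(seed, {
    nc <- spec$n_coils
    sd_j <- spec$noise_sigma * stats::runif(nc, 0.8, 1.2)
    R <- spec$noise_rho^abs(outer(seq_len(nc), seq_len(nc), "-"))
    noise_cov(matrix(complex(real = outer(sd_j, sd_j) * R), nc, nc))
  })
}

#' Generate a full phantom scan with known ground truth
#'
#' Per slice: draws magnitude, phase, and sensitivity maps, forms the
#' noiseless coil images `M * P * CSM_j`, transforms them to k-space, and adds
#' coil-correlated complex Gaussian noise with a known covariance. The true
#' [map_triplet()]s are retained in `$ground_truth` so calibration, synthesis,
#' and generative modules can be tested against exact oracles.
#'
#' @inheritParams make_magnitude
#' @param n_slices number of slices.
#' @param split split label for the record.
#' @return a [scan_record()] with `$ground_truth`.
#' @export
make_scan <- function(spec, n_slices = 1L, seed = 1L,
                      split = c("train", "validation", "test")) {
  split <- match.arg(split)
  kspace <- vector("list", n_slices)
  magnitude <- vector("list", n_slices)
  truth <- vector("list", n_slices)
  for (s in seq_len(n_slices)) {
    m <- make_magnitude(spec, derive_seed(seed, "mag", s))
    p <- make_phase(spec, derive_seed(seed, "phase", s))
    cs <- make_csms(spec, derive_seed(seed, "csm", s))
    phi <- phantom_noise_cov(spec, derive_seed(seed, "ncov", s))
    truth[[s]] <- map_triplet(m, p, cs, phi)
    k <- synthesize_raw(m, p, cs, phi, seed = derive_seed(seed, "noise", s))
    kspace[[s]] <- k
    magnitude[[s]] <- rss_combine(coil_ifft2c(k))
  }
  scan_record(kspace, magnitude, scanner = "phantom", split = split,
              scale_factor = 1, ground_truth = truth)
}

#' Generate a deterministic multi-scan phantom dataset
#'
#' Split sizes follow a documented rounding rule: `floor` for validation and
#' test, remainder to train (so fractions `(0.8, 0.05, 0.15)` of 20 scans give
#' a 16/1/3 split). Per-scan seeds are derived from the master seed, so the
#' dataset is reproducible scan by scan.
#'
#' @inheritParams make_magnitude
#' @param n_scans total number of scans.
#' @param split_fractions length-3 numeric (train, validation, test) summing
#'   to 1.
#' @param slices_per_scan slices per scan.
#' @return list of [scan_record()]s.
#' @export
make_dataset <- function(spec, n_scans, split_fractions = c(0.8, 0.05, 0.15),
                         slices_per_scan = 2L, seed = 1L) {
  stopifnot(length(split_fractions) == 3L,
            abs(sum(split_fractions) - 1) < 1e-8, n_scans >= 1L)
  n_val <- floor(split_fractions[2L] * n_scans)
  n_test <- floor(split_fractions[3L] * n_scans)
  n_train <- n_scans - n_val - n_test
  splits <- rep(c("train", "validation", "test"), c(n_train, n_val, n_test))
  lapply(seq_len(n_scans), function(i) {
    make_scan(spec, n_slices = slices_per_scan,
              seed = derive_seed(seed, "scan", i), split = splits[i])
  })
}
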