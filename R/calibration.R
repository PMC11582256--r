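#' Coil sensitivity map container
#'
#' Holds complex sensitivity maps for all coils together with the boolean
#' support mask on which they are defined. Inside the support the
#' root-sum-of-squares across coils is 1 (to within `1e-6`); outside it the
#' maps are identically zero.
#'
#' @param data complex array `coils x ky x kx`.
#' @param support logical matrix `ky x kx`.
#' @return object of class `csm`.
#' @export
csm_maps <- function(data, support) {
  assert_multicoil(data, "CSM")
  d <- dim(data)
  stopifnot(is.logical(support), all(dim(support) == d[2:3]))
  rss <- rss_combine(data)
  if (any(abs(rss[support] - 1) > 1e-6))
    stop("CSM root-sum-of-squares must be 1 inside the support")
  if (any(rss[!support] != 0))
    stop("CSM must be zero outside the support")
  structure(list(data = data, support = support), class = "csm")
}

#' @export
print.csm <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<csm> %d coils, %dx%d, support %.1f%%\n", d[1L], d[2L], d[3L],
              100 * mean(x$support)))
  invisible(x)
}

#' Coil noise covariance
#'
#' The `coils x coils` Hermitian positive semi-definite covariance of complex
#' receiver noise, by convention the *total* complex variance per coil (real
#' and imaginary parts each carry half of the diagonal).
#'
#' @param matrix complex Hermitian PSD matrix.
#' @param source_region optional `c(row, col)` top-left corner of the
#'   background patch the estimate came from.
#' @return object of class `noise_cov`.
#' @export
noise_cov <- function(matrix, source_region = NULL) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (!is.complex(matrix)) storage.mode(matrix) <- "complex"
  herm_err <- max(abs(matrix - Conj(t(matrix))))
  if (herm_err > 1e-10) stop("noise covariance must be Hermitian (error ",
                             format(herm_err), ")")
  ev <- eigen((matrix + Conj(t(matrix))) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("noise covariance must be positive semi-definite")
  structure(list(matrix = matrix, source_region = source_region),
            class = "noise_cov")
}

#' Magnitude / phase / sensitivity / noise decomposition of one slice
#'
#' The four right-hand-side quantities of the raw-data synthesis equation
#' `raw = M * (P/|P|) * CSM + N(0, phi)` for a single slice.
#'
#' @param magnitude non-negative real matrix `M`.
#' @param phase complex matrix `P` (magnitude-carried; unit-normalized only
#'   inside the synthesis equation).
#' @param csm a [csm_maps()] object.
#' @param noise_cov a [noise_cov()] object whose dimension equals the coil
#'   count.
#' @return object of class `map_triplet`.
#' @export
map_triplet <- function(magnitude, phase, csm, noise_cov) {
  assert_magnitude(magnitude)
  stopifnot(inherits(csm, "csm"), inherits(noise_cov, "noise_cov"))
  d <- dim(magnitude)
  stopifnot(all(dim(phase) == d), all(dim(csm$data)[2:3] == d),
            nrow(noise_cov$matrix) == dim(csm$data)[1L])
  structure(list(magnitude = magnitude, phase = phase, csm = csm,
                 noise_cov = noise_cov), class = "map_triplet")
}

# central calibration block indices along an axis of length n (0-based start
# n/2 - w/2, matching the centered-FFT convention), returned 1-based
calib_range <- function(n, w) {
  start <- n %/% 2L - w %/% 2L
  (start + 1L):(start + w)
}

#' Estimate coil sensitivity maps from the calibration region
#'
#' Low-resolution coil images are formed from the central, fully sampled
#' k-space block (`calib_lines` wide along the phase-encoding axis, and the
#' same width along the readout axis for isotropic smoothing), apodized with a
#' Hamming window to suppress ringing. Each coil's low-pass image is divided
#' by their root-sum-of-squares, yielding unit-RSS maps on the support (pixels
#' where the low-pass RSS exceeds 5% of its maximum); the maps are zero
#' outside the support. As with any phase-sensitive estimator, the maps carry
#' a smooth reference phase shared by all coils — the decomposition of the
#' coil images into object phase and coil phase is only defined up to such a
#' common smooth field.
#'
#' @param kspace complex array `coils x ky x kx` of fully sampled data.
#' @param calib_lines width of the calibration block (>= 8).
#' @param support_threshold relative low-pass RSS threshold defining the
#'   support.
#' @return a [csm_maps()] object.
#' @export
estimate_csm <- function(kspace, calib_lines = 26L, support_threshold = 0.05) {
  assert_multicoil(kspace)
  d <- dim(kspace)
  if (calib_lines < 8L || calib_lines > min(d[2:3]))
    stop("calib_lines must be between 8 and the k-space extent")
  if (all(kspace == 0)) stop("degenerate input: all-zero k-space")
  wky <- calib_range(d[2L], calib_lines)
  wkx <- calib_range(d[3L], calib_lines)
  # Hamming apodization centred on the DC line (not the block centre): keeps
  # the effective low-pass kernel nearly real, so the maps pick up minimal
  # spurious phase from the window itself
  ham <- function(idx, n) {
    f <- idx - 1L - n %/% 2L
    0.54 + 0.46 * cos(pi * f / (calib_lines / 2))
  }
  apod <- outer(ham(wky, d[2L]), ham(wkx, d[3L]))
  lowres <- array(0 + 0i, dim = d)
  for (j in seq_len(d[1L])) {
    k <- matrix(0 + 0i, d[2L], d[3L])
    k[wky, wkx] <- kspace[j, wky, wkx] * apod
    lowres[j, , ] <- ifft2c(k)
  }
  rss <- rss_combine(lowres)
  support <- rss >= support_threshold * max(rss)
  maps <- array(0 + 0i, dim = d)
  for (j in seq_len(d[1L])) {
    mj <- matrix(0 + 0i, d[2L], d[3L])
    mj[support] <- lowres[j, , ][support] / rss[support]
    maps[j, , ] <- mj
  }
  csm_maps(maps, support)
}

#' Phase-sensitive coil combination
#'
#' Combines per-coil complex images into one complex image as the
#' sensitivity-weighted sum `sum_j conj(CSM_j) * x_j`. Where the maps are
#' exact (unit RSS), the magnitude equals the RSS combination and the phase is
#' the coil-combined object phase relative to the maps' reference phase.
#'
#' @param coil_images complex array `coils x ky x kx`.
#' @param csm a [csm_maps()] object of matching shape.
#' @return complex matrix `ky x kx`.
#' @export
phase_sensitive_combine <- function(coil_images, csm) {
  stopifnot(inherits(csm, "csm"))
  assert_multicoil(coil_images, "coil image stack")
  if (!all(dim(coil_images) == dim(csm$data)))
    stop("shape mismatch between coil images and CSM")
  d <- dim(coil_images)
  acc <- matrix(0 + 0i, d[2L], d[3L])
  for (j in seq_len(d[1L])) acc <- acc + Conj(csm$data[j, , ]) * coil_images[j, , ]
  acc
}

#' Normalize the global phase of coil sensitivity maps
#'
#' Divides all coils by the average phase of the first coil over the support
#' (computed as the argument of the support-masked mean of the unit-normalized
#' first-coil map — a circular mean, robust to angle wrapping), so maps are
#' phase-consistent across scans. Idempotent; magnitudes are untouched.
#'
#' @param csm a [csm_maps()] object; coil 1 must be nonzero somewhere on the
#'   support.
#' @return a [csm_maps()] object with mean first-coil phase 0.
#' @export
normalize_csm_phase <- function(csm) {
  stopifnot(inherits(csm, "csm"))
  c0 <- csm$data[1L, , ]
  sel <- csm$support & (abs(c0) > 0)
  if (!any(sel)) stop("empty support: cannot normalize CSM phase")
  theta <- Arg(mean(c0[sel] / abs(c0[sel])))
  csm_maps(csm$data * exp(-1i * theta), csm$support)
}

#' Estimate coil noise covariance from a background region
#'
#' Computes the complex sample covariance across coils of all pixels in a
#' square background patch of the coil images (mean-subtracted, normalized by
#' `n - 1`). When `region` is `NULL`, the patch is chosen deterministically as
#' the corner patch (among the four image corners) with minimal mean
#' root-sum-of-squares — a reproducible stand-in for manual background
#' selection.
#'
#' @param coil_images complex array `coils x ky x kx` (image domain).
#' @param region optional `c(row, col)` top-left corner (1-based) of the
#'   patch.
#' @param size patch side length (default 20).
#' @return a [noise_cov()] object.
#' @export
estimate_noise_cov <- function(coil_images, region = NULL, size = 20L) {
  assert_multicoil(coil_images, "coil image stack")
  d <- dim(coil_images)
  if (size > min(d[2:3])) stop("background region does not fit inside the grid")
  if (size * size < 2L * d[1L])
    stop("background region must contain at least 2x coils samples")
  corners <- list(c(1L, 1L), c(1L, d[3L] - size + 1L),
                  c(d[2L] - size + 1L, 1L), c(d[2L] - size + 1L, d[3L] - size + 1L))
  if (is.null(region)) {
    rss <- rss_combine(coil_images)
    score <- vapply(corners, function(cr) {
      mean(rss[cr[1L]:(cr[1L] + size - 1L), cr[2L]:(cr[2L] + size - 1L)])
    }, numeric(1))
    region <- corners[[which.min(score)]]
  }
  if (region[1L] < 1L || region[2L] < 1L ||
      region[1L] + size - 1L > d[2L] || region[2L] + size - 1L > d[3L])
    stop("background region out of bounds")
  rows <- region[1L]:(region[1L] + size - 1L)
  cols <- region[2L]:(region[2L] + size - 1L)
  X <- matrix(0 + 0i, d[1L], size * size)
  for (j in seq_len(d[1L])) X[j, ] <- as.vector(coil_images[j, rows, cols])
  Xc <- X - rowMeans(X)
  phi <- (Xc %*% Conj(t(Xc))) / (ncol(X) - 1L)
  phi <- (phi + Conj(t(phi))) / 2  # exact Hermitian symmetry
  noise_cov(phi, source_region = region)
}

#' Decompose a fully sampled scan into magnitude, phase, CSM, and noise
#'
#' Per slice: reconstructs coil images, estimates phase-normalized coil
#' sensitivity maps from the central calibration block, combines the coils
#' phase-sensitively, and estimates the background noise covariance. The
#' result is the per-slice [map_triplet()] `(M = |combined|, P = combined,
#' CSM, phi)` from which raw data can be resynthesized.
#'
#' @param scan a [scan_record()] with fully sampled k-space.
#' @param calib_lines calibration block width for [estimate_csm()].
#' @param noise_region_size background patch size for [estimate_noise_cov()].
#' @return list of [map_triplet()], one per slice.
#' @export
decompose_scan <- function(scan, calib_lines = 26L, noise_region_size = 20L) {
  stopifnot(inherits(scan, "scan_record"))
  lapply(scan$kspace, function(k) {
    imgs <- coil_ifft2c(k)
    cs <- normalize_csm_phase(estimate_csm(k, calib_lines))
    combined <- phase_sensitive_combine(imgs, cs)
    phi <- estimate_noise_cov(imgs, size = noise_region_size)
    map_triplet(magnitude = abs(combined), phase = combined, csm = cs,
                noise_cov = phi)
  })
}
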