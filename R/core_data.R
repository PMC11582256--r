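#' mrisynth: synthetic multi-coil raw MRI data generation
#'
#' Decomposes fully sampled multi-coil raw k-space into magnitude, phase, and
#' coil sensitivity maps; learns conditional generative models of the phase and
#' sensitivity maps; resynthesizes raw data from magnitude-only images; and
#' benchmarks undersampled deep-learning reconstruction trained on mixtures of
#' real and synthetic raw data.
#'
#' @useDynLib mrisynth, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# ---- validators for the array-backed domain types ---------------------------

assert_multicoil <- function(data, what = "k-space") {
  if (length(dim(data)) != 3L) stop(what, " must be a coils x ky x kx array")
  if (dim(data)[1L] < 1L) stop(what, " needs at least one coil")
  if (!all(is.finite(Re(data))) || !all(is.finite(Im(data))))
    stop("non-finite entries in ", what)
  invisible(data)
}

assert_magnitude <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("magnitude must be a real matrix")
  if (any(!is.finite(m))) stop("non-finite entries in magnitude")
  if (any(m < 0)) stop("magnitude must be non-negative")
  invisible(m)
}

# ---- root-sum-of-squares ----------------------------------------------------

#' Root-sum-of-squares coil combination
#'
#' Combines a stack of per-coil images into a magnitude image as the per-pixel
#' Euclidean norm across the coil axis: `sqrt(sum_j |x_j|^2)`. This is the
#' standard ground-truth reconstruction for fully sampled multi-coil data.
#'
#' @param coil_images complex array `coils x ky x kx`.
#' @return real non-negative matrix `ky x kx`.
#' @export
rss_combine <- function(coil_images) {
  assert_multicoil(coil_images, "coil image stack")
  d <- dim(coil_images)
  sq <- Re(coil_images)^2 + Im(coil_images)^2
  matrix(sqrt(colSums(matrix(sq, d[1L], d[2L] * d[3L]))), d[2L], d[3L])
}

#' Scale raw k-space data by a constant factor
#'
#' Raw scanner data have arbitrary (tiny) physical units; multiplying by a
#' constant factor (default `1e6`) brings coil-combined reconstructions near
#' unit intensity so that downstream network training and metric constants
#' operate on a sane scale.
#'
#' @param kspace complex array `coils x ky x kx` (or any complex array).
#' @param factor positive scale factor.
#' @return scaled array of the same shape.
#' @export
scale_raw <- function(kspace, factor = 1e6) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) || factor <= 0)
    stop("scale factor must be a single positive number")
  kspace * factor
}

# ---- ScanRecord -------------------------------------------------------------

#' Construct a multi-slice scan record
#'
#' A `scan_record` bundles the per-slice multi-coil k-space of one scan with
#' its per-slice magnitude reconstructions and acquisition metadata. It is the
#' in-memory form of the HDF5 container written by [write_scan()].
#'
#' @param kspace list of complex arrays `coils x ky x kx`, one per slice.
#' @param magnitude optional list of real matrices `ky x kx` (e.g. RSS
#'   reconstructions), one per slice.
#' @param scanner free-text scanner label.
#' @param split one of `"train"`, `"validation"`, `"test"`.
#' @param scale_factor the factor already applied to the raw data (see
#'   [scale_raw()]).
#' @param ground_truth optional list of [map_triplet()]s (phantom fixtures
#'   carry the true decomposition for oracle testing).
#' @return object of class `scan_record`.
#' @export
scan_record <- function(kspace, magnitude = NULL, scanner = "synthetic",
                        split = c("train", "validation", "test"),
                        scale_factor = 1, ground_truth = NULL) {
  split <- match.arg(split)
  if (!is.list(kspace) || length(kspace) == 0L)
    stop("kspace must be a nonempty list of per-slice arrays")
  dims <- vapply(kspace, function(k) dim(assert_multicoil(k)), integer(3))
  if (any(dims != dims[, 1L]))
    stop("all slices must share coil count and matrix size")
  if (!is.null(magnitude)) {
    stopifnot(length(magnitude) == length(kspace))
    lapply(magnitude, assert_magnitude)
  }
  structure(list(
    kspace = kspace, magnitude = magnitude,
    metadata = list(scanner = scanner, n_coils = dims[1L, 1L],
                    matrix_size = dims[2:3, 1L], scale_factor = scale_factor),
    split = split, ground_truth = ground_truth
  ), class = "scan_record")
}

#' @export
print.scan_record <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<scan_record> %d slice(s), %d coils, %dx%d, split=%s, scanner=%s\n",
              length(x$kspace), md$n_coils, md$matrix_size[1L], md$matrix_size[2L],
              x$split, md$scanner))
  invisible(x)
}

n_slices <- function(record) length(record$kspace)
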