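#' Construct a Cartesian undersampling mask
#'
#' The fourfold-acceleration scheme used for retrospective undersampling:
#' every `stride`-th line along the phase-encoding axis is sampled (offset 0
#' by default), plus a contiguous block of `calib_width` central calibration
#' lines for coil sensitivity estimation. For an even extent `n` the central
#' block occupies 0-based lines `[n/2 - w/2, n/2 + w/2)`, consistent with the
#' centered-FFT convention.
#'
#' @param ky_extent number of phase-encoding lines.
#' @param stride sampling stride (default 4).
#' @param calib_width width of the central calibration block (default 26).
#' @param offset 0-based offset of the regular stride pattern.
#' @return object of class `undersampling_mask` with logical `$lines`.
#' @export
make_mask <- function(ky_extent, stride = 4L, calib_width = 26L, offset = 0L) {
  stopifnot(stride >= 1L, ky_extent >= 1L)
  if (calib_width > ky_extent) stop("calib_width exceeds ky extent")
  lines <- rep(FALSE, ky_extent)
  lines[seq(offset + 1L, ky_extent, by = stride)] <- TRUE
  lines[calib_range(ky_extent, calib_width)] <- TRUE
  structure(list(lines = lines, stride = as.integer(stride),
                 calib_width = as.integer(calib_width),
                 offset = as.integer(offset)),
            class = "undersampling_mask")
}

#' @export
print.undersampling_mask <- function(x, ...) {
  cat(sprintf("<undersampling_mask> %d/%d lines sampled (acceleration %.2f), stride %d, %d calibration lines\n",
              sum(x$lines), length(x$lines), length(x$lines) / sum(x$lines),
              x$stride, x$calib_width))
  invisible(x)
}

#' Retrospectively undersample k-space
#'
#' Copies the sampled phase-encoding lines verbatim and zeroes all others,
#' simulating an accelerated acquisition from fully sampled data.
#'
#' @param kspace complex array `coils x ky x kx`.
#' @param mask an [make_mask()] object with `length(mask$lines) == ky`.
#' @return undersampled array of the same shape.
#' @export
apply_undersampling <- function(kspace, mask) {
  assert_multicoil(kspace)
  stopifnot(inherits(mask, "undersampling_mask"))
  if (length(mask$lines) != dim(kspace)[2L])
    stop("mask length does not match the ky extent")
  kspace[, !mask$lines, ] <- 0 + 0i
  kspace
}
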