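#' Centered orthonormal 2D Fourier transforms
#'
#' MRI raw data live in k-space; images are obtained by an inverse 2D discrete
#' Fourier transform. `fft2c()` maps an image to k-space and `ifft2c()` maps
#' k-space to an image. Both use the *centered* convention (the DC component
#' sits at the grid centre, index `n/2` in 0-based terms for an even axis of
#' length `n`) and *orthonormal* scaling (division by `sqrt(ky * kx)` in each
#' direction), so that total energy is preserved and white Gaussian noise has
#' identical statistics in both domains.
#'
#' @param x complex (or real) matrix, `ky x kx`, all entries finite.
#' @return complex matrix of the same dimensions.
#' @examples
#' img <- matrix(0, 8, 8); img[5, 5] <- 1   # centred impulse (0-based index 4)
#' k <- fft2c(img)                          # constant 1/8 everywhere
#' max(abs(ifft2c(k) - img))
#' @export
fft2c <- function(x) {
  x <- as_complex_matrix(x)
  ft <- fftshift2(stats::fft(ifftshift2(x)))
  ft / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  x <- as_complex_matrix(x)
  im <- fftshift2(stats::fft(ifftshift2(x), inverse = TRUE))
  im / sqrt(length(x))
}

as_complex_matrix <- function(x) {
  if (!is.matrix(x)) stop("input must be a 2D matrix")
  if (!all(is.finite(Re(x))) || !all(is.finite(Im(x))))
    stop("non-finite entries in input")
  if (any(dim(x) < 8L)) stop("grid must be at least 8x8")
  if (!is.complex(x)) storage.mode(x) <- "complex"
  x
}

# circular roll of indices 1..n by k positions (numpy-style)
roll_index <- function(n, k) ((seq_len(n) - 1L - k) %% n) + 1L

fftshift2 <- function(x) {
  d <- dim(x)
  x[roll_index(d[1L], d[1L] %/% 2L), roll_index(d[2L], d[2L] %/% 2L), drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  x[roll_index(d[1L], -(d[1L] %/% 2L)), roll_index(d[2L], -(d[2L] %/% 2L)), drop = FALSE]
}

# apply fft2c/ifft2c across the coil axis of a (coils x ky x kx) array
coilwise <- function(arr, fun) {
  stopifnot(length(dim(arr)) == 3L)
  out <- array(0 + 0i, dim = dim(arr))
  for (j in seq_len(dim(arr)[1L])) out[j, , ] <- fun(arr[j, , ])
  out
}

#' Transform multi-coil images to k-space and back
#'
#' Convenience wrappers applying [fft2c()] / [ifft2c()] to every coil of a
#' `coils x ky x kx` array.
#'
#' @param arr complex 3D array `coils x ky x kx`.
#' @return complex array of the same shape.
#' @export
coil_fft2c <- function(arr) coilwise(arr, fft2c)

#' @rdname coil_fft2c
#' @export
coil_ifft2c <- function(arr) coilwise(arr, ifft2c)
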