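# Mean structural similarity (mSSIM), with an analytic gradient for use as a
# training objective. Conventions follow the standard Wang et al. settings:
# 11-tap Gaussian window (sigma 1.5, truncated at 3.5 sigma), population
# (filtered) moments, stabilisation constants K1 = 0.01, K2 = 0.03, reflected
# edge handling, and a border crop of the filter radius before averaging.
# Smoothing is expressed as explicit 1-D matrices so the adjoint needed by
# the backward pass is the exact matrix transpose.

gauss_kernel <- function(sigma = 1.5, truncate = 3.5) {
  r <- floor(truncate * sigma + 0.5)
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w / sum(w)
}

# reflected (edge-repeating) index into 1..n
reflect_idx <- function(j, n) {
  m <- (j - 1L) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

# n x n smoothing matrix with reflected boundary
smooth_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  S <- matrix(0, n, n)
  for (o in -r:r) {
    src <- reflect_idx(seq_len(n) + o, n)
    S[cbind(seq_len(n), src)] <- S[cbind(seq_len(n), src)] + kernel[o + r + 1L]
  }
  S
}

ssim_terms <- function(x, y, Sr, Sc, C1, C2) {
  blur <- function(v) Sr %*% v %*% t(Sc)
  ux <- blur(x); uy <- blur(y)
  vx <- blur(x * x) - ux^2
  vy <- blur(y * y) - uy^2
  vxy <- blur(x * y) - ux * uy
  A1 <- 2 * ux * uy + C1; A2 <- 2 * vxy + C2
  B1 <- ux^2 + uy^2 + C1; B2 <- vx + vy + C2
  list(S = A1 * A2 / (B1 * B2), ux = ux, uy = uy, A1 = A1, A2 = A2,
       B1 = B1, B2 = B2)
}

#' Mean structural similarity index (mSSIM)
#'
#' Windowed perceptual similarity between two magnitude images, averaged over
#' all local windows after cropping the filter-radius border. Matches the
#' standard Gaussian-weighted SSIM (11x11 window, sigma 1.5, K1 = 0.01,
#' K2 = 0.03, population moments).
#'
#' @param x,y real matrices of the same shape.
#' @param data_range dynamic range of the data; by convention the maximum of
#'   the ground-truth volume. Defaults to the joint maximum of `x` and `y`
#'   (which keeps the metric symmetric).
#' @param sigma Gaussian window standard deviation.
#' @param K1,K2 stabilisation constants.
#' @return scalar in `[-1, 1]`.
#' @export
mssim <- function(x, y, data_range = NULL, sigma = 1.5,
                  K1 = 0.01, K2 = 0.03) {
  stopifnot(is.matrix(x), is.matrix(y))
  if (!all(dim(x) == dim(y))) stop("shape mismatch")
  kern <- gauss_kernel(sigma)
  r <- (length(kern) - 1L) %/% 2L
  if (2L * r + 1L > min(dim(x))) stop("window exceeds image extent")
  if (is.null(data_range)) data_range <- max(abs(c(x, y)))
  if (data_range <= 0) data_range <- 1
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  Sr <- smooth_matrix(nrow(x), kern); Sc <- smooth_matrix(ncol(x), kern)
  S <- ssim_terms(x, y, Sr, Sc, C1, C2)$S
  rows <- (r + 1L):(nrow(x) - r); cols <- (r + 1L):(ncol(x) - r)
  mean(S[rows, cols])
}

# value and gradient of loss = 1 - mSSIM(x, y) with respect to x
ssim_loss_grad <- function(x, y, data_range, sigma = 1.5,
                           K1 = 0.01, K2 = 0.03) {
  kern <- gauss_kernel(sigma)
  r <- (length(kern) - 1L) %/% 2L
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  Sr <- smooth_matrix(nrow(x), kern); Sc <- smooth_matrix(ncol(x), kern)
  tm <- ssim_terms(x, y, Sr, Sc, C1, C2)
  rows <- (r + 1L):(nrow(x) - r); cols <- (r + 1L):(ncol(x) - r)
  W <- matrix(0, nrow(x), ncol(x))
  W[rows, cols] <- -1 / (length(rows) * length(cols))  # d(1 - mean S)/dS
  # partials of S with respect to the filtered moments
  dS_dux <- 2 * tm$uy * tm$A2 / (tm$B1 * tm$B2) - tm$S * 2 * tm$ux / tm$B1
  dS_dvx <- -tm$S / tm$B2
  dS_dvxy <- 2 * tm$A1 / (tm$B1 * tm$B2)
  blur_t <- function(v) t(Sr) %*% v %*% Sc
  t1 <- W * (dS_dux - 2 * tm$ux * dS_dvx - tm$uy * dS_dvxy)
  t2 <- W * dS_dvx
  t3 <- W * dS_dvxy
  grad <- blur_t(t1) + 2 * x * blur_t(t2) + y * blur_t(t3)
  list(value = 1 - mean(tm$S[rows, cols]), grad = grad)
}
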