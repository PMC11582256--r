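# Physics-aware data augmentation: geometric transforms are applied in the
# image domain, identically to every coil image (complex, as separate
# Re/Im channels) and to the RSS ground truth, after which k-space is
# regenerated — so the augmented sample remains a consistent acquisition.

#' Augmentation configuration
#'
#' Each augmentation is enabled independently with probability `prob`
#' (default 0.5) and draws its parameters uniformly from the listed ranges:
#' integer pixel translation (±8 px), 90-degree rotations (0/90/180/270),
#' mirroring (x, y, or both), fine rotation (±10 degrees), zoom (90-110%),
#' and sub-pixel translation (±16 px).
#'
#' @param prob per-augmentation enable probability.
#' @param int_translate_max integer translation bound in pixels.
#' @param fine_rotate_max fine rotation bound in degrees.
#' @param zoom_range zoom factor range.
#' @param subpix_translate_max sub-pixel translation bound in pixels.
#' @return list of class `augmentation_config`.
#' @export
augmentation_config <- function(prob = 0.5, int_translate_max = 8,
                                fine_rotate_max = 10, zoom_range = c(0.9, 1.1),
                                subpix_translate_max = 16) {
  stopifnot(prob >= 0, prob <= 1, length(zoom_range) == 2L)
  structure(as.list(environment()), class = "augmentation_config")
}

#' Exact discrete image transforms
#'
#' `rotate90()` rotates a matrix counter-clockwise by `k` quarter turns;
#' `mirror_image()` flips along the x axis (columns), y axis (rows), or both;
#' `shift_image()` translates by whole pixels with zero fill. These commute
#' exactly with the root-sum-of-squares combination when applied per coil.
#'
#' @param img matrix (real or complex).
#' @param k number of quarter turns (any integer).
#' @param axis `"x"`, `"y"`, or `"both"`.
#' @param dy,dx integer shifts along rows / columns.
#' @return transformed matrix.
#' @export
rotate90 <- function(img, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  if (k == 0L) return(img)
  for (i in seq_len(k)) img <- t(img)[ncol(img):1L, , drop = FALSE]
  img
}

#' @rdname rotate90
#' @export
mirror_image <- function(img, axis = c("x", "y", "both")) {
  axis <- match.arg(axis)
  if (axis %in% c("x", "both")) img <- img[, ncol(img):1L, drop = FALSE]
  if (axis %in% c("y", "both")) img <- img[nrow(img):1L, , drop = FALSE]
  img
}

#' @rdname rotate90
#' @export
shift_image <- function(img, dy = 0L, dx = 0L) {
  out <- img
  out[] <- 0
  n <- nrow(img); m <- ncol(img)
  if (abs(dy) >= n || abs(dx) >= m) return(out)
  sr <- max(1L, 1L + dy):min(n, n + dy)
  sc <- max(1L, 1L + dx):min(m, m + dx)
  if (length(sr) > 0L && length(sc) > 0L)
    out[sr, sc] <- img[sr - dy, sc - dx]
  out
}

# bilinear resample of a real matrix under an affine map about the image
# centre: source = R(-theta) (p - t) / zoom; zero fill outside
affine_resample <- function(img, theta = 0, zoom = 1, ty = 0, tx = 0) {
  n <- nrow(img); m <- ncol(img)
  ci <- (n + 1) / 2; cj <- (m + 1) / 2
  gi <- matrix(seq_len(n) - ci, n, m)
  gj <- matrix(seq_len(m) - cj, n, m, byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  si <- (ct * (gi - ty) + st * (gj - tx)) / zoom + ci
  sj <- (-st * (gi - ty) + ct * (gj - tx)) / zoom + cj
  inside <- si >= 1 & si <= n & sj >= 1 & sj <= m
  v <- pracma::interp2(x = seq_len(m), y = seq_len(n), Z = img,
                       xp = pmin(pmax(as.vector(sj), 1), m),
                       yp = pmin(pmax(as.vector(si), 1), n),
                       method = "linear")
  out <- matrix(v, n, m)
  out[!inside] <- 0
  out
}

apply_transform_real <- function(img, tr) {
  if (!is.null(tr$int_shift)) img <- shift_image(img, tr$int_shift[1L], tr$int_shift[2L])
  if (!is.null(tr$rot90)) img <- rotate90(img, tr$rot90)
  if (!is.null(tr$mirror)) img <- mirror_image(img, tr$mirror)
  if (!is.null(tr$affine))
    img <- affine_resample(img, theta = tr$affine$theta, zoom = tr$affine$zoom,
                           ty = tr$affine$ty, tx = tr$affine$tx)
  img
}

apply_transform_complex <- function(img, tr) {
  re <- apply_transform_real(Re(img), tr)
  im <- apply_transform_real(Im(img), tr)
  matrix(complex(real = re, imaginary = im), nrow(re), ncol(re))
}

# draw the set of enabled transforms and their parameters
draw_transform <- function(config, seed) {
  with_seed(seed, {
    tr <- list()
    if (stats::runif(1) < config$prob)
      tr$int_shift <- sample(seq(-config$int_translate_max,
                                 config$int_translate_max), 2L, replace = TRUE)
    if (stats::runif(1) < config$prob)
      tr$rot90 <- sample(0:3, 1L)
    if (stats::runif(1) < config$prob)
      tr$mirror <- sample(c("x", "y", "both"), 1L)
    aff <- list(theta = 0, zoom = 1, ty = 0, tx = 0)
    any_aff <- FALSE
    if (stats::runif(1) < config$prob) {
      aff$theta <- stats::runif(1, -config$fine_rotate_max,
                                config$fine_rotate_max) * pi / 180
      any_aff <- TRUE
    }
    if (stats::runif(1) < config$prob) {
      aff$zoom <- stats::runif(1, config$zoom_range[1L], config$zoom_range[2L])
      any_aff <- TRUE
    }
    if (stats::runif(1) < config$prob) {
      aff$ty <- stats::runif(1, -config$subpix_translate_max,
                             config$subpix_translate_max)
      aff$tx <- stats::runif(1, -config$subpix_translate_max,
                             config$subpix_translate_max)
      any_aff <- TRUE
    }
    if (any_aff) tr$affine <- aff
    tr
  })
}

#' Augment a fully sampled raw slice and its ground truth
#'
#' Draws the enabled augmentations for this sample, applies the identical
#' spatial transform to every coil image (in the image domain, bilinear on
#' real and imaginary channels for the continuous transforms, exact index
#' operations for the discrete ones) and to the ground-truth image, and
#' regenerates k-space from the transformed coil images.
#'
#' @param sample list with `kspace` (`coils x ky x kx`) and `target`
#'   (real matrix).
#' @param config an [augmentation_config()].
#' @param seed integer seed; the same seed reproduces the augmentation.
#' @return list with transformed `kspace` and `target`.
#' @export
augment <- function(sample, config = augmentation_config(), seed = 1L) {
  stopifnot(inherits(config, "augmentation_config"))
  tr <- draw_transform(config, seed)
  if (length(tr) == 0L) return(sample[c("kspace", "target")])
  imgs <- coil_ifft2c(sample$kspace)
  d <- dim(imgs)
  out <- array(0 + 0i, dim = d)
  for (j in seq_len(d[1L])) out[j, , ] <- apply_transform_complex(imgs[j, , ], tr)
  list(kspace = coil_fft2c(out),
       target = apply_transform_real(sample$target, tr))
}
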