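#' Read and write scans in a FastMRI-style HDF5 container
#'
#' One file holds one scan: a complex 4-D dataset `"kspace"` with axes
#' `slices x coils x ky x kx` stored as the h5py-compatible compound `{r, i}`
#' type, an optional real dataset `"reconstruction_rss"`
#' (`slices x ky x kx`), and root attributes `"scanner"`, `"split"` and
#' `"scale_factor"`. The round trip through [write_scan()] / [read_scan()] is
#' lossless for the k-space values and metadata.
#'
#' @param record a [scan_record()].
#' @param path file path (`.h5`).
#' @return `read_scan()` returns a [scan_record()]; `write_scan()` returns
#'   `path` invisibly.
#' @export
write_scan <- function(record, path) {
  stopifnot(inherits(record, "scan_record"))
  md <- record$metadata
  ns <- n_slices(record)
  d <- dim(record$kspace[[1L]])  # coils, ky, kx
  buf <- array(0 + 0i, dim = c(d[3L], d[2L], d[1L], ns))
  for (s in seq_len(ns)) buf[, , , s] <- aperm(record$kspace[[s]], c(3L, 2L, 1L))
  rssbuf <- NULL
  if (!is.null(record$magnitude)) {
    rssbuf <- array(0, dim = c(d[3L], d[2L], ns))
    for (s in seq_len(ns)) rssbuf[, , s] <- t(record$magnitude[[s]])
  }
  .Call(C_h5_write_scan, path.expand(path), buf, rssbuf,
        as.character(md$scanner), record$split, as.double(md$scale_factor))
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- .Call(C_h5_read_scan, path.expand(path))
  kd <- dim(raw$kspace)  # kx, ky, coils, slices
  ns <- kd[4L]
  kspace <- vector("list", ns)
  for (s in seq_len(ns)) {
    sl <- array(raw$kspace[, , , s], dim = kd[1:3])
    kspace[[s]] <- aperm(sl, c(3L, 2L, 1L))
  }
  magnitude <- NULL
  if (!is.null(raw$rss)) {
    magnitude <- vector("list", ns)
    for (s in seq_len(ns)) magnitude[[s]] <- t(raw$rss[, , s])
  }
  scan_record(
    kspace = kspace, magnitude = magnitude,
    scanner = if (is.null(raw$scanner)) "unknown" else raw$scanner,
    split = if (is.null(raw$split)) "train" else raw$split,
    scale_factor = if (is.null(raw$scale_factor)) 1 else raw$scale_factor
  )
}
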