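# Minimal reader/writer for the IDX binary format used by the MNIST
# distribution, so the sequential classification front-end can optionally be
# run on real digit images. Nothing in the package depends on it.

#' Read an IDX-format array
#'
#' Parses the IDX binary format (magic number, big-endian dimension sizes,
#' unsigned-byte data) and returns the data as an array with the dimensions
#' reversed into column-major order (e.g. a 60000 x 28 x 28 image file
#' becomes a 28 x 28 x 60000 array).
#'
#' @param path file path.
#' @return numeric array.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (any(magic[1:2] != as.raw(0)) || magic[3] != as.raw(8))
    stop_invalid("not an unsigned-byte IDX file")
  ndim <- as.integer(magic[4])
  dims <- readBin(con, "integer", ndim, size = 4, endian = "big")
  dat <- readBin(con, "integer", prod(dims), size = 1, signed = FALSE)
  aperm(array(dat, rev(dims)))
}

#' Write an array in IDX format
#'
#' Inverse of [read_idx()] for unsigned-byte data (values are rounded and
#' clipped to 0..255).
#'
#' @param x numeric array or matrix.
#' @param path file path.
#' @export
write_idx <- function(x, path) {
  dims <- dim(x) %||% length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0, 0, 8, length(dims))), con)
  writeBin(as.integer(dims), con, size = 4, endian = "big")
  vals <- as.integer(pmin(pmax(round(aperm(array(x, dims))), 0), 255))
  writeBin(vals, con, size = 1)
  invisible(path)
}
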