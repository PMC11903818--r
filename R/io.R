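# raster I/O helpers: masks as 8-bit TIFF, gray maps and RGB as TIFF

#' Write / read a binary mask as TIFF
#' @param mask Binary matrix.
#' @param path Output path.
#' @return `path` / the mask matrix.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)),
                  path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' Write / read a single-channel float image (activation/density map)
#' @param x Numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @return `path` / the matrix.
#' @export
write_gray <- function(x, path) {
  tiff::writeTIFF(x, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_gray
#' @export
read_gray <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m
}

#' Write an RGB image as 8-bit TIFF
#' @param rgb Array `[H, W, 3]` in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(rgb, path) {
  tiff::writeTIFF(rgb, path, bits.per.sample = 8L)
  invisible(path)
}
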