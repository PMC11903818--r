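#' Hyperspectral cube container
#'
#' A `spectral_cube` bundles an absorbance array of dimension H x W x C with
#' its wavenumber axis and the physical pixel size. The default pixel size of
#' 4.25 um matches a 4x QCL-IR objective projecting a 2 x 2 mm field of view
#' onto a 480 x 480 microbolometer array.
#'
#' @param data Numeric array `[H, W, C]` of absorbance values (dimensionless).
#' @param axis A [make_wavenumber_axis()] object; `C` must equal `axis$count`.
#' @param pixel_size Pixel edge length in um/pixel (> 0).
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, axis, pixel_size = 4.25) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            inherits(axis, "wavenumber_axis"))
  if (dim(data)[3] != axis$count)
    stop(sprintf("cube has %d channels but axis has %d samples",
                 dim(data)[3], axis$count))
  if (!all(is.finite(data))) stop("absorbance values must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  structure(list(data = data, axis = axis, pixel_size = pixel_size),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_cube> %d x %d px (%.2f um/px), %d channels %g->%g cm^-1\n",
              d[1], d[2], x$pixel_size, d[3], x$axis$start, x$axis$stop))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

#' Write / read a spectral cube
#'
#' Cubes are stored as a multi-page 32-bit TIFF (one page per wavenumber)
#' accompanied by a JSON sidecar (`<path>.json`) holding the wavenumber grid,
#' pixel size, optional seed, and the affine offset/scale used to map
#' absorbance into the TIFF's unit interval.
#'
#' @param cube A [spectral_cube()].
#' @param path Output TIFF path; the sidecar is written next to it.
#' @param seed Optional integer recorded in the sidecar metadata.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, seed = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  rng <- range(cube$data)
  offset <- rng[1]
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  pages <- lapply(seq_len(dim(cube$data)[3]), function(k) {
    (cube$data[, , k] - offset) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    format = "irplaque-cube-v1",
    wavenumbers = cube$axis$values,
    axis = list(start = cube$axis$start, stop = cube$axis$stop,
                step = cube$axis$step),
    pixel_size_um = cube$pixel_size,
    offset = offset, scale = scale,
    seed = seed
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]]); C <- length(pages)
  data <- array(0, c(h, w, C))
  for (k in seq_len(C)) data[, , k] <- pages[[k]] * meta$scale + meta$offset
  axis <- make_wavenumber_axis(meta$axis$start, meta$axis$stop, meta$axis$step)
  spectral_cube(data, axis, meta$pixel_size_um)
}
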