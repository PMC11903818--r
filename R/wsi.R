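#' Plan the tiling of a whole-slide image
#'
#' Sliding-window origins (1-based) with fixed tile size and overlap; the
#' stride is `tile - overlap`, and the last origin per axis is clamped to
#' `dim - tile + 1` so that every pixel is covered by at least one tile. No
#' padding is ever used, so the model only sees measured spectra.
#'
#' @param height,width Image size in pixels (both >= `tile`).
#' @param tile Tile edge length (default 64).
#' @param overlap Overlap between adjacent tiles in pixels (default 16);
#'   `0 <= overlap < tile`.
#' @return Two-column integer matrix of (row, col) origins, ascending in
#'   row-major order.
#' @export
tile_plan <- function(height, width, tile = 64L, overlap = 16L) {
  if (height < tile || width < tile)
    stop(sprintf("image (%d x %d) smaller than tile (%d)", height, width, tile))
  if (overlap < 0 || overlap >= tile)
    stop("`overlap` must satisfy 0 <= overlap < tile")
  stride <- tile - overlap
  axis_origins <- function(n) {
    o <- seq.int(1L, n - tile + 1L, by = stride)
    if (o[length(o)] + tile - 1L < n) o <- c(o, n - tile + 1L)
    o
  }
  rows <- axis_origins(height)
  cols <- axis_origins(width)
  cbind(row = rep(rows, each = length(cols)),
        col = rep(cols, times = length(rows)))
}

#' Stitch tile activation maps by maximum
#'
#' Each output pixel takes the maximum over all tiles covering it. The merge
#' is associative and commutative, so tile order is irrelevant; an uncovered
#' pixel indicates a plan violation and is rejected.
#'
#' @param tile_maps List of `list(origin = c(row, col), map = matrix)`.
#' @param height,width Output size.
#' @return Numeric matrix `[height, width]`.
#' @export
merge_max <- function(tile_maps, height, width) {
  out <- matrix(-Inf, height, width)
  cov <- matrix(0L, height, width)
  for (tm in tile_maps) {
    r <- tm$origin[1]; c <- tm$origin[2]
    th <- nrow(tm$map); tw <- ncol(tm$map)
    rr <- r:(r + th - 1L); cc <- c:(c + tw - 1L)
    out[rr, cc] <- pmax(out[rr, cc], tm$map)
    cov[rr, cc] <- cov[rr, cc] + 1L
  }
  if (any(cov == 0L)) stop("tiling does not cover every pixel")
  out
}

#' Whole-slide segmentation
#'
#' Tiles a cube, runs the model on every tile and stitches the per-tile
#' activation maps by [merge_max()]. Deterministic given the weights.
#'
#' @param model A `compsegnet`.
#' @param cube A [spectral_cube()] whose channel count matches the model.
#' @param tile,overlap Tiling parameters (defaults 64 and 16).
#' @return Whole-slide activation map (matrix in `[0, 1]`).
#' @export
segment_wsi <- function(model, cube, tile = 64L, overlap = 16L) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  if (d[3] != model$in_channels)
    stop(sprintf("cube has %d channels but the model expects %d",
                 d[3], model$in_channels))
  plan <- tile_plan(d[1], d[2], tile, overlap)
  maps <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    r <- plan[i, 1]; c <- plan[i, 2]
    patch <- cube$data[r:(r + tile - 1L), c:(c + tile - 1L), , drop = FALSE]
    maps[[i]] <- list(origin = c(r, c), map = compseg_forward(model, patch))
  }
  merge_max(maps, d[1], d[2])
}
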