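#' Laser-microdissection export configuration
#'
#' Parameters of the morphological sequence that turns a whole-slide
#' activation map into cuttable plaque shapes: a fixed 0.9 binarization
#' threshold, a first area filter at 100 um^2, dilation by 15 um, hole
#' filling, erosion by 10 um (net +5 um margin compensating tissue loss
#' during cutting), a second area filter at 300 um^2, and shape filters on
#' eccentricity and solidity that reject elongated folds and stringy
#' artifacts.
#'
#' The printed exclusion rule "eccentricity < 0.97, or solidity > 0.7" would
#' discard round, solid objects — the opposite of plaque-like shapes — so the
#' default keeps components with `eccentricity <= eccentricity_cut` and
#' `solidity >= solidity_cut`; set `literal_printed_rule = TRUE` to apply the
#' verbatim polarity instead.
#'
#' @param threshold Activation binarization threshold (default 0.9).
#' @param min_area1_um2 First minimum component area in um^2 (default 100).
#' @param dilate_um Dilation radius in um (default 15).
#' @param erode_um Erosion radius in um (default 10); must be < `dilate_um`.
#' @param min_area2_um2 Second minimum component area in um^2 (default 300).
#' @param eccentricity_cut Eccentricity bound (default 0.97).
#' @param solidity_cut Solidity bound (default 0.7).
#' @param literal_printed_rule Apply the verbatim exclusion polarity.
#' @return A list of class `lmd_config`.
#' @export
lmd_config <- function(threshold = 0.9, min_area1_um2 = 100, dilate_um = 15,
                       erode_um = 10, min_area2_um2 = 300,
                       eccentricity_cut = 0.97, solidity_cut = 0.7,
                       literal_printed_rule = FALSE) {
  stopifnot(threshold > 0, threshold < 1, min_area1_um2 >= 0,
            dilate_um > erode_um, erode_um >= 0, min_area2_um2 >= 0,
            eccentricity_cut > 0, eccentricity_cut <= 1,
            solidity_cut > 0, solidity_cut <= 1)
  structure(list(threshold = threshold, min_area1_um2 = min_area1_um2,
                 dilate_um = dilate_um, erode_um = erode_um,
                 min_area2_um2 = min_area2_um2,
                 eccentricity_cut = eccentricity_cut,
                 solidity_cut = solidity_cut,
                 literal_printed_rule = literal_printed_rule),
            class = "lmd_config")
}

# second-central-moment eccentricity of a pixel set (rows = (row, col)),
# with the 1/12 pixel-extent correction so a single pixel has eccentricity 0
component_eccentricity <- function(px) {
  n <- nrow(px)
  y <- px[, 1] - mean(px[, 1]); x <- px[, 2] - mean(px[, 2])
  cxx <- sum(x * x) / n + 1 / 12
  cyy <- sum(y * y) / n + 1 / 12
  cxy <- sum(x * y) / n
  tr <- cxx + cyy
  det <- cxx * cyy - cxy * cxy
  disc <- sqrt(max(tr * tr / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(1 - l2 / l1, 0))
}

# solidity: pixel count / area of the convex hull over the pixel corners
component_solidity <- function(px) {
  n <- nrow(px)
  if (n <= 2) return(1)
  corners <- rbind(cbind(px[, 2] - 1, px[, 1] - 1), cbind(px[, 2], px[, 1] - 1),
                   cbind(px[, 2] - 1, px[, 1]), cbind(px[, 2], px[, 1]))
  corners <- unique(corners)
  hull <- corners[grDevices::chull(corners[, 1], corners[, 2]), , drop = FALSE]
  if (nrow(hull) < 3) return(1)
  xh <- hull[, 1]; yh <- hull[, 2]
  area <- abs(sum(xh * c(yh[-1], yh[1]) - c(xh[-1], xh[1]) * yh)) / 2
  if (area <= 0) return(1)
  min(n / area, 1)
}

#' Morphological plaque-mask generation for LMD
#'
#' Applies the [lmd_config()] sequence in its printed order: threshold at
#' `threshold`, drop components below `min_area1_um2`, dilate by a disc of
#' radius `round(dilate_um / pixel_size)` px, fill holes, erode by a disc of
#' radius `round(erode_um / pixel_size)` px, then drop components failing
#' the second area filter or the eccentricity/solidity shape filters.
#'
#' @param a Whole-slide activation map (matrix in `[0, 1]`).
#' @param cfg An [lmd_config()].
#' @param pixel_size Pixel size in um/pixel.
#' @param exclusion_mask Optional binary mask of manually excluded (damaged)
#'   regions; pixels set to 1 there are removed before any processing.
#' @return Binary integer matrix.
#' @export
activation_to_plaque_mask <- function(a, cfg = lmd_config(),
                                      pixel_size = 4.25,
                                      exclusion_mask = NULL) {
  stopifnot(pixel_size > 0)
  m <- matrix(as.integer(a >= cfg$threshold), nrow(a), ncol(a))
  if (!is.null(exclusion_mask)) m[exclusion_mask != 0] <- 0L
  px2 <- pixel_size^2
  if (cfg$min_area1_um2 > 0)
    m <- remove_small_components(m, ceiling(cfg$min_area1_um2 / px2))
  rd <- round(cfg$dilate_um / pixel_size)
  if (rd >= 1) m <- morph_dilate(m, disc_kernel(rd))
  m <- morph_fill_holes(m)
  re <- round(cfg$erode_um / pixel_size)
  if (re >= 1) m <- morph_erode(m, disc_kernel(re))
  lab <- label_components(m)
  n <- max(lab)
  if (n == 0L) return(m)
  keep <- logical(n)
  for (id in seq_len(n)) {
    px <- which(lab == id, arr.ind = TRUE)
    area <- nrow(px) * px2
    ecc <- component_eccentricity(px)
    sol <- component_solidity(px)
    keep[id] <- if (cfg$literal_printed_rule) {
      area >= cfg$min_area2_um2 && ecc >= cfg$eccentricity_cut &&
        sol <= cfg$solidity_cut
    } else {
      area >= cfg$min_area2_um2 && ecc <= cfg$eccentricity_cut &&
        sol >= cfg$solidity_cut
    }
  }
  matrix(as.integer(lab > 0L & keep[pmax(lab, 1L)]), nrow(m), ncol(m))
}

# trace the crack boundary rings of one 4-connected pixel set; returns a list
# of closed rings (two-column matrices of vertex (x, y) in pixel units)
trace_rings <- function(px, h, w) {
  inside <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(px)))
    assign(paste(px[i, 1], px[i, 2]), TRUE, envir = inside)
  has <- function(r, c) !is.null(inside[[paste(r, c)]])
  # directed crack edges, oriented clockwise (screen coords) around pixels
  edges <- new.env(parent = emptyenv(), hash = TRUE)
  ekey <- function(x, y) paste(x, y)
  add_edge <- function(x0, y0, x1, y1) {
    k <- ekey(x0, y0)
    edges[[k]] <- c(edges[[k]], list(c(x1, y1)))
  }
  for (i in seq_len(nrow(px))) {
    r <- px[i, 1]; c <- px[i, 2] # pixel occupies x in [c-1, c], y in [r-1, r]
    if (!has(r - 1, c)) add_edge(c - 1, r - 1, c, r - 1)     # top
    if (!has(r, c + 1)) add_edge(c, r - 1, c, r)             # right
    if (!has(r + 1, c)) add_edge(c, r, c - 1, r)             # bottom
    if (!has(r, c - 1)) add_edge(c - 1, r, c - 1, r - 1)     # left
  }
  pop_edge <- function(x, y, prefer) {
    k <- ekey(x, y)
    cand <- edges[[k]]
    if (is.null(cand) || !length(cand)) return(NULL)
    pick <- 1L
    if (length(cand) > 1L && !is.null(prefer)) {
      # right-turn preference keeps rings simple at checkerboard corners
      dirs <- lapply(cand, function(e) c(e[1] - x, e[2] - y))
      right <- c(-prefer[2], prefer[1])
      score <- vapply(dirs, function(d) {
        if (all(d == right)) 3 else if (all(d == prefer)) 2 else 1
      }, numeric(1))
      pick <- which.max(score)
    }
    e <- cand[[pick]]
    cand[[pick]] <- NULL
    edges[[k]] <- cand
    e
  }
  rings <- list()
  repeat {
    keys <- ls(edges)
    keys <- keys[vapply(keys, function(k) length(edges[[k]]) > 0, logical(1))]
    if (!length(keys)) break
    start <- as.numeric(strsplit(keys[1], " ")[[1]])
    ring <- list(start)
    cur <- start; dir <- NULL
    repeat {
      nxt <- pop_edge(cur[1], cur[2], dir)
      if (is.null(nxt)) break
      dir <- c(nxt[1] - cur[1], nxt[2] - cur[2])
      cur <- nxt
      if (all(cur == start)) break
      ring[[length(ring) + 1L]] <- cur
    }
    rings[[length(rings) + 1L]] <- do.call(rbind, ring)
  }
  rings
}

ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Convert a binary mask into shape polygons
#'
#' Traces the outer boundary of every connected region along the pixel
#' boundaries (cracks), so the polygon area equals
#' `pixel count * pixel_size^2` exactly for hole-free regions. Rings are
#' traced per 4-connected region, which guarantees simple
#' (non-self-intersecting) rings. Eccentricity and solidity are recomputed
#' from the pixels and attached.
#'
#' @param mask Binary matrix.
#' @param pixel_size Pixel size in um/pixel.
#' @return List of `shape_polygon`s: `list(vertices (n x 2 matrix of x, y in
#'   um, closed ring without repeated endpoint), source_component, area_um2,
#'   eccentricity, solidity)`.
#' @export
mask_to_polygons <- function(mask, pixel_size = 4.25) {
  lab <- label_components(mask, connectivity = 4)
  n <- max(lab)
  if (n == 0L) return(list())
  shapes <- vector("list", n)
  for (id in seq_len(n)) {
    px <- which(lab == id, arr.ind = TRUE)
    rings <- trace_rings(px, nrow(mask), ncol(mask))
    areas <- vapply(rings, ring_area, numeric(1))
    outer <- rings[[which.max(areas)]]
    shapes[[id]] <- structure(list(
      vertices = outer * pixel_size,
      source_component = id,
      area_um2 = max(areas) * pixel_size^2,
      n_pixels = nrow(px),
      eccentricity = component_eccentricity(px),
      solidity = component_solidity(px)
    ), class = "shape_polygon")
  }
  shapes
}

#' Fit a two-dimensional Helmert (similarity) transform
#'
#' Least-squares fit of the 4-parameter similarity (uniform scale, rotation,
#' translation) mapping `src` points onto `dst`:
#' `T(p) = s R(theta) p + t`, minimizing the summed squared residual. The fit
#' is exact when the point pairs are related by a true similarity. Typically
#' fitted from three reference points marked in both coordinate systems.
#'
#' @param src,dst Two-column matrices of matching (x, y) points (>= 2 rows,
#'   source points not all coincident).
#' @return A list of class `helmert_transform`: `scale`, `theta` (radians),
#'   `tx`, `ty`, and the fit `rmse`.
#' @export
fit_helmert <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2, ncol(dst) == 2, nrow(src) == nrow(dst),
            nrow(src) >= 2)
  mx <- colMeans(src); my <- colMeans(dst)
  xs <- src[, 1] - mx[1]; ys <- src[, 2] - mx[2]
  xd <- dst[, 1] - my[1]; yd <- dst[, 2] - my[2]
  den <- sum(xs^2 + ys^2)
  if (den <= .Machine$double.eps)
    stop("degenerate source points (all coincident)")
  a <- sum(xs * xd + ys * yd) / den
  b <- sum(xs * yd - ys * xd) / den
  s <- sqrt(a^2 + b^2)
  theta <- atan2(b, a)
  t <- my - c(a * mx[1] - b * mx[2], b * mx[1] + a * mx[2])
  tr <- structure(list(scale = s, theta = theta, tx = t[1], ty = t[2]),
                  class = "helmert_transform")
  res <- helmert_apply(tr, src) - dst
  tr$rmse <- sqrt(mean(res^2))
  tr
}

#' Apply or invert a Helmert transform
#'
#' @param transform A `helmert_transform` (or a list with `scale`, `theta`,
#'   `tx`, `ty`).
#' @param pts Two-column matrix of (x, y) points.
#' @return Transformed points / the inverse transform.
#' @export
helmert_apply <- function(transform, pts) {
  pts <- as.matrix(pts)
  a <- transform$scale * cos(transform$theta)
  b <- transform$scale * sin(transform$theta)
  cbind(a * pts[, 1] - b * pts[, 2] + transform$tx,
        b * pts[, 1] + a * pts[, 2] + transform$ty)
}

#' @rdname helmert_apply
#' @export
helmert_invert <- function(transform) {
  s <- 1 / transform$scale
  th <- -transform$theta
  a <- s * cos(th); b <- s * sin(th)
  structure(list(scale = s, theta = th,
                 tx = -(a * transform$tx - b * transform$ty),
                 ty = -(b * transform$tx + a * transform$ty)),
            class = "helmert_transform")
}

#' Identity Helmert transform
#' @return A `helmert_transform` with scale 1, no rotation, no translation.
#' @export
helmert_identity <- function() {
  structure(list(scale = 1, theta = 0, tx = 0, ty = 0),
            class = "helmert_transform")
}

#' Export shapes to stage coordinates
#'
#' Maps every polygon vertex through the Helmert transform and writes a
#' vertex table `(shape_id, vertex_index, x_um, y_um)` to `path` plus a
#' summary table `(shape_id, area_um2, eccentricity, solidity)` to
#' `<path stem>_summary.csv`.
#'
#' @param shapes List of `shape_polygon`s from [mask_to_polygons()].
#' @param transform A `helmert_transform` (default identity).
#' @param path Output CSV path.
#' @return `path`, invisibly; the shape count is reported via `message`.
#' @export
export_shapes <- function(shapes, transform = helmert_identity(), path) {
  rows <- lapply(seq_along(shapes), function(i) {
    v <- helmert_apply(transform, shapes[[i]]$vertices)
    data.frame(shape_id = i, vertex_index = seq_len(nrow(v)),
               x_um = v[, 1], y_um = v[, 2])
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(shape_id = integer(0), vertex_index = integer(0),
               x_um = numeric(0), y_um = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  summ <- data.frame(
    shape_id = seq_along(shapes),
    area_um2 = vapply(shapes, function(s) s$area_um2, numeric(1)),
    eccentricity = vapply(shapes, function(s) s$eccentricity, numeric(1)),
    solidity = vapply(shapes, function(s) s$solidity, numeric(1)))
  spath <- paste0(sub("\\.csv$", "", path), "_summary.csv")
  utils::write.csv(summ, spath, row.names = FALSE)
  message(sprintf("exported %d shape(s) to %s", length(shapes), path))
  invisible(path)
}

#' Read back an exported shape file
#'
#' @param path CSV written by [export_shapes()].
#' @return List of vertex matrices (x_um, y_um), one per shape.
#' @export
read_shapes <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$shape_id), function(d)
    cbind(d$x_um, d$y_um)[order(d$vertex_index), , drop = FALSE])
}
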