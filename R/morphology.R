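#' Structuring elements
#'
#' `disc_kernel(r)` returns a (2r+1) x (2r+1) binary disc (pixels whose centre
#' distance is <= r); `cross_kernel()` is the 3 x 3 4-neighbour cross used as
#' the default smoothing element for morphological opening. `box_kernel(n)` is
#' an n x n block of ones (the "3 x 3 white kernel" of the mask dilation).
#'
#' @param r Integer radius in pixels (>= 1).
#' @return Integer 0/1 matrix.
#' @keywords internal
disc_kernel <- function(r) {
  r <- as.integer(r)
  stopifnot(r >= 1)
  d <- 2L * r + 1L
  xy <- seq_len(d) - r - 1L
  k <- outer(xy, xy, function(a, b) as.integer(a * a + b * b <= r * r))
  storage.mode(k) <- "integer"
  k
}

#' @rdname disc_kernel
#' @keywords internal
cross_kernel <- function() {
  matrix(c(0L, 1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L), 3L, 3L)
}

#' @rdname disc_kernel
#' @keywords internal
box_kernel <- function(n = 3L) matrix(1L, n, n)

#' Label connected components
#'
#' Integer-labels the foreground of a binary matrix. With
#' `connectivity = 8` (the default, matching the convention of common image
#' processing toolboxes) diagonally touching pixels belong to the same
#' component; labels produced by the underlying 4-connected pass are merged by
#' union-find over diagonal adjacencies.
#'
#' @param mask Binary matrix (0/1 or logical).
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 = background), with labels
#'   renumbered consecutively from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  if (connectivity == 8 && max(lab) > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    # diagonal neighbour pairs of distinct labels
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(max(lab))
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_along(parent), find, integer(1))
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  }
  # renumber consecutively
  u <- sort(unique(lab[lab > 0L]))
  if (length(u)) lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

# thin wrappers keeping EBImage behind the module surface ------------------

morph_dilate <- function(mask, kern) {
  out <- EBImage::dilate(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), kern)
  matrix(as.integer(out > 0), nrow(mask), ncol(mask))
}

morph_erode <- function(mask, kern) {
  out <- EBImage::erode(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), kern)
  matrix(as.integer(out > 0), nrow(mask), ncol(mask))
}

morph_open <- function(mask, kern) morph_dilate(morph_erode(mask, kern), kern)

morph_fill_holes <- function(mask) {
  out <- EBImage::fillHull(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)))
  matrix(as.integer(out > 0), nrow(mask), ncol(mask))
}

#' Remove small connected components
#' @param mask Binary matrix.
#' @param min_area Minimum pixel count; components with fewer pixels
#'   (strictly `< min_area`) are removed.
#' @param connectivity Passed to [label_components()].
#' @return Binary matrix.
#' @export
remove_small_components <- function(mask, min_area, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  matrix(as.integer(lab %in% keep), nrow(mask), ncol(mask))
}
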