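#' Dihedral transforms of images and samples
#'
#' The eight symmetries of the square are indexed `0..7` as
#' `op = r + 4 * f`: `r` quarter-turn counterclockwise rotations (0-3)
#' applied after an optional horizontal flip (`f` = 0/1). `apply_dihedral`
#' transforms a matrix or an `[H, W, C]` array; [augment()] transforms a ROI
#' sample's patch and effective mask identically, leaving the label unchanged.
#'
#' @param x Matrix or 3-d array (square spatial dims).
#' @param op Integer in `0..7`.
#' @return Transformed object of the same shape.
#' @export
apply_dihedral <- function(x, op) {
  stopifnot(op %in% 0:7)
  r <- op %% 4L
  f <- op %/% 4L
  rot1 <- function(m) { # 90 degrees counterclockwise
    if (length(dim(m)) == 3L) {
      m <- aperm(m, c(2, 1, 3))
      m[rev(seq_len(dim(m)[1])), , , drop = FALSE]
    } else {
      m <- t(m)
      m[rev(seq_len(nrow(m))), , drop = FALSE]
    }
  }
  if (f == 1L) {
    x <- if (length(dim(x)) == 3L) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
    else x[, rev(seq_len(ncol(x))), drop = FALSE]
  }
  for (k in seq_len(r)) x <- rot1(x)
  x
}

#' @rdname apply_dihedral
#' @param sample A ROI sample (see [extract_rois()]).
#' @export
augment <- function(sample, op) {
  sample$patch <- apply_dihedral(sample$patch, op)
  sample$effective_mask <- apply_dihedral(sample$effective_mask, op)
  sample
}

#' Extract labeled 64x64 ROI samples from a cube
#'
#' Crops spectral patches at the given top-left origins (1-based), derives
#' the weak label and effective background mask from the stain mask via
#' [roi_label()], and drops windows that fall in neither label class
#' (positive fraction strictly between 0 and the threshold), reporting the
#' dropped count.
#'
#' @param cube A [spectral_cube()].
#' @param mask Whole-slide binary stain mask (matrix matching the cube grid),
#'   or a list of per-position `roi_size x roi_size` masks (e.g. from per-ROI
#'   Otsu thresholding).
#' @param positions Two-column matrix/data frame of (row, col) origins.
#' @param case_id Case identifier attached to every sample.
#' @param threshold Positive-fraction threshold (default 0.05).
#' @param roi_size Window edge length (default 64).
#' @return List of ROI samples: `list(patch, y, effective_mask, case_id,
#'   sample_id, origin)`.
#' @export
extract_rois <- function(cube, mask, positions, case_id = "case",
                         threshold = 0.05, roi_size = 64L) {
  stopifnot(inherits(cube, "spectral_cube"))
  positions <- as.matrix(positions)
  d <- dim(cube$data)
  per_roi <- is.list(mask)
  if (!per_roi) stopifnot(all(dim(mask) == d[1:2]))
  out <- list()
  n_excluded <- 0L; n_oob <- 0L
  for (i in seq_len(nrow(positions))) {
    r <- positions[i, 1]; c <- positions[i, 2]
    if (r < 1 || c < 1 || r + roi_size - 1 > d[1] || c + roi_size - 1 > d[2]) {
      n_oob <- n_oob + 1L
      next
    }
    m_roi <- if (per_roi) mask[[i]] else
      mask[r:(r + roi_size - 1), c:(c + roi_size - 1)]
    lab <- roi_label(m_roi, threshold, roi_size)
    if (!lab$keep) { n_excluded <- n_excluded + 1L; next }
    out[[length(out) + 1L]] <- list(
      patch = cube$data[r:(r + roi_size - 1), c:(c + roi_size - 1), ,
                        drop = FALSE],
      y = lab$y, effective_mask = lab$effective_mask,
      case_id = as.character(case_id),
      sample_id = sprintf("%s_%04d", case_id, i),
      origin = c(row = r, col = c))
  }
  if (n_oob > 0)
    warning(sprintf("%d out-of-bounds window(s) rejected", n_oob))
  if (n_excluded > 0)
    message(sprintf("%d window(s) excluded (0 < positive fraction < %g)",
                    n_excluded, threshold))
  out
}

#' Partition samples by case
#'
#' Enforces the strict case-level split: every sample goes to the partition
#' its case is assigned to, and a case appears in exactly one partition.
#'
#' @param samples List of ROI samples.
#' @param assignment Named character vector `case_id -> "train"/"val"/"test"`.
#' @return `list(train =, val =, test =)`.
#' @export
split_by_case <- function(samples, assignment) {
  stopifnot(all(assignment %in% c("train", "val", "test")))
  cases <- vapply(samples, function(s) s$case_id, character(1))
  unknown <- setdiff(unique(cases), names(assignment))
  if (length(unknown))
    stop("samples reference cases missing from the split: ",
         paste(unknown, collapse = ", "))
  grp <- assignment[cases]
  list(train = samples[grp == "train"],
       val = samples[grp == "val"],
       test = samples[grp == "test"])
}

#' Seeded ROI position sampler for phantom scenes
#'
#' Deterministic surrogate for manual ROI selection: one window centered on
#' each plaque component (clamped to the scene), plus an equal number of
#' randomly placed amyloid-free windows (windows whose stain mask is empty).
#'
#' @param truth A `scene_truth`.
#' @param mask Whole-slide stain mask used to verify that negative windows
#'   are amyloid-free (defaults to the truth's plaque mask).
#' @param roi_size Window edge length.
#' @param n_negative Number of negative windows (defaults to the number of
#'   positives).
#' @param seed Seed for negative placement.
#' @param max_tries Rejection-sampling bound.
#' @return `list(positive =, negative =)` two-column origin matrices.
#' @export
sample_roi_positions <- function(truth, mask = truth$plaque_mask,
                                 roi_size = 64L, n_negative = NULL,
                                 seed = 1L, max_tries = 2000L) {
  lab <- truth$plaque_labels
  h <- nrow(lab); w <- ncol(lab)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  pos <- matrix(0L, length(ids), 2)
  for (k in seq_along(ids)) {
    px <- which(lab == ids[k], arr.ind = TRUE)
    cy <- mean(px[, 1]); cx <- mean(px[, 2])
    r <- round(cy - roi_size / 2 + 0.5); c <- round(cx - roi_size / 2 + 0.5)
    pos[k, ] <- c(min(max(r, 1L), h - roi_size + 1L),
                  min(max(c, 1L), w - roi_size + 1L))
  }
  n_neg <- n_negative %||% nrow(pos)
  neg <- matrix(0L, 0, 2)
  with_seed(seed, {
    tries <- 0L
    while (nrow(neg) < n_neg && tries < max_tries) {
      tries <- tries + 1L
      r <- sample.int(h - roi_size + 1L, 1)
      c <- sample.int(w - roi_size + 1L, 1)
      if (sum(mask[r:(r + roi_size - 1), c:(c + roi_size - 1)]) == 0)
        neg <- rbind(neg, c(r, c))
    }
  })
  if (nrow(neg) < n_neg)
    warning(sprintf("placed only %d of %d negative windows", nrow(neg), n_neg))
  list(positive = pos, negative = neg)
}

#' Class-balance report for a split dataset
#'
#' @param splits Result of [split_by_case()].
#' @return Data frame with per-split counts of positive and negative ROIs.
#' @export
class_balance <- function(splits) {
  do.call(rbind, lapply(names(splits), function(nm) {
    y <- vapply(splits[[nm]], function(s) s$y, numeric(1))
    data.frame(split = nm, n = length(y),
               n_positive = sum(y == 1), n_negative = sum(y == 0))
  }))
}
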