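#' Pixelwise confusion counts
#'
#' @param pred,truth Binary matrices on the same grid.
#' @return A list of class `pixel_confusion` with `tp`, `fp`, `tn`, `fn`.
#' @export
pixel_confusion <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("prediction/truth grid mismatch")
  p <- pred != 0; t <- truth != 0
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "pixel_confusion")
}

#' Precision (positive predictive value)
#'
#' `PPV = TP / (TP + FP)`: the proportion of predicted plaque area that is
#' truly plaque — in application terms, the purity of a plaque extraction.
#'
#' @param c A [pixel_confusion()].
#' @return Fraction, or `NA` when nothing was predicted positive.
#' @export
ppv <- function(c) {
  if (c$tp + c$fp == 0) return(NA_real_)
  c$tp / (c$tp + c$fp)
}

#' Prevalence
#'
#' `PR = (TP + FN) / total`: the proportion of the section that is truly
#' plaque — the purity of a random tissue extraction.
#'
#' @param c A [pixel_confusion()].
#' @return Fraction in `[0, 1]`.
#' @export
prevalence <- function(c) {
  tot <- c$tp + c$fp + c$tn + c$fn
  stopifnot(tot > 0)
  (c$tp + c$fn) / tot
}

#' Purification factor
#'
#' `PF = PPV / PR`: the factor by which plaque material is enriched relative
#' to a homogenized tissue section. Undefined (NA) when prevalence is zero or
#' precision is undefined.
#'
#' @param c A [pixel_confusion()].
#' @return Positive real, or `NA`.
#' @export
purification_factor <- function(c) {
  pr <- prevalence(c)
  pv <- ppv(c)
  if (is.na(pv) || pr == 0) return(NA_real_)
  pv / pr
}

#' Binarize an activation map
#'
#' @param a Activation map (matrix in `[0, 1]`).
#' @param threshold Threshold in `(0, 1)`; values `>= threshold` become 1.
#' @return Binary integer matrix.
#' @export
binarize_activation <- function(a, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  matrix(as.integer(a >= threshold), nrow(a), ncol(a))
}

#' Per-sample and pooled segmentation evaluation
#'
#' Computes the confusion, precision, prevalence and purification factor per
#' sample, plus the mean across samples (the per-sample average, as used for
#' cohort summaries) and the pooled values over all pixels. The per-sample
#' mean of PF and the pooled PF generally differ.
#'
#' @param preds,truths Lists of binary masks (same grids pairwise).
#' @return `list(per_sample = data.frame, mean_ppv, mean_prevalence, mean_pf,
#'   pooled = pixel_confusion, pooled_ppv, pooled_prevalence, pooled_pf)`.
#' @export
evaluate_segmentation <- function(preds, truths) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  rows <- lapply(seq_along(preds), function(i) {
    cf <- pixel_confusion(preds[[i]], truths[[i]])
    data.frame(sample = i, tp = cf$tp, fp = cf$fp, tn = cf$tn, fn = cf$fn,
               ppv = ppv(cf), prevalence = prevalence(cf),
               pf = purification_factor(cf))
  })
  per_sample <- do.call(rbind, rows)
  pooled <- structure(list(tp = sum(per_sample$tp), fp = sum(per_sample$fp),
                           tn = sum(per_sample$tn), fn = sum(per_sample$fn)),
                      class = "pixel_confusion")
  list(per_sample = per_sample,
       mean_ppv = mean(per_sample$ppv, na.rm = TRUE),
       mean_prevalence = mean(per_sample$prevalence),
       mean_pf = mean(per_sample$pf, na.rm = TRUE),
       pooled = pooled, pooled_ppv = ppv(pooled),
       pooled_prevalence = prevalence(pooled),
       pooled_pf = purification_factor(pooled))
}

#' Color-coded comparison overlay
#'
#' Renders the pixelwise comparison of a prediction with the stain truth:
#' true positives green, false positives red, false negatives blue, true
#' negatives white.
#'
#' @param pred,truth Binary masks on the same grid.
#' @return RGB array `[H, W, 3]`.
#' @export
comparison_overlay <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  p <- pred != 0; t <- truth != 0
  h <- nrow(pred); w <- ncol(pred)
  R <- matrix(1, h, w); G <- matrix(1, h, w); B <- matrix(1, h, w)
  tp <- p & t; fp <- p & !t; fn <- !p & t
  R[tp] <- 0; G[tp] <- 0.8; B[tp] <- 0
  R[fp] <- 0.9; G[fp] <- 0; B[fp] <- 0
  R[fn] <- 0; G[fn] <- 0; B[fn] <- 0.9
  array(c(R, G, B), c(h, w, 3))
}

#' Per-component hit rate of a segmentation
#'
#' Fraction of ground-truth plaque components overlapped by at least
#' `min_overlap_px` predicted-positive pixels — a detection-oriented score:
#' was each plaque found at all.
#'
#' @param pred Binary prediction mask.
#' @param truth_labels Integer component map of the ground truth.
#' @param min_overlap_px Minimum overlapping pixels to count a hit.
#' @return `list(hit_rate, n_components, n_hit)`.
#' @export
component_hit_rate <- function(pred, truth_labels, min_overlap_px = 1L) {
  ids <- setdiff(sort(unique(as.vector(truth_labels))), 0L)
  if (!length(ids)) return(list(hit_rate = NA_real_, n_components = 0L,
                                n_hit = 0L))
  hits <- vapply(ids, function(id)
    sum(pred[truth_labels == id] != 0) >= min_overlap_px, logical(1))
  list(hit_rate = mean(hits), n_components = length(ids),
       n_hit = sum(hits))
}
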