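#' Mask-generation configuration
#'
#' Parameters of the IHC-to-mask preprocessing chain: contrast windowing of
#' the blue channel, Otsu binarization, hole filling, small-component removal,
#' morphological opening, and dilation so that pixels surrounding stained
#' structures are included in the mask.
#'
#' @param window_lo,window_hi Contrast window bounds on the blue channel
#'   (defaults 0.3 and 0.9); values outside are clipped.
#' @param min_area_px Components with strictly fewer pixels are removed
#'   (default 30; at 4.25 um/pixel this corresponds to ~542 um^2).
#' @param opening_radius_px Radius of the disc structuring element for the
#'   smoothing opening (default 1, a 3 x 3 cross); 0 skips the opening.
#' @param dilate_iterations Iterations of dilation with a 3 x 3 ones kernel
#'   (default 4).
#' @param positive_fraction_threshold Minimum positive-area fraction for a
#'   region of interest to be labeled amyloid-positive (default 0.05).
#' @param otsu_per Whether the Otsu threshold is computed per ROI (default)
#'   or per slide when extracting ROI masks.
#' @return A list of class `mask_config`.
#' @export
mask_config <- function(window_lo = 0.3, window_hi = 0.9, min_area_px = 30,
                        opening_radius_px = 1, dilate_iterations = 4,
                        positive_fraction_threshold = 0.05,
                        otsu_per = c("roi", "slide")) {
  stopifnot(window_lo >= 0, window_lo < window_hi, window_hi <= 1,
            min_area_px >= 0, opening_radius_px >= 0, dilate_iterations >= 0,
            positive_fraction_threshold > 0, positive_fraction_threshold < 1)
  structure(list(window_lo = window_lo, window_hi = window_hi,
                 min_area_px = min_area_px,
                 opening_radius_px = opening_radius_px,
                 dilate_iterations = dilate_iterations,
                 positive_fraction_threshold = positive_fraction_threshold,
                 otsu_per = match.arg(otsu_per)),
            class = "mask_config")
}

#' Linear contrast window
#'
#' Maps intensities in `[lo, hi]` linearly onto `[0, 1]`, clipping values
#' below/above the bounds.
#'
#' @param x Numeric image (matrix or array) with values in `[0, 1]`.
#' @param lo,hi Window bounds, `lo < hi`.
#' @return Image of the same shape with values in `[0, 1]`.
#' @export
contrast_window <- function(x, lo = 0.3, hi = 0.9) {
  if (lo >= hi) stop("`lo` must be < `hi`")
  clip01((x - lo) / (hi - lo))
}

#' Otsu binarization of a stain channel
#'
#' Thresholds an image at the 256-bin Otsu threshold (the threshold
#' maximizing between-class variance). DAB-stained structures are dark in the
#' blue channel, so by default the image is inverted (`x -> 1 - x`) before
#' thresholding; the foreground of the returned mask is then the stain.
#' A constant image carries no threshold information and yields an all-zero
#' mask with a warning.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param invert Invert before thresholding (default `TRUE`).
#' @param threshold Optional fixed threshold on the (possibly inverted) image,
#'   bypassing Otsu; used for per-slide thresholding of ROI crops.
#' @return Binary integer matrix (1 = stain foreground).
#' @export
otsu_binarize <- function(image, invert = TRUE, threshold = NULL) {
  x <- if (invert) 1 - image else image
  if (is.null(threshold)) {
    if (max(x) - min(x) < .Machine$double.eps^0.5) {
      warning("constant image: no Otsu threshold, returning empty mask")
      return(matrix(0L, nrow(image), ncol(image)))
    }
    threshold <- EBImage::otsu(x, range = c(0, 1), levels = 256)
  }
  matrix(as.integer(x > threshold), nrow(image), ncol(image))
}

#' Morphological cleaning of a binary stain mask
#'
#' Applies, in order: hole filling, removal of connected components smaller
#' than `min_area_px` pixels, morphological opening with a disc element, and
#' `dilate_iterations` dilations with a 3 x 3 ones kernel so that the pixels
#' surrounding stained structures are set to 1.
#'
#' @param mask Binary matrix.
#' @param cfg A [mask_config()].
#' @return Binary integer matrix.
#' @export
clean_mask <- function(mask, cfg = mask_config()) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  m <- morph_fill_holes(m)
  if (cfg$min_area_px > 0) m <- remove_small_components(m, cfg$min_area_px)
  if (cfg$opening_radius_px > 0)
    m <- morph_open(m, disc_kernel(cfg$opening_radius_px))
  if (cfg$dilate_iterations > 0) {
    k <- box_kernel(3L)
    for (i in seq_len(cfg$dilate_iterations)) m <- morph_dilate(m, k)
  }
  m
}

#' Weak label for a region of interest
#'
#' Assigns the binary image-level label from the positive-area fraction
#' `f = mean(mask_roi)`: `f >= threshold` gives a positive ROI with the mask
#' as its effective background mask; `f = 0` gives a negative ROI whose
#' effective mask is all ones (preventing division by zero and vanishing
#' gradients in the masked pooling); intermediate fractions
#' `0 < f < threshold` fall in neither class and are flagged for exclusion
#' from training.
#'
#' @param mask_roi Binary matrix of size `roi_size x roi_size`.
#' @param threshold Positive-fraction threshold (default 0.05).
#' @param roi_size Expected ROI edge length in pixels (default 64).
#' @return `list(y, effective_mask, keep, fraction)`; `y` is `NA` when
#'   `keep` is `FALSE`.
#' @export
roi_label <- function(mask_roi, threshold = 0.05, roi_size = 64L) {
  if (!is.matrix(mask_roi) || !all(dim(mask_roi) == roi_size))
    stop(sprintf("`mask_roi` must be %d x %d", roi_size, roi_size))
  m <- matrix(as.integer(mask_roi != 0), roi_size, roi_size)
  f <- mean(m)
  if (f >= threshold) {
    list(y = 1L, effective_mask = m, keep = TRUE, fraction = f)
  } else if (f == 0) {
    list(y = 0L, effective_mask = matrix(1L, roi_size, roi_size),
         keep = TRUE, fraction = f)
  } else {
    list(y = NA_integer_, effective_mask = m, keep = FALSE, fraction = f)
  }
}

#' Full IHC-to-mask pipeline
#'
#' Blue channel -> contrast window -> inversion + Otsu -> morphological
#' cleaning. Operates on whatever image it is given (a whole slide or a
#' single ROI crop).
#'
#' @param rgb Numeric array `[H, W, 3]` in `[0, 1]`.
#' @param cfg A [mask_config()].
#' @param threshold Optional fixed binarization threshold (see
#'   [otsu_binarize()]).
#' @return Binary integer matrix.
#' @export
ihc_mask_pipeline <- function(rgb, cfg = mask_config(), threshold = NULL) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] >= 3L)
  blue <- rgb[, , 3]
  wb <- contrast_window(blue, cfg$window_lo, cfg$window_hi)
  bm <- suppressWarnings(otsu_binarize(wb, invert = TRUE,
                                       threshold = threshold))
  clean_mask(bm, cfg)
}

#' Pixel-count to area conversion
#'
#' @param n_px Pixel count.
#' @param pixel_size Pixel size in um/pixel.
#' @return Area in um^2 (`n_px * pixel_size^2`), exact.
#' @export
px_area_um2 <- function(n_px, pixel_size = 4.25) n_px * pixel_size^2

#' Minimum component area of a mask config, in um^2
#'
#' Derived metadata: the um^2 equivalent of `min_area_px`, rounded to the
#' nearest integer (30 px at 4.25 um/pixel gives 542 um^2).
#'
#' @param cfg A [mask_config()].
#' @param pixel_size Pixel size in um/pixel.
#' @return Rounded area in um^2.
#' @export
min_area_um2 <- function(cfg = mask_config(), pixel_size = 4.25) {
  round(px_area_um2(cfg$min_area_px, pixel_size))
}

#' Mask quality-control report
#'
#' @param mask Binary matrix.
#' @param pixel_size Pixel size in um/pixel.
#' @return `data.frame(component, area_px, area_um2)`, one row per connected
#'   component (8-connectivity).
#' @export
mask_qc_report <- function(mask, pixel_size = 4.25) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L)
    return(data.frame(component = integer(0), area_px = integer(0),
                      area_um2 = numeric(0)))
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  data.frame(component = seq_len(n), area_px = sizes,
             area_um2 = px_area_um2(sizes, pixel_size))
}
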