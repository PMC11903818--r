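test_that("contrast window maps the stated bounds and clips outside", {
  expect_equal(contrast_window(0.3, 0.3, 0.9), 0)
  expect_equal(contrast_window(0.9, 0.3, 0.9), 1)
  expect_equal(contrast_window(0.6, 0.3, 0.9), 0.5)
  expect_equal(contrast_window(0.1, 0.3, 0.9), 0)
  expect_equal(contrast_window(0.95, 0.3, 0.9), 1)
  expect_error(contrast_window(0.5, 0.9, 0.3), "lo")
})

test_that("Otsu binarization matches the exhaustive threshold scan", {
  # two-valued blue channel: dark stain pixels become foreground
  img <- matrix(c(rep(0.2, 30), rep(0.8, 70)), 10, 10)
  mask <- otsu_binarize(img)
  expect_identical(mask, matrix(as.integer(img == 0.2), 10, 10))

  # oracle equivalence on random images
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(stats::runif(400)^2, 20, 20)
    th_pkg <- EBImage::otsu(x, range = c(0, 1), levels = 256)
    th_orc <- otsu_oracle(x)
    expect_equal(matrix(as.integer(x > th_pkg), 20, 20),
                 matrix(as.integer(x > th_orc), 20, 20))
  }
})

test_that("constant images give an empty mask with a warning", {
  expect_warning(m <- otsu_binarize(matrix(0.5, 8, 8)), "constant")
  expect_true(all(m == 0))
})

test_that("clean_mask removes sub-threshold components and keeps 30-px ones", {
  cfg <- mask_config(dilate_iterations = 0, opening_radius_px = 0)
  m29 <- matrix(0L, 40, 40); m29[10:14, 10:15] <- 1L; m29[14, 15] <- 0L
  expect_equal(sum(m29), 29)
  expect_true(all(clean_mask(m29, cfg) == 0))

  m30 <- matrix(0L, 40, 40); m30[10:14, 10:15] <- 1L
  expect_equal(sum(m30), 30)
  expect_equal(sum(clean_mask(m30, cfg)), 30)
})

test_that("four 3x3 dilations turn a retained pixel into a 9x9 square", {
  cfg <- mask_config(min_area_px = 1, opening_radius_px = 0,
                     dilate_iterations = 4)
  m <- matrix(0L, 21, 21); m[11, 11] <- 1L
  out <- clean_mask(m, cfg)
  expect_equal(sum(out), 81)
  expect_true(all(out[7:15, 7:15] == 1L))
})

test_that("cleaning is idempotent up to the dilation stage", {
  set.seed(42)
  cfg <- mask_config(dilate_iterations = 0)
  for (s in 1:3) {
    # blob-like masks as produced by stain binarization
    m <- matrix(0L, 64, 64)
    for (b in 1:6) {
      cy <- stats::runif(1, 8, 56); cx <- stats::runif(1, 8, 56)
      r <- stats::runif(1, 2, 7)
      yy <- matrix(1:64, 64, 64); xx <- t(yy)
      m[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- 1L
    }
    once <- clean_mask(m, cfg)
    twice <- clean_mask(once, cfg)
    expect_identical(once, twice)
  }
})

test_that("dilation is local: foreground stays within Chebyshev reach", {
  set.seed(7)
  cfg <- mask_config(min_area_px = 5, opening_radius_px = 0,
                     dilate_iterations = 4)
  m <- matrix(0L, 50, 50)
  m[10:13, 10:13] <- 1L; m[30:35, 38:41] <- 1L
  out <- clean_mask(m, cfg)
  pre <- clean_mask(m, mask_config(min_area_px = 5, opening_radius_px = 0,
                                   dilate_iterations = 0))
  src <- which(pre == 1L, arr.ind = TRUE)
  for (p in which(out == 1L)) {
    i <- (p - 1) %% 50 + 1; j <- (p - 1) %/% 50 + 1
    cheb <- min(pmax(abs(src[, 1] - i), abs(src[, 2] - j)))
    expect_lte(cheb, 4)
  }
})

test_that("weak ROI labels follow the 5% rule with the all-ones fallback", {
  m <- matrix(0L, 64, 64)
  m[seq_len(205)] <- 1L # 205/4096 ~ 0.0500 >= 5%
  lab <- roi_label(m)
  expect_equal(lab$y, 1L)
  expect_identical(lab$effective_mask, m)
  expect_true(lab$keep)

  lab0 <- roi_label(matrix(0L, 64, 64))
  expect_equal(lab0$y, 0L)
  expect_true(all(lab0$effective_mask == 1L))
  expect_true(lab0$keep)

  m2 <- matrix(0L, 64, 64); m2[seq_len(82)] <- 1L # ~2%
  lab2 <- roi_label(m2)
  expect_false(lab2$keep)
  expect_true(is.na(lab2$y))

  expect_error(roi_label(matrix(0L, 32, 32)), "64 x 64")
})

test_that("component recall of cored plaques on renderings is high", {
  hit <- 0L; tot <- 0L
  for (s in c(21, 22, 23)) {
    sc <- small_scene(seed = s, n_plaques = 8, h = 192, w = 192)
    ihc <- render_pseudo_ihc(sc$truth, stain_params(seed = s))
    m <- ihc_mask_pipeline(ihc)
    lab <- sc$truth$plaque_labels
    for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
      if (max(sc$truth$plaque_density[lab == id]) < 0.99) next # cored cores
      tot <- tot + 1L
      if (sum(m[lab == id]) / sum(lab == id) >= 0.5) hit <- hit + 1L
    }
  }
  expect_gte(tot, 5L)
  expect_gte(hit / tot, 0.9)
})

test_that("area metadata converts pixels to um^2", {
  expect_equal(px_area_um2(30, 4.25), 541.875)
  expect_equal(min_area_um2(mask_config(), 4.25), 542)
  expect_equal(px_area_um2(1, 4.25), 18.0625)
})

test_that("mask QC report lists components with areas", {
  m <- matrix(0L, 30, 30)
  m[2:5, 2:5] <- 1L; m[20:22, 20:25] <- 1L
  qc <- mask_qc_report(m, 4.25)
  expect_equal(nrow(qc), 2)
  expect_setequal(qc$area_px, c(16, 18))
  expect_equal(sort(qc$area_um2), sort(c(16, 18) * 4.25^2))
})
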