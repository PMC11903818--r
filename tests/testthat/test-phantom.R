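test_that("wavenumber axis is an inclusive descending grid", {
  ax <- make_wavenumber_axis(1800, 948, 2)
  expect_equal(ax$count, 427L)
  expect_equal(length(ax$values), 427L)
  expect_equal(ax$values[1], 1800)
  expect_equal(ax$values[427], 948)
  expect_true(all(diff(ax$values) == -2))

  expect_equal(make_wavenumber_axis(1800, 1800, 2)$count, 1L)
  ax3 <- make_wavenumber_axis(10, 0, 5)
  expect_equal(ax3$values, c(10, 5, 0))
  expect_equal(ax3$count, 3L)
})

test_that("non-divisible spectral ranges are rejected", {
  expect_error(make_wavenumber_axis(1800, 949, 2), "not divisible")
  expect_error(make_wavenumber_axis(948, 1800, 2), "descending")
  expect_error(make_wavenumber_axis(1800, 948, -2), "step")
})

test_that("scenes are seeded-deterministic with correct plaque counts", {
  sc <- small_scene(seed = 7, n_plaques = 5)
  sc2 <- small_scene(seed = 7, n_plaques = 5)
  expect_identical(sc$cube$data, sc2$cube$data)
  expect_identical(sc$truth, sc2$truth)

  # component count against an independent flood-fill oracle
  expect_equal(flood_fill_count(sc$truth$plaque_mask), 5L)
  expect_equal(max(label_components(sc$truth$plaque_mask)), 5L)

  sc0 <- small_scene(seed = 1, n_plaques = 0)
  expect_true(all(sc0$truth$plaque_mask == 0))
})

test_that("scene truth is internally consistent", {
  sc <- small_scene(seed = 9, n_plaques = 6)
  tr <- sc$truth
  expect_identical(tr$plaque_mask, matrix(as.integer(tr$plaque_density > 0),
                                          nrow(tr$plaque_density),
                                          ncol(tr$plaque_density)))
  expect_true(all((tr$plaque_labels > 0) == (tr$plaque_mask == 1)))
  expect_true(all(tr$plaque_density >= 0 & tr$plaque_density <= 1))
  # artifacts never overlap plaques
  expect_true(all(tr$artifact_mask * tr$plaque_mask == 0))
})

test_that("impossible placements fail with the achieved count", {
  expect_error(generate_scene(64, 64, 200, seed = 1, axis = axis16(),
                              max_retries = 20),
               "could only place")
})

test_that("spectral contrast lives in the configured difference bands", {
  sm <- spectral_model(noise_sd = 0, baseline_slope_sd = 0,
                       baseline_intercept = c(0, 0))
  ax <- make_wavenumber_axis(1800, 948, 4) # denser grid to resolve bands
  sc <- generate_scene(96, 96, 4, spectral = sm, seed = 2, axis = ax,
                       n_folds = 0, n_holes = 0)
  plaque_px <- sc$truth$plaque_density > 0.5
  bg_px <- sc$truth$plaque_mask == 0
  X <- sc$cube$data
  dim(X) <- c(96 * 96, ax$count)
  dmean <- colMeans(X[as.vector(plaque_px), , drop = FALSE]) -
    colMeans(X[as.vector(bg_px), , drop = FALSE])
  in_band <- rep(FALSE, ax$count)
  for (b in seq_len(nrow(sm$diff_bands)))
    in_band <- in_band | (ax$values >= sm$diff_bands[b, 1] &
                            ax$values <= sm$diff_bands[b, 2])
  top <- order(abs(dmean), decreasing = TRUE)[1:5]
  expect_true(all(in_band[top]))
})

test_that("zero contrast makes plaque and background indistinguishable", {
  sm <- spectral_model(contrast_scale = 0)
  pvals <- vapply(1:6, function(s) {
    sc <- generate_scene(80, 80, 3, spectral = sm, seed = s, axis = axis16(),
                         n_folds = 0, n_holes = 0)
    band <- sc$cube$data[, , 2] # ester-band channel
    suppressWarnings(stats::ks.test(band[sc$truth$plaque_mask == 1],
                                    band[sc$truth$plaque_mask == 0])$p.value)
  }, numeric(1))
  # p-values behave like draws from a uniform: no systematic rejection
  expect_lt(sum(pvals < 0.05), 3)
  expect_gt(max(pvals), 0.2)
})

test_that("noiseless absorbance is non-negative after baseline addition", {
  sm <- spectral_model(noise_sd = 0)
  sc <- generate_scene(80, 80, 4, spectral = sm, seed = 5, axis = axis16())
  expect_true(all(sc$cube$data >= 0))
})

test_that("pseudo-IHC rendering follows the stated blue-channel law", {
  sc <- small_scene(seed = 4, n_plaques = 0, h = 64, w = 64)
  ihc <- render_pseudo_ihc(sc$truth)
  expect_gte(min(ihc[, , 3]), 0.9) # no stain anywhere

  # a single full-density pixel maps to dab_blue_min exactly
  tr <- sc$truth
  tr$plaque_density[30, 30] <- 1
  tr$plaque_mask[30, 30] <- 1L
  tr$plaque_labels[30, 30] <- 1L
  ihc2 <- render_pseudo_ihc(tr, stain_params(counterstain_density = 0))
  expect_equal(ihc2[30, 30, 3], 0.1)
  expect_true(all(ihc2 >= 0 & ihc2 <= 1))
})

test_that("mask pipeline on a rendering recovers plaque components", {
  sc <- small_scene(seed = 12, n_plaques = 6, h = 160, w = 160)
  ihc <- render_pseudo_ihc(sc$truth)
  m <- ihc_mask_pipeline(ihc)
  lab <- sc$truth$plaque_labels
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  big <- ids[vapply(ids, function(id) sum(lab == id) >= 30, logical(1))]
  overlap <- vapply(big, function(id) sum(m[lab == id]) / sum(lab == id),
                    numeric(1))
  # dense plaques must be recovered; diffuse ones may be missed at
  # whole-slide thresholds, mirroring faintly stained diffuse deposits
  dense <- vapply(big, function(id)
    max(sc$truth$plaque_density[lab == id]) > 0.8, logical(1))
  expect_true(all(overlap[dense] >= 0.5))
})

test_that("cube round-trips through the TIFF container", {
  sc <- small_scene(seed = 6, n_plaques = 2, h = 64, w = 64)
  path <- tempfile(fileext = ".tif")
  write_cube(sc$cube, path, seed = 6)
  back <- read_cube(path)
  expect_equal(back$data, sc$cube$data, tolerance = 1e-6)
  expect_equal(back$axis$values, sc$cube$axis$values)
  expect_equal(back$pixel_size, 4.25)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$seed, 6)
  unlink(c(path, paste0(path, ".json")))
})
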