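# reference morphology oracle for hand-staging the LMD sequence
disk_mask <- function(h, w, cy, cx, r) {
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  matrix(as.integer((yy - cy)^2 + (xx - cx)^2 <= r^2), h, w)
}

test_that("the morphological sequence retains exactly the qualifying disk", {
  ps <- 4.25
  a <- matrix(0, 120, 120)
  big <- disk_mask(120, 120, 30, 30, 2.65)     # ~22 px ~ 400 um^2
  small <- disk_mask(120, 120, 30, 90, 1.25)   # ~5 px ~ 90 um^2, fails area 1
  line <- matrix(0L, 120, 120); line[90, 40:80] <- 1L # 41 px, elongated
  a[big == 1] <- 0.95; a[small == 1] <- 0.95; a[line == 1] <- 0.95
  expect_gte(sum(big) * ps^2, 350)
  expect_lt(sum(small) * ps^2, 100)

  out <- activation_to_plaque_mask(a, lmd_config(), pixel_size = ps)
  lab <- label_components(out)
  expect_equal(max(lab), 1L) # exactly one survivor
  # the survivor contains the big disk's centre, not the line or small disk
  expect_equal(out[30, 30], 1L)
  expect_equal(sum(out[90, ]), 0)
  expect_equal(sum(out[, 90]), 0)

  # staged oracle: after threshold + area filter only big and line remain
  m0 <- matrix(as.integer(a >= 0.9), 120, 120)
  m1 <- remove_small_components(m0, ceiling(100 / ps^2))
  expect_equal(max(label_components(m1)), 2L)
  # the line survives the margin stages but fails the eccentricity filter
  ln <- which(line == 1L, arr.ind = TRUE)
  expect_gt(irplaque:::component_eccentricity(ln), 0.97)
  bg <- which(big == 1L, arr.ind = TRUE)
  expect_lt(irplaque:::component_eccentricity(bg), 0.97)
  expect_gte(irplaque:::component_solidity(bg), 0.7)
})

test_that("sub-threshold activation yields an empty mask", {
  a <- matrix(0.85, 50, 50)
  expect_true(all(activation_to_plaque_mask(a) == 0))
  one90 <- matrix(0, 50, 50)
  one90[10:11, 10:12] <- 0.95 # 6 px at 4.25 um = 108 um^2; shrink to 5 px
  one90[11, 12] <- 0
  expect_equal(sum(one90 >= 0.9), 5) # ~90 um^2 < 100
  expect_true(all(activation_to_plaque_mask(one90) == 0))
})

test_that("the net morphological margin grows an isolated disk by ~5 um", {
  ps <- 4.25
  a <- matrix(0, 100, 100)
  d <- disk_mask(100, 100, 50, 50, 8)
  a[d == 1] <- 1
  out <- activation_to_plaque_mask(a, lmd_config(), pixel_size = ps)
  r_in <- sqrt(sum(d) / pi)
  r_out <- sqrt(sum(out) / pi)
  expected <- (round(15 / ps) - round(10 / ps)) # px
  expect_equal(r_out - r_in, expected, tolerance = 1)
})

test_that("the literal printed shape rule inverts the polarity", {
  ps <- 4.25
  a <- matrix(0, 120, 120)
  big <- disk_mask(120, 120, 30, 30, 2.65)
  a[big == 1] <- 0.95
  keep_default <- activation_to_plaque_mask(a, lmd_config(), ps)
  keep_literal <- activation_to_plaque_mask(
    a, lmd_config(literal_printed_rule = TRUE), ps)
  expect_gt(sum(keep_default), 0) # round solid disk kept by default
  expect_equal(sum(keep_literal), 0) # verbatim rule discards it
})

test_that("polygons trace pixel boundaries with exact areas", {
  m <- matrix(0L, 10, 10); m[1, 1] <- 1L
  shp <- mask_to_polygons(m, pixel_size = 4.25)
  expect_length(shp, 1)
  expect_equal(shp[[1]]$area_um2, 18.0625)
  expect_equal(nrow(shp[[1]]$vertices), 4)

  m2 <- matrix(0L, 10, 10); m2[3:4, 5:6] <- 1L
  shp2 <- mask_to_polygons(m2, pixel_size = 2)
  expect_equal(shp2[[1]]$area_um2, 4 * 4)

  expect_length(mask_to_polygons(matrix(0L, 5, 5)), 0)

  # polygon area equals pixel count * pixel_size^2 for arbitrary blobs
  set.seed(4)
  blob <- disk_mask(30, 30, 15, 15, 6)
  shp3 <- mask_to_polygons(blob, pixel_size = 1)
  expect_equal(shp3[[1]]$area_um2, sum(blob))
  # simple ring: no repeated vertices
  v <- shp3[[1]]$vertices
  expect_equal(nrow(unique(v)), nrow(v))
})

test_that("Helmert fits recover exact similarities", {
  src <- cbind(c(0, 10, 3), c(0, 0, 7))
  idt <- fit_helmert(src, src)
  expect_equal(idt$scale, 1)
  expect_equal(idt$theta, 0)
  expect_equal(c(idt$tx, idt$ty), c(0, 0))

  tra <- fit_helmert(src, src + matrix(rep(c(10, -5), each = 3), 3))
  expect_equal(tra$scale, 1)
  expect_equal(c(tra$tx, tra$ty), c(10, -5))

  # scale 2, rotation 90 degrees, translation (1, 2)
  R90 <- cbind(c(0, 1), c(-1, 0))
  dst <- t(2 * R90 %*% t(src)) + matrix(rep(c(1, 2), each = 3), 3)
  fit <- fit_helmert(src, dst)
  expect_equal(fit$scale, 2)
  expect_equal(fit$theta, pi / 2)
  expect_equal(c(fit$tx, fit$ty), c(1, 2))
  expect_lt(fit$rmse, 1e-9)

  expect_error(fit_helmert(cbind(c(1, 1), c(2, 2)), cbind(c(0, 1), c(0, 1))),
               "degenerate")
})

test_that("1000 random similarities are recovered to 1e-6", {
  set.seed(77)
  worst <- 0
  for (i in 1:1000) {
    s <- stats::runif(1, 0.2, 5)
    th <- stats::runif(1, -pi, pi)
    t <- stats::rnorm(2, 0, 100)
    src <- matrix(stats::rnorm(6, 0, 50), 3, 2)
    R <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
    dst <- t(s * R %*% t(src)) + matrix(rep(t, each = 3), 3)
    fit <- fit_helmert(src, dst)
    err <- max(abs(fit$scale - s),
               abs(atan2(sin(fit$theta - th), cos(fit$theta - th))),
               abs(fit$tx - t[1]), abs(fit$ty - t[2]))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-6)
})

test_that("applying then inverting a transform is the identity", {
  tr <- structure(list(scale = 1.7, theta = 0.6, tx = 12, ty = -3),
                  class = "helmert_transform")
  pts <- matrix(stats::rnorm(20), 10, 2)
  back <- helmert_apply(helmert_invert(tr), helmert_apply(tr, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("shape export writes stage coordinates and round-trips", {
  m <- matrix(0L, 20, 20); m[5:8, 5:8] <- 1L; m[14:16, 12:15] <- 1L
  shapes <- mask_to_polygons(m, pixel_size = 4.25)
  path <- tempfile(fileext = ".csv")

  suppressMessages(export_shapes(shapes, helmert_identity(), path))
  back <- read_shapes(path)
  expect_length(back, 2)
  for (i in 1:2)
    expect_lt(max(abs(back[[i]] - shapes[[i]]$vertices)), 1e-6)

  tr <- structure(list(scale = 1, theta = 0, tx = 100, ty = 50),
                  class = "helmert_transform")
  suppressMessages(export_shapes(shapes, tr, path))
  back2 <- read_shapes(path)
  expect_equal(back2[[1]][, 1], shapes[[1]]$vertices[, 1] + 100)
  expect_equal(back2[[1]][, 2], shapes[[1]]$vertices[, 2] + 50)

  summ <- utils::read.csv(paste0(sub("\\.csv$", "", path), "_summary.csv"))
  expect_equal(nrow(summ), 2)
  expect_true(all(summ$area_um2 > 0))
  unlink(c(path, paste0(sub("\\.csv$", "", path), "_summary.csv")))
})

test_that("every exported polygon stems from a surviving component", {
  ps <- 4.25
  a <- matrix(0, 120, 120)
  a[disk_mask(120, 120, 30, 30, 4) == 1] <- 0.95
  a[disk_mask(120, 120, 80, 80, 3) == 1] <- 0.95
  mask <- activation_to_plaque_mask(a, lmd_config(), ps)
  shapes <- mask_to_polygons(mask, ps)
  lab <- label_components(mask, connectivity = 4)
  expect_equal(length(shapes), max(lab))
  for (s in shapes) {
    # polygon centroid falls inside its source component's bounding box
    px <- which(lab == s$source_component, arr.ind = TRUE)
    cx <- mean(s$vertices[, 1]) / ps; cy <- mean(s$vertices[, 2]) / ps
    expect_gte(cx, min(px[, 2]) - 1); expect_lte(cx, max(px[, 2]))
    expect_gte(cy, min(px[, 1]) - 1); expect_lte(cy, max(px[, 1]))
  }
})
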