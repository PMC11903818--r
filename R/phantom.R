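#' Spectral model for the synthetic phantom
#'
#' Describes the two endmember spectra of the phantom as sums of Gaussian
#' bands in wavenumber. Both tissue endmembers share the protein backbone
#' bands (Amide I ~1655 cm^-1, Amide II ~1545 cm^-1); the plaque endmember
#' additionally carries a beta-sheet shoulder at 1630 cm^-1 and perturbed
#' amplitudes at the lipid ester band (~1740 cm^-1), the C-H deformation bands
#' (1480-1430 cm^-1) and the mixed 1320-1200 cm^-1 region. All perturbations
#' scale linearly with `contrast_scale`, so `contrast_scale = 0` makes both
#' endmembers identical.
#'
#' @param contrast_scale Fractional spectral contrast between plaque and
#'   background endmembers (default 0.15; differences are deliberately subtle).
#' @param noise_sd Standard deviation of i.i.d. Gaussian voxel noise, in
#'   absorbance units (default 0.01).
#' @param baseline_slope_sd Standard deviation of the per-pixel linear
#'   baseline slope, absorbance per cm^-1 (default 2e-5). Slopes are clamped
#'   so that baselines never drive absorbance negative.
#' @param baseline_intercept Range (lo, hi) of the per-pixel baseline offset
#'   in absorbance units; set `c(0, 0)` together with `baseline_slope_sd = 0`
#'   for a baseline-free cube.
#' @return A list of class `spectral_model` with background/plaque band tables
#'   and the configured difference-band windows.
#' @export
spectral_model <- function(contrast_scale = 0.15, noise_sd = 0.01,
                           baseline_slope_sd = 2e-5,
                           baseline_intercept = c(0.01, 0.04)) {
  stopifnot(contrast_scale >= 0, noise_sd >= 0, baseline_slope_sd >= 0,
            length(baseline_intercept) == 2L,
            baseline_intercept[1] >= 0,
            baseline_intercept[2] >= baseline_intercept[1])
  bg <- data.frame(
    center = c(1655, 1545, 1740, 1455, 1240),
    sigma  = c(28,   25,   18,   20,   30),
    amp    = c(1.00, 0.55, 0.10, 0.15, 0.12)
  )
  cs <- contrast_scale
  pl <- bg
  pl$amp[pl$center == 1740] <- pl$amp[pl$center == 1740] * (1 - cs)
  pl$amp[pl$center == 1455] <- pl$amp[pl$center == 1455] * (1 + 0.8 * cs)
  pl$amp[pl$center == 1240] <- pl$amp[pl$center == 1240] * (1 + 0.8 * cs)
  pl <- rbind(pl, data.frame(center = 1630, sigma = 15, amp = 0.5 * cs))
  structure(list(
    background = bg, plaque = pl,
    contrast_scale = cs, noise_sd = noise_sd,
    baseline_slope_sd = baseline_slope_sd,
    baseline_intercept = baseline_intercept,
    diff_bands = rbind(c(1722, 1758), c(1600, 1660),
                       c(1430, 1480), c(1200, 1320))
  ), class = "spectral_model")
}

#' Evaluate an endmember spectrum on a wavenumber grid
#' @param bands Band table (`center`, `sigma`, `amp`).
#' @param wn Numeric wavenumber vector.
#' @return Numeric absorbance vector of `length(wn)`.
#' @keywords internal
endmember_spectrum <- function(bands, wn) {
  out <- numeric(length(wn))
  for (i in seq_len(nrow(bands))) {
    out <- out + bands$amp[i] *
      exp(-((wn - bands$center[i])^2) / (2 * bands$sigma[i]^2))
  }
  out
}

# draw one plaque into the density matrix; returns updated (density, labels)
draw_plaque <- function(density, labels, type, cy, cx, pars, id) {
  h <- nrow(density); w <- ncol(density)
  r_max <- pars$r_out
  rows <- max(1L, floor(cy - r_max)):min(h, ceiling(cy + r_max))
  cols <- max(1L, floor(cx - r_max)):min(w, ceiling(cx + r_max))
  dy <- rows - cy
  dx <- cols - cx
  rr <- outer(dy, dx, function(a, b) sqrt(a * a + b * b))
  d <- matrix(0, length(rows), length(cols))
  if (type == "cored") {
    d[rr <= pars$r_out] <- 0.45
    d[rr <= pars$r_core] <- 1.0
  } else if (type == "compact") {
    d[rr <= pars$r_out] <- 0.85
  } else { # diffuse: ragged star-shaped blob of low density
    th <- outer(dy, dx, function(a, b) atan2(a, b))
    rad <- pars$r_out * (0.7 + 0.3 * abs(sin(pars$freq * th + pars$phase)))
    inside <- rr <= rad
    tex <- matrix(stats::runif(length(d), 0.7, 1.3), nrow(d), ncol(d))
    d[inside] <- (0.35 * (1 - (rr[inside] / (rad[inside] + 1e-9))^2) *
                    tex[inside])
    d[inside] <- pmax(d[inside], 0.05)
  }
  sub_d <- density[rows, cols]
  sub_l <- labels[rows, cols]
  put <- d > 0 & sub_d == 0
  sub_d[put] <- d[put]
  sub_l[put] <- id
  density[rows, cols] <- sub_d
  labels[rows, cols] <- sub_l
  list(density = density, labels = labels)
}

#' Generate a synthetic hyperspectral scene with ground truth
#'
#' Places non-overlapping plaques of cored (dense disk plus lower-density
#' corona), compact, and diffuse (low, ragged density) morphologies on a
#' tissue background, optionally adds fold/hole artifacts, and synthesizes the
#' absorbance cube as
#' `background + density * jitter * (plaque - background) + baseline + noise`,
#' where `jitter` is a per-plaque amplitude factor (uniform +/-50%) emulating
#' plaque-to-plaque spectral heterogeneity. The same `seed` reproduces the
#' scene bit-identically.
#'
#' @param height,width Scene size in pixels (>= 64).
#' @param n_plaques Number of plaques to place (>= 0).
#' @param spectral A [spectral_model()].
#' @param seed Integer seed controlling all randomness of the scene.
#' @param axis Wavenumber axis of the cube (defaults to the full instrument
#'   grid; small scenes typically use a compressed band set).
#' @param pixel_size Pixel size in um/pixel.
#' @param n_folds,n_holes Number of fold / hole artifacts.
#' @param max_retries Placement retries per plaque before giving up.
#' @return `list(cube = spectral_cube, truth = scene_truth)`, where the truth
#'   carries `plaque_mask`, `plaque_density`, `plaque_labels`,
#'   `artifact_mask` and `pixel_size`.
#' @export
generate_scene <- function(height, width, n_plaques,
                           spectral = spectral_model(), seed = 1L,
                           axis = make_wavenumber_axis(1800, 948, 2),
                           pixel_size = 4.25,
                           n_folds = 1L, n_holes = 1L,
                           max_retries = 200L) {
  stopifnot(height >= 64, width >= 64, n_plaques >= 0)
  with_seed(seed, {
    density <- matrix(0, height, width)
    labels <- matrix(0L, height, width)
    centers <- matrix(numeric(0), 0, 3) # cy, cx, radius
    jitters <- numeric(0)
    types <- character(0)

    for (k in seq_len(n_plaques)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        type <- sample(c("cored", "compact", "diffuse"), 1,
                       prob = c(0.35, 0.35, 0.30))
        pars <- switch(type,
          cored = { rc <- stats::runif(1, 3, 5)
                    list(r_core = rc, r_out = rc + stats::runif(1, 3, 5)) },
          compact = list(r_out = stats::runif(1, 4, 7)),
          diffuse = list(r_out = stats::runif(1, 6, 10),
                         freq = sample(2:4, 1),
                         phase = stats::runif(1, 0, 2 * pi))
        )
        m <- pars$r_out + 2
        cy <- stats::runif(1, 1 + m, height - m)
        cx <- stats::runif(1, 1 + m, width - m)
        ok <- TRUE
        if (nrow(centers)) {
          dd <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
          ok <- all(dd > centers[, 3] + pars$r_out + 3)
        }
        if (ok) {
          res <- draw_plaque(density, labels, type, cy, cx, pars, k)
          density <- res$density; labels <- res$labels
          centers <- rbind(centers, c(cy, cx, pars$r_out))
          jitters <- c(jitters, 1 + stats::runif(1, -0.5, 0.5))
          types <- c(types, type)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("could only place %d of %d plaques without overlap",
                     k - 1L, n_plaques))
    }

    # artifacts: folds (bright lines) and holes (missing tissue), kept off
    # plaque pixels so the ground truth stays unambiguous
    artifact <- matrix(0L, height, width)
    artifact_mult <- matrix(1, height, width)
    for (f in seq_len(n_folds)) {
      th <- stats::runif(1, 0, pi)
      off <- stats::runif(1, 0.25, 0.75) *
        (abs(cos(th)) * width + abs(sin(th)) * height)
      yy <- matrix(seq_len(height), height, width)
      xx <- matrix(seq_len(width), height, width, byrow = TRUE)
      dist <- abs(sin(th) * yy + cos(th) * xx - off)
      hit <- dist <= 1 & density == 0
      artifact[hit] <- 1L
      artifact_mult[hit] <- 1.6
    }
    for (hls in seq_len(n_holes)) {
      r <- stats::runif(1, 4, 8)
      cy <- stats::runif(1, 1 + r, height - r)
      cx <- stats::runif(1, 1 + r, width - r)
      yy <- matrix(seq_len(height), height, width)
      xx <- matrix(seq_len(width), height, width, byrow = TRUE)
      hit <- (yy - cy)^2 + (xx - cx)^2 <= r^2 & density == 0
      artifact[hit] <- 1L
      artifact_mult[hit] <- 0.08
    }

    wn <- axis$values
    C <- axis$count
    hw <- height * width
    bg_spec <- endmember_spectrum(spectral$background, wn)
    pl_spec <- endmember_spectrum(spectral$plaque, wn)
    diff <- pl_spec - bg_spec

    jit_map <- matrix(1, height, width)
    if (n_plaques > 0) jit_map[labels > 0L] <- jitters[labels[labels > 0L]]
    eff <- as.vector(density * jit_map)

    X <- matrix(bg_spec, hw, C, byrow = TRUE) + eff %o% diff

    # per-pixel linear baseline, clamped to keep absorbance non-negative
    bi <- spectral$baseline_intercept
    intercept <- stats::runif(hw, bi[1], bi[2])
    mid <- (axis$start + axis$stop) / 2
    halfspan <- max(abs(wn - mid))
    slope <- stats::rnorm(hw, 0, spectral$baseline_slope_sd)
    if (halfspan > 0) {
      lim <- intercept / halfspan
      slope <- pmin(pmax(slope, -lim), lim)
    }
    baseline <- intercept + slope %o% (wn - mid)
    baseline[baseline < 0] <- 0 # guard against float rounding at the clamp
    X <- X + baseline

    X <- X * as.vector(artifact_mult)
    if (spectral$noise_sd > 0)
      X <- X + stats::rnorm(hw * C, 0, spectral$noise_sd)

    cube <- spectral_cube(array(X, c(height, width, C)), axis, pixel_size)
    truth <- structure(list(
      plaque_mask = matrix(as.integer(density > 0), height, width),
      plaque_density = density,
      plaque_labels = labels,
      artifact_mask = artifact,
      plaque_types = types,
      pixel_size = pixel_size
    ), class = "scene_truth")
    list(cube = cube, truth = truth)
  })
}

#' Staining parameters for the pseudo-IHC rendering
#'
#' @param dab_blue_min Blue-channel value at full DAB stain density (brown
#'   chromogen has a dark blue channel; default 0.1).
#' @param background_blue Blue-channel value of unstained tissue/background
#'   (default 0.95). Must exceed `dab_blue_min`.
#' @param counterstain_density Cresyl-violet speckle density in dots/mm^2.
#' @param seed Seed for speckle placement.
#' @return A list of class `stain_params`.
#' @export
stain_params <- function(dab_blue_min = 0.1, background_blue = 0.95,
                         counterstain_density = 2000, seed = 1L) {
  stopifnot(dab_blue_min >= 0, dab_blue_min < background_blue,
            background_blue <= 1, counterstain_density >= 0)
  structure(list(dab_blue_min = dab_blue_min,
                 background_blue = background_blue,
                 counterstain_density = counterstain_density,
                 seed = as.integer(seed)),
            class = "stain_params")
}

#' Render a pseudo-IHC image from scene truth
#'
#' Produces an RGB image emulating an anti-amyloid DAB stain with cresyl
#' violet counterstain: brown where plaque density is positive (blue channel
#' `background_blue - density * (background_blue - dab_blue_min)`), a white
#' background sprinkled with small violet counterstain dots (which mostly
#' reduce the red/green channels, leaving the blue channel above 0.9), and
#' faint gray rendering of fold/hole artifacts.
#'
#' @param truth A `scene_truth` from [generate_scene()].
#' @param stain A [stain_params()].
#' @return Numeric array `[H, W, 3]` with values in `[0, 1]`.
#' @export
render_pseudo_ihc <- function(truth, stain = stain_params()) {
  stopifnot(inherits(truth, "scene_truth"))
  d <- truth$plaque_density
  h <- nrow(d); w <- ncol(d)
  bb <- stain$background_blue
  R <- matrix(bb, h, w); G <- matrix(bb, h, w); B <- matrix(bb, h, w)

  # faint artifact rendering (keeps blue >= 0.9 so the mask chain ignores it)
  art <- truth$artifact_mask > 0
  R[art] <- 0.90; G[art] <- 0.90; B[art] <- 0.90

  # DAB brown proportional to density
  R <- R - d * (R - 0.45)
  G <- G - d * (G - 0.25)
  B <- B - d * (B - stain$dab_blue_min)

  # violet counterstain speckle (bounded size: 1-2 px)
  area_mm2 <- (h * truth$pixel_size / 1000) * (w * truth$pixel_size / 1000)
  n_dots <- round(stain$counterstain_density * area_mm2)
  if (n_dots > 0) {
    with_seed(stain$seed, {
      ys <- sample.int(h, n_dots, replace = TRUE)
      xs <- sample.int(w, n_dots, replace = TRUE)
      grow <- stats::runif(n_dots) < 0.3
      if (any(grow)) {
        step <- sample(c(-1L, 1L), sum(grow), replace = TRUE)
        vert <- stats::runif(sum(grow)) < 0.5
        y2 <- ys[grow] + ifelse(vert, step, 0L)
        x2 <- xs[grow] + ifelse(vert, 0L, step)
        ok <- y2 >= 1 & y2 <= h & x2 >= 1 & x2 <= w
        ys <- c(ys, y2[ok]); xs <- c(xs, x2[ok])
      }
      idx <- cbind(ys, xs)
      R[idx] <- pmin(R[idx], 0.72)
      G[idx] <- pmin(G[idx], 0.55)
      B[idx] <- pmin(B[idx], 0.92)
    })
  }
  out <- array(0, c(h, w, 3))
  out[, , 1] <- clip01(R); out[, , 2] <- clip01(G); out[, , 3] <- clip01(B)
  out
}
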