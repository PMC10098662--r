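#' Parameters of a synthetic device scene
#'
#' Describes one synthetic leaf-on-black-background scene as captured by a
#' touch-based four-band leaf imager: an ovate leaf centered in the frame, a
#' smooth multiplicative illumination field (two diffused LED boards), a
#' +/-45 degree nylon-thread grid spanning the imaging window, and additive
#' sensor noise. All reflectances are on the (0,1) scale; `noise_sd` is in
#' raw intensity counts at the chosen `bit_depth`.
#'
#' @param height,width frame size in pixels.
#' @param leaf_scale leaf major-axis length as a fraction of frame width.
#' @param reflectance named mean leaf reflectance per band, each in (0,1).
#' @param reflectance_texture_sd sd of the smooth multiplicative within-leaf
#'   texture field (shared across bands, so per-pixel NDVI is untouched).
#' @param illum_strength amplitude of the illumination field around its unit
#'   mean, in `[0, 1)`. 0 gives perfectly uniform light.
#' @param thread_spacing,thread_width grid period and line width in pixels;
#'   `thread_width < thread_spacing`.
#' @param thread_reflectance reflectance of the nylon threads, in (0, 1].
#' @param noise_sd additive Gaussian read-noise sd, raw counts.
#' @param background_level reflectance of the black felt background, in (0,1).
#' @param bit_depth sensor quantization, 8 or 16.
#' @param seed integer seed; every stochastic element is reproducible.
#' @return a `scene_params` list.
#' @export
scene_params <- function(height = 480, width = 600, leaf_scale = 0.75,
                         reflectance = c(blue = 0.10, green = 0.24,
                                         red = 0.12, nir = 0.60),
                         reflectance_texture_sd = 0.04,
                         illum_strength = 0.25,
                         thread_spacing = 24, thread_width = 2,
                         thread_reflectance = 0.85,
                         noise_sd = 80, background_level = 0.02,
                         bit_depth = 16, seed = 1L) {
  stopifnot(
    thread_width < thread_spacing,
    all(reflectance > 0), all(reflectance < 1),
    leaf_scale > 0, leaf_scale <= 1,
    illum_strength >= 0, illum_strength < 1,
    thread_reflectance > 0, thread_reflectance <= 1,
    background_level > 0, background_level < 1,
    bit_depth %in% c(8, 16),
    noise_sd >= 0
  )
  if (!setequal(names(reflectance), PHENOLEAF_BANDS)) {
    abort("reflectance must name blue, green, red, nir")
  }
  structure(
    list(height = height, width = width, leaf_scale = leaf_scale,
         reflectance = reflectance[PHENOLEAF_BANDS],
         reflectance_texture_sd = reflectance_texture_sd,
         illum_strength = illum_strength,
         thread_spacing = thread_spacing, thread_width = thread_width,
         thread_reflectance = thread_reflectance, noise_sd = noise_sd,
         background_level = background_level, bit_depth = bit_depth,
         seed = as.integer(seed)),
    class = "scene_params"
  )
}

#' Generate a soybean-like ovate leaf mask
#'
#' Places a single connected ovate outline (superellipse-like half-width
#' profile tapering to a tip) at the frame center, with seed-controlled
#' jitter of position, aspect and rotation. Area is roughly a third of the
#' frame at the default `leaf_scale`.
#'
#' @param params a [scene_params()].
#' @return logical matrix, `TRUE` on leaf pixels.
#' @export
generate_leaf_mask <- function(params) {
  h <- params$height; w <- params$width
  if (min(h, w) < 32) abort("degenerate frame: sides must be >= 32 px")
  withr::with_seed(params$seed, {
    jitter_x <- runif(1, -0.03, 0.03) * w
    jitter_y <- runif(1, -0.03, 0.03) * h
    aspect <- runif(1, 0.85, 1.05)
    theta <- runif(1, -8, 8) * pi / 180
  })
  cx <- (w + 1) / 2 + jitter_x
  cy <- (h + 1) / 2 + jitter_y
  a <- 0.5 * params$leaf_scale * w          # semi-major (along leaf axis)
  b <- 0.40 * params$leaf_scale * h * aspect # max semi-width
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  row <- matrix(seq_len(h), h, w)
  xr <- (col - cx) * cos(theta) + (row - cy) * sin(theta)
  yr <- -(col - cx) * sin(theta) + (row - cy) * cos(theta)
  u <- xr / a
  inside <- abs(u) < 1
  # ovate half-width profile: broad near the base (u = -1), pointed tip (u = 1)
  prof <- matrix(0, h, w)
  prof[inside] <- (1 - u[inside])^0.55 * (1 + u[inside])^0.85
  prof_max <- (2 * 0.55 / (0.55 + 0.85))^0.55 * (2 * 0.85 / (0.55 + 0.85))^0.85
  inside & abs(yr) <= b * prof / prof_max
}

# +/-45 degree thread grid over the whole frame
thread_grid <- function(params) {
  h <- params$height; w <- params$width
  s <- params$thread_spacing; tw <- params$thread_width
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  row <- matrix(seq_len(h), h, w)
  ((row + col) %% s) < tw | ((row - col) %% s) < tw
}

# smooth unit-mean illumination field: centered Gaussian plus linear ramp,
# rescaled so the peak deviation from 1 equals illum_strength
illumination_field <- function(params) {
  h <- params$height; w <- params$width
  if (params$illum_strength == 0) return(matrix(1, h, w))
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  row <- matrix(seq_len(h), h, w)
  g <- exp(-(((col - (w + 1) / 2) / (0.45 * w))^2 +
               ((row - (h + 1) / 2) / (0.45 * h))^2))
  ramp <- 0.3 * (col / w - 0.5)
  f <- g + ramp
  dev <- f - mean(f)
  1 + params$illum_strength * dev / max(abs(dev))
}

# smooth multiplicative texture: low-pass filtered white noise, unit mean
texture_field <- function(params) {
  h <- params$height; w <- params$width
  if (params$reflectance_texture_sd == 0) return(matrix(1, h, w))
  z <- matrix(rnorm(h * w), h, w)
  sm <- gaussian_blur(z, sigma = min(h, w) / 24)
  sm <- (sm - mean(sm)) / sd(sm)
  1 + params$reflectance_texture_sd * sm
}

# separable FFT Gaussian blur with circular wrap; adequate for generating
# smooth random fields (not used on measurement paths)
gaussian_blur <- function(x, sigma) {
  h <- nrow(x); w <- ncol(x)
  gy <- stats::dnorm(c(0:(h %/% 2), -((h - h %/% 2 - 1):1)), sd = sigma)
  gx <- stats::dnorm(c(0:(w %/% 2), -((w - w %/% 2 - 1):1)), sd = sigma)
  gy <- gy / sum(gy); gx <- gx / sum(gx)
  Re(fft(fft(x) * outer(fft(gy), fft(gx)), inverse = TRUE)) / (h * w)
}

#' Render a synthetic raw/white image pair with ground truth
#'
#' Composites reflectance (background felt, textured leaf, thread grid
#' overriding both), multiplies by the illumination field and a gain chosen
#' so the white reference just fills the sensor range, quantizes to
#' `bit_depth`, and adds Gaussian read noise to the raw image. The white
#' image is the illumination field times the same gain (a perfect white
#' panel), so flat-fielding recovers reflectance up to quantization.
#'
#' @param params a [scene_params()].
#' @return list with elements `raw` and `white` ([multispectral_image()]s)
#'   and `truth` (list: `leaf_mask`, `thread_mask`, `true_reflectance`,
#'   `true_mean_ndvi`). `true_reflectance` is the leaf/background composite
#'   before thread overlay; `true_mean_ndvi` is its leaf-masked NDVI mean.
#' @export
render_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  leaf <- generate_leaf_mask(params)
  threads <- thread_grid(params)
  illum <- illumination_field(params)
  full <- 2^params$bit_depth - 1
  gain <- full / max(illum)
  tex <- withr::with_seed(params$seed + 1L, texture_field(params))
  true_refl <- lapply(PHENOLEAF_BANDS, function(b) {
    r <- matrix(params$background_level, params$height, params$width)
    r[leaf] <- pmin(pmax(params$reflectance[[b]] * tex[leaf], 0.001), 0.999)
    r
  })
  names(true_refl) <- PHENOLEAF_BANDS
  noise <- withr::with_seed(params$seed + 2L, {
    lapply(PHENOLEAF_BANDS, function(b) {
      if (params$noise_sd > 0)
        matrix(rnorm(params$height * params$width, sd = params$noise_sd),
               params$height, params$width)
      else 0
    })
  })
  names(noise) <- PHENOLEAF_BANDS
  raw_bands <- lapply(PHENOLEAF_BANDS, function(b) {
    r <- true_refl[[b]]
    r[threads] <- params$thread_reflectance
    counts <- round(illum * r * gain + noise[[b]])
    pmin(pmax(counts, 0), full)
  })
  names(raw_bands) <- PHENOLEAF_BANDS
  white_counts <- pmin(pmax(round(illum * gain), 0), full)
  white_bands <- lapply(PHENOLEAF_BANDS, function(b) white_counts)
  names(white_bands) <- PHENOLEAF_BANDS
  nd <- (true_refl$nir - true_refl$red) / (true_refl$nir + true_refl$red)
  list(
    raw = multispectral_image(raw_bands, role = "raw",
                              bit_depth = params$bit_depth),
    white = multispectral_image(white_bands, role = "white",
                                bit_depth = params$bit_depth),
    truth = list(leaf_mask = leaf, thread_mask = threads,
                 true_reflectance = true_refl,
                 true_mean_ndvi = mean(nd[leaf]))
  )
}

#' Draw a two-group synthetic experiment design
#'
#' Emulates a two-treatment trial (e.g. high/low nitrogen with 10 replicate
#' plants each): per-leaf true NDVI is drawn from
#' `Normal(group mean, between_sd)` and imposed on the scene by solving the
#' red reflectance with NIR held at `base$reflectance["nir"]`
#' (`red = nir * (1 - d) / (1 + d)`); green and blue follow red at fixed
#' ratios (2x and 0.8x) so Greenness stays well above 1 on leaf tissue.
#'
#' @param n_per_group leaves (plants) per treatment group, `>= 2`.
#' @param ndvi_low,ndvi_high group mean true NDVI of the two treatments.
#' @param between_sd between-leaf sd of true NDVI.
#' @param base a [scene_params()] supplying everything but the reflectance.
#' @param seed integer seed for the draws and the per-scene seeds.
#' @return tibble with columns `sample_id`, `group` (`"low"`/`"high"`),
#'   `true_ndvi`, and `params` (list column of per-leaf [scene_params()]).
#' @export
generate_experiment <- function(n_per_group = 10, ndvi_low = 0.55,
                                ndvi_high = 0.70, between_sd = 0.05,
                                base = scene_params(), seed = 1L) {
  stopifnot(n_per_group >= 2)
  nir <- base$reflectance[["nir"]]
  d <- withr::with_seed(as.integer(seed), {
    c(rnorm(n_per_group, ndvi_low, between_sd),
      rnorm(n_per_group, ndvi_high, between_sd))
  })
  d <- pmin(pmax(d, -0.999), 0.999)
  red <- nir * (1 - d) / (1 + d)
  if (any(red <= 0 | red >= 1)) {
    abort(sprintf(
      "infeasible NDVI for nir = %.3f: required red reflectance outside (0,1)",
      nir))
  }
  group <- rep(c("low", "high"), each = n_per_group)
  params <- lapply(seq_along(d), function(i) {
    p <- base
    p$reflectance <- c(blue = min(0.8 * red[i], 0.95),
                       green = min(2 * red[i], 0.95),
                       red = red[i], nir = nir)
    p$seed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483646 + 1)
    class(p) <- "scene_params"
    p
  })
  tibble::tibble(
    sample_id = sprintf("%s_%02d", group, rep(seq_len(n_per_group), 2)),
    group = group,
    true_ndvi = d,
    params = params
  )
}

#' Write a synthetic experiment to disk as device-like files
#'
#' Renders every scene of a design, writes raw/white TIFF pairs and truth
#' masks, and emits a manifest CSV consumable by [run_experiment()].
#'
#' @param design tibble from [generate_experiment()].
#' @param dir output directory (created if needed).
#' @return the manifest tibble (also written to `dir/manifest.csv`),
#'   with a `true_ndvi` column appended for reference.
#' @export
write_experiment <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::pmap(design, function(sample_id, group, true_ndvi, params) {
    sc <- render_scene(params)
    raw_path <- file.path(dir, paste0(sample_id, ".raw.tiff"))
    white_path <- file.path(dir, paste0(sample_id, ".white.tiff"))
    write_multispectral(sc$raw, raw_path)
    write_multispectral(sc$white, white_path)
    mask_path <- file.path(dir, paste0(sample_id, ".leafmask.tiff"))
    tiff::writeTIFF(sc$truth$leaf_mask * 1, mask_path, bits.per.sample = 8)
    tibble::tibble(sample_id = sample_id, image_path = raw_path,
                   white_path = white_path, plant_id = sample_id,
                   plot_id = group, treatment = group,
                   leaf_position = "top", true_ndvi = true_ndvi)
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest[setdiff(names(manifest), "true_ndvi")],
                   file.path(dir, "manifest.csv"))
  manifest
}
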