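#' Gabor filter parameterization
#'
#' A complex 2-D Gabor filter: a sinusoidal carrier of the given wavelength
#' travelling along the wave-vector direction `orientation_deg` (CCW from
#' +x), under an elliptical Gaussian envelope. A small `aspect_ratio`
#' elongates the envelope perpendicular to the wave vector, tuning the
#' filter to line-like structures such as the nylon threads. The envelope
#' sigma follows the standard half-response bandwidth closed form
#' `sigma = lambda * (1/pi) * sqrt(ln 2 / 2) * (2^b + 1) / (2^b - 1)`.
#'
#' @param wavelength carrier wavelength, pixels per cycle (default 5).
#' @param aspect_ratio spatial aspect ratio gamma in (0, 1] (default 0.1).
#' @param orientation_deg wave-vector direction, degrees CCW from +x.
#' @param bandwidth_octaves half-response spatial-frequency bandwidth
#'   (default 1 octave).
#' @param phase_offset carrier phase psi, radians (default 0).
#' @param dc_correct subtract the mean of the real part so the filter has
#'   zero response to constant input (default `TRUE`).
#' @return a `gabor_params` list with the derived `sigma` attached.
#' @export
gabor_params <- function(wavelength = 5, aspect_ratio = 0.1,
                         orientation_deg = 45, bandwidth_octaves = 1,
                         phase_offset = 0, dc_correct = TRUE) {
  stopifnot(wavelength >= 2, aspect_ratio > 0, aspect_ratio <= 1,
            bandwidth_octaves > 0)
  b <- bandwidth_octaves
  sigma <- wavelength * (1 / pi) * sqrt(log(2) / 2) * (2^b + 1) / (2^b - 1)
  structure(list(wavelength = wavelength, aspect_ratio = aspect_ratio,
                 orientation_deg = orientation_deg,
                 bandwidth_octaves = b, phase_offset = phase_offset,
                 dc_correct = dc_correct, sigma = sigma),
            class = "gabor_params")
}

#' Build the complex Gabor kernel
#'
#' `g(x, y) = exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) *
#' exp(i (2 pi x' / lambda + psi))` with `x' = x cos(theta) + y sin(theta)`,
#' `y' = -x sin(theta) + y cos(theta)`. Support is a square truncated at
#' `3 sigma / gamma`, odd-sized. With `dc_correct` the real part is made
#' zero-mean.
#'
#' @param params a [gabor_params()].
#' @return complex matrix; `x` increases with column, `y` with row.
#' @export
gabor_kernel <- function(params) {
  stopifnot(inherits(params, "gabor_params"))
  sigma <- params$sigma
  gamma <- params$aspect_ratio
  half <- ceiling(3 * sigma / gamma)
  xs <- -half:half
  x <- matrix(xs, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  y <- matrix(xs, 2 * half + 1, 2 * half + 1)
  th <- params$orientation_deg * pi / 180
  xp <- x * cos(th) + y * sin(th)
  yp <- -x * sin(th) + y * cos(th)
  env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
  g <- env * exp(1i * (2 * pi * xp / params$wavelength + params$phase_offset))
  if (params$dc_correct) g <- g - mean(Re(g))
  g
}

# symmetric (edge-repeating) reflection padding by p pixels on each side
pad_symmetric <- function(x, p) {
  h <- nrow(x); w <- ncol(x)
  if (p > h || p > w) {
    abort("raster smaller than kernel support",
          class = "phenoleaf_kernel_support")
  }
  ri <- c(p:1, 1:h, h:(h - p + 1))
  ci <- c(p:1, 1:w, w:(w - p + 1))
  x[ri, ci, drop = FALSE]
}

# circular correlation of a real raster with a complex kernel via FFT
fft_correlate <- function(x, kernel) {
  h <- nrow(x); w <- ncol(x)
  kh <- (nrow(kernel) - 1L) / 2L
  kw <- (ncol(kernel) - 1L) / 2L
  embed <- matrix(0 + 0i, h, w)
  for (u in -kh:kh) {
    r <- ((-u) %% h) + 1L
    cc <- ((-(-kw:kw)) %% w) + 1L
    embed[r, cc] <- kernel[u + kh + 1L, (-kw:kw) + kw + 1L]
  }
  fft(fft(x) * fft(embed), inverse = TRUE) / (h * w)
}

#' Apply a Gabor filter to a raster
#'
#' Complex correlation of the raster with the kernel, with symmetric
#' (edge-reflecting) boundary padding; returns the per-pixel magnitude and
#' phase of the complex response. FFT-based; numerically equal to direct
#' spatial-domain correlation.
#'
#' @param image_band 2-D numeric raster, finite values.
#' @param params a [gabor_params()].
#' @return a `gabor_response` list: `magnitude` (>= 0) and `phase`
#'   (`(-pi, pi]`), both shaped like the input.
#' @export
gabor_response <- function(image_band, params) {
  stopifnot(is.matrix(image_band), all(is.finite(image_band)))
  kernel <- gabor_kernel(params)
  half <- (nrow(kernel) - 1L) / 2L
  padded <- pad_symmetric(image_band, half)
  resp <- fft_correlate(padded, kernel)
  h <- nrow(image_band); w <- ncol(image_band)
  core <- resp[half + seq_len(h), half + seq_len(w), drop = FALSE]
  structure(list(magnitude = Mod(core), phase = Arg(core)),
            class = "gabor_response")
}

#' Detect the nylon-thread grid
#'
#' Runs the Gabor filter on the calibrated NIR band at each orientation
#' (default both grid directions, 45 and 135 degrees), thresholds each
#' magnitude map at `rel_threshold` times its 99th percentile over the
#' frame, unions the detections and dilates by `dilate_radius`. The
#' threshold is relative so the same configuration works across bit depths
#' and on reflectance-scale input (an absolute magnitude cut would be tied
#' to one intensity scale).
#'
#' @param cal calibrated [multispectral_image()].
#' @param leaf logical leaf mask (for the coverage statistic).
#' @param orientations wave-vector orientations in degrees
#'   (default `c(45, 135)`).
#' @param params a [gabor_params()]; its `orientation_deg` is overridden per
#'   element of `orientations`.
#' @param rel_threshold fraction of the 99th-percentile magnitude
#'   (default 0.25).
#' @param dilate_radius mask dilation radius in pixels (default 1).
#' @param band band to run detection on (default `"nir"`, the highest
#'   leaf/thread contrast).
#' @return logical thread mask with attribute `coverage`, the fraction of
#'   leaf pixels masked.
#' @export
thread_mask <- function(cal, leaf, orientations = c(45, 135),
                        params = gabor_params(), rel_threshold = 0.25,
                        dilate_radius = 1, band = "nir") {
  stopifnot(inherits(cal, "multispectral_image"), is.matrix(leaf))
  if (!length(orientations)) abort("orientations must be nonempty")
  if (!any(leaf)) abort("leaf mask empty", class = "phenoleaf_no_leaf")
  x <- cal$bands[[match.arg(band, PHENOLEAF_BANDS)]]
  mask <- matrix(FALSE, nrow(x), ncol(x))
  for (o in orientations) {
    p <- params
    p$orientation_deg <- o
    mag <- gabor_response(x, p)$magnitude
    p99 <- stats::quantile(mag, 0.99, names = FALSE)
    if (is.finite(rel_threshold)) {
      mask <- mask | (mag > rel_threshold * p99)
    }
  }
  if (dilate_radius >= 1 && any(mask)) {
    m <- mask
    mode(m) <- "integer"
    mask <- EBImage::dilate(m, EBImage::makeBrush(2 * dilate_radius + 1,
                                                  "disc")) > 0
  }
  attr(mask, "coverage") <- sum(mask & leaf) / sum(leaf)
  mask
}
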