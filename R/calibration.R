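#' White-reference flat-field calibration
#'
#' Divides each raw band by the matching band of a white-reference image,
#' cancelling the non-uniform illumination of the LED boards. The same white
#' image can be reused across samples, since the non-uniformity depends only
#' on the fixed LED geometry. The denominator is floored at `epsilon` counts
#' to bound amplification in vignetted corners, and the quotient is clipped
#' at `clip_max` (specular thread highlights can exceed the white panel).
#'
#' @param raw a [multispectral_image()] with role `raw`.
#' @param white a [multispectral_image()] with role `white`, same shape and
#'   bit depth.
#' @param epsilon denominator floor, intensity counts (default 1).
#' @param clip_max reflectance ceiling (default 2); the number of clipped
#'   pixels is recorded in the `clipped` attribute of the result.
#' @return a calibrated [multispectral_image()] (float reflectance).
#' @examples
#' b <- matrix(240, 6, 6)
#' w <- multispectral_image(list(blue = b, green = b, red = b, nir = b),
#'                          role = "white", bit_depth = 8)
#' r <- multispectral_image(lapply(w$bands, function(x) x * 0 + 60),
#'                          role = "raw", bit_depth = 8)
#' band(flat_field(r, w), "red")[1, 1]  # 0.25
#' @export
flat_field <- function(raw, white, epsilon = 1, clip_max = 2) {
  stopifnot(inherits(raw, "multispectral_image"),
            inherits(white, "multispectral_image"))
  if (raw$role != "raw" || white$role != "white") {
    abort("flat_field needs a raw image and a white reference, in that order",
          class = "phenoleaf_role_mismatch")
  }
  if (!identical(dim(raw), dim(white)) ||
      !identical(raw$bit_depth, white$bit_depth)) {
    abort("raw and white must share shape and bit depth",
          class = "phenoleaf_shape_mismatch")
  }
  if (any(vapply(white$bands, function(b) all(b == 0), logical(1)))) {
    abort("corrupt white reference: an all-zero band",
          class = "phenoleaf_corrupt_white")
  }
  clipped <- 0L
  cal <- lapply(PHENOLEAF_BANDS, function(b) {
    q <- raw$bands[[b]] / pmax(white$bands[[b]], epsilon)
    clipped <<- clipped + sum(q > clip_max)
    pmin(q, clip_max)
  })
  names(cal) <- PHENOLEAF_BANDS
  out <- multispectral_image(cal, role = "calibrated")
  attr(out, "clipped") <- clipped
  out
}
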