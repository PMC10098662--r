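#' Per-pixel index map (Greenness or NDVI)
#'
#' Thin container for a scalar per-pixel map plus the mask of pixels where
#' its defining ratio was computable.
#'
#' @param values numeric matrix.
#' @param kind `"greenness"` or `"ndvi"`.
#' @param valid_mask logical matrix, `TRUE` where the ratio was computable.
#' @return an `index_map` object.
#' @keywords internal
index_map <- function(values, kind = c("greenness", "ndvi"), valid_mask) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), is.matrix(valid_mask),
            identical(dim(values), dim(valid_mask)))
  structure(list(values = values, kind = kind, valid_mask = valid_mask),
            class = "index_map")
}

#' @export
print.index_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("<index_map:%s> %d x %d, %d valid px, range [%.3f, %.3f]\n",
              x$kind, nrow(x$values), ncol(x$values), length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Greenness map of a calibrated image
#'
#' Greenness = green^2 / (red * blue). Neutral (grey/black/white) surfaces
#' score about 1; green tissue scores well above 1, which separates the leaf
#' from the black felt background. The denominator is floored at `epsilon^2`
#' and pixels below the floor are flagged invalid.
#'
#' @param cal calibrated [multispectral_image()].
#' @param epsilon reflectance floor for red and blue (default 0.01).
#' @return an `index_map` of kind `greenness`.
#' @export
greenness_map <- function(cal, epsilon = 0.01) {
  stopifnot(inherits(cal, "multispectral_image"))
  if (cal$role != "calibrated") {
    abort("greenness_map expects a calibrated image",
          class = "phenoleaf_role_mismatch")
  }
  den <- cal$bands$red * cal$bands$blue
  valid <- den >= epsilon^2
  values <- cal$bands$green^2 / pmax(den, epsilon^2)
  index_map(values, "greenness", valid)
}

#' Threshold a Greenness map into a leaf mask
#'
#' With `method = "otsu"` the threshold is chosen by Otsu's criterion on the
#' valid, finite Greenness values (256 histogram bins); with
#' `method = "fixed"` the given threshold is used. The mask is
#' `values > threshold` restricted to valid pixels. An empty result is
#' flagged via the `empty` attribute, not an error.
#'
#' @param greenness an `index_map` of kind `greenness`.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold fixed threshold (default 1.5; ignored under otsu).
#' @return logical leaf mask with attributes `threshold` (the value used)
#'   and `empty`.
#' @export
threshold_leaf <- function(greenness, method = c("otsu", "fixed"),
                           threshold = 1.5) {
  method <- match.arg(method)
  stopifnot(inherits(greenness, "index_map"))
  if (greenness$kind != "greenness") {
    abort("threshold_leaf expects a greenness index_map")
  }
  v <- greenness$values[greenness$valid_mask & is.finite(greenness$values)]
  if (!length(v)) abort("empty valid region", class = "phenoleaf_empty_region")
  if (method == "otsu") {
    rng <- range(v)
    if (diff(rng) == 0) {
      threshold <- rng[1]
    } else {
      scaled <- (v - rng[1]) / diff(rng)
      th01 <- EBImage::otsu(EBImage::Image(matrix(scaled, nrow = 1)),
                            range = c(0, 1), levels = 256)
      threshold <- th01 * diff(rng) + rng[1]
    }
  }
  mask <- greenness$valid_mask & is.finite(greenness$values) &
    greenness$values > threshold
  attr(mask, "threshold") <- threshold
  attr(mask, "empty") <- !any(mask)
  mask
}

#' Morphologically refine a leaf mask
#'
#' Dilation followed by erosion (closing) with a disc brush smooths the leaf
#' edge and bridges small gaps; afterwards all connected components except
#' the largest are dropped, removing specks.
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels (default 2).
#' @param min_area minimum pixel count of the surviving component; default
#'   1% of the frame. Smaller largest components raise a "no leaf found"
#'   error.
#' @return logical mask with exactly one connected component.
#' @export
refine_mask <- function(mask, radius = 2, min_area = NULL) {
  stopifnot(is.matrix(mask), radius >= 1)
  mode(mask) <- "integer"
  if (is.null(min_area)) min_area <- ceiling(0.01 * length(mask))
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  closed <- EBImage::closing(mask, brush)
  lab <- EBImage::bwlabel(closed)
  if (max(lab) == 0) {
    abort("no leaf found: mask empty after closing",
          class = "phenoleaf_no_leaf")
  }
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  if (sizes[keep] < min_area) {
    abort(sprintf("no leaf found: largest component %d px < min_area %d px",
                  sizes[keep], as.integer(min_area)),
          class = "phenoleaf_no_leaf")
  }
  out <- lab == keep
  out
}

#' Intersection-over-union of two binary masks
#' @param a,b logical matrices of equal shape.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
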