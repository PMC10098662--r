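#' Exemplar inpainting parameters
#'
#' @param patch_size odd patch side length in pixels (default 9).
#' @param data_term `"gradient"` (classic isophote term, default) or
#'   `"tensor"` (structure-tensor variant of the fill-order term).
#' @param search_mask optional logical raster of allowed source pixels; by
#'   default [inpaint_exemplar()] restricts the search to the intact leaf.
#' @param alpha normalization constant of the data term (default 1.0 on
#'   reflectance scale).
#' @return an `inpaint_params` list.
#' @export
inpaint_params <- function(patch_size = 9,
                           data_term = c("gradient", "tensor"),
                           search_mask = NULL, alpha = 1.0) {
  data_term <- match.arg(data_term)
  stopifnot(patch_size >= 3, patch_size %% 2 == 1, alpha > 0)
  structure(list(patch_size = as.integer(patch_size), data_term = data_term,
                 search_mask = search_mask, alpha = alpha),
            class = "inpaint_params")
}

#' Initial fill state for exemplar inpainting
#'
#' Confidence starts at 1 on source (intact) pixels and 0 on target pixels;
#' the fill front is the set of target pixels with at least one intact
#' 8-neighbour.
#'
#' @param target logical raster of pixels to be filled.
#' @return a `fill_state` list: `confidence`, `fill_front` (two-column
#'   matrix of 1-based (row, col) coordinates), `remaining`.
#' @export
fill_state <- function(target) {
  stopifnot(is.matrix(target))
  confidence <- matrix(as.numeric(!target), nrow(target), ncol(target))
  structure(list(confidence = confidence,
                 fill_front = front_coords(!target),
                 remaining = sum(target)),
            class = "fill_state")
}

# target pixels (unfilled) adjacent (8-connectivity) to a filled pixel
front_coords <- function(filled) {
  h <- nrow(filled); w <- ncol(filled)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- filled
  near <- matrix(FALSE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    near <- near | pad[2:(h + 1) + dr, 2:(w + 1) + dc]
  }
  which(!filled & near, arr.ind = TRUE)
}

#' Fill priority of a front pixel
#'
#' `priority = C(p) * D(p)`: `C` is the mean confidence over the patch at
#' `p` (clipped to the frame); `D` is the data term, `|isophote . n| /
#' alpha` with the isophote taken from the maximum finite-difference
#' gradient over filled patch pixels (gradient variant) or from the
#' structure tensor's minor eigen-direction scaled by the root dominant
#' eigenvalue (tensor variant); `n` is the unit front normal.
#'
#' @param state a [fill_state()].
#' @param image_band 2-D numeric raster the isophotes are read from.
#' @param p length-2 integer (row, col), 1-based, on the fill front.
#' @param params an [inpaint_params()].
#' @return non-negative priority value.
#' @export
patch_priority <- function(state, image_band, p, params = inpaint_params()) {
  stopifnot(inherits(state, "fill_state"), length(p) == 2)
  on_front <- any(state$fill_front[, 1] == p[1] & state$fill_front[, 2] == p[2])
  if (!on_front) abort("p is not on the fill front",
                       class = "phenoleaf_not_on_front")
  filled <- state$confidence > 0
  cpp_priority(image_band, filled, state$confidence,
               p[1] - 1L, p[2] - 1L, (params$patch_size - 1L) %/% 2L,
               params$alpha, if (params$data_term == "gradient") 0L else 1L)
}

# centers whose full patch lies inside the frame with every pixel allowed;
# exact integral-image count, no border leniency
admissible_centers <- function(mask, patch_size) {
  h <- nrow(mask); w <- ncol(mask)
  half <- (patch_size - 1L) %/% 2L
  cs <- rbind(0, apply(mask, 2, cumsum))
  ii <- cbind(0, t(apply(cs, 1, cumsum)))            # (h+1) x (w+1) integral
  ok <- matrix(FALSE, h, w)
  rr <- (half + 1):(h - half); cc <- (half + 1):(w - half)
  if (length(rr) && length(cc) && h - 2 * half > 0 && w - 2 * half > 0) {
    r1 <- rr - half; r2 <- rr + half
    c1 <- cc - half; c2 <- cc + half
    cnt <- ii[r2 + 1, c2 + 1, drop = FALSE] - ii[r1, c2 + 1, drop = FALSE] -
      ii[r2 + 1, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
    ok[rr, cc] <- cnt == patch_size^2
  }
  ok
}

#' Best-matching source patch for a target patch
#'
#' Exhaustively minimizes the summed squared difference over the target
#' patch's already-filled pixels, summed across all four bands, over every
#' candidate center whose full patch lies inside `params$search_mask`.
#' Ties are broken by the smallest row-major linear index.
#'
#' @param image [multispectral_image()].
#' @param target_patch_center length-2 (row, col), 1-based.
#' @param state a [fill_state()].
#' @param params an [inpaint_params()]; `search_mask` must be set.
#' @return list: `center` (row, col), `ssd`.
#' @export
best_source_patch <- function(image, target_patch_center, state,
                              params = inpaint_params()) {
  stopifnot(inherits(image, "multispectral_image"),
            inherits(state, "fill_state"))
  if (is.null(params$search_mask)) {
    abort("params$search_mask must be a logical raster of allowed source pixels")
  }
  ok <- admissible_centers(params$search_mask, params$patch_size)
  idx <- which(ok, arr.ind = TRUE)
  if (!nrow(idx)) {
    abort("no admissible source patch: mask too dense for patch size",
          class = "phenoleaf_no_source")
  }
  arr <- band_array(image)
  filled <- state$confidence > 0
  res <- cpp_best_source(arr, filled,
                         target_patch_center[1] - 1L,
                         target_patch_center[2] - 1L,
                         as.integer(idx[, 1] - 1L), as.integer(idx[, 2] - 1L),
                         (params$patch_size - 1L) %/% 2L)
  list(center = c(res$r + 1L, res$c + 1L), ssd = res$ssd)
}

band_array <- function(image) {
  arr <- array(0, c(image$height, image$width, 4L))
  for (i in seq_along(PHENOLEAF_BANDS)) arr[, , i] <- image$bands[[i]]
  arr
}

array_to_image <- function(arr, role = "calibrated") {
  bands <- lapply(seq_len(4), function(i) arr[, , i])
  names(bands) <- PHENOLEAF_BANDS
  multispectral_image(bands, role = role)
}

#' Exemplar-based inpainting of thread-occluded pixels
#'
#' Priority-ordered patch-copy inpainting: repeatedly takes the
#' highest-priority pixel on the fill front, finds the best-matching fully
#' intact source patch inside the leaf, and copies its pixels into the
#' unfilled positions of the target patch across all four bands jointly
#' (one fill order, one SSD over bands, so red/NIR stay correlated and
#' NDVI is not distorted). Only `target` pixels near the leaf
#' (within `patch_size` of it) are inpainted; target pixels further out
#' (threads over the felt) are set to 0. The source search region is the
#' leaf minus the target, so every filled value is a copy of intact leaf
#' tissue.
#'
#' @param cal calibrated [multispectral_image()].
#' @param target logical thread mask (pixels to replace).
#' @param leaf logical leaf mask.
#' @param params an [inpaint_params()].
#' @return calibrated [multispectral_image()] with attributes `iterations`
#'   and `remaining_history` (unfilled-pixel count after each fill step).
#' @export
inpaint_exemplar <- function(cal, target, leaf, params = inpaint_params()) {
  stopifnot(inherits(cal, "multispectral_image"),
            is.matrix(target), is.matrix(leaf))
  if (cal$role != "calibrated") {
    abort("inpaint_exemplar expects a calibrated image",
          class = "phenoleaf_role_mismatch")
  }
  if (!any(target)) return(cal)
  leaf_zone <- EBImage::dilate(matrix(as.integer(leaf), nrow(leaf)),
                               EBImage::makeBrush(params$patch_size, "disc")) > 0
  fill_region <- target & leaf_zone
  far_target <- target & !leaf_zone
  arr <- band_array(cal)
  if (any(far_target)) {
    for (i in seq_len(4)) {
      pl <- arr[, , i]
      pl[far_target] <- 0
      arr[, , i] <- pl
    }
  }
  if (!any(fill_region)) {
    return(structure(array_to_image(arr), iterations = 0L,
                     remaining_history = integer(0)))
  }
  search <- params$search_mask %||% (leaf & !target)
  ok <- admissible_centers(search, params$patch_size)
  idx <- which(ok, arr.ind = TRUE)
  if (!nrow(idx)) {
    abort("no admissible source patch: mask too dense for patch size",
          class = "phenoleaf_no_source")
  }
  res <- cpp_inpaint(arr, fill_region,
                     as.integer(idx[, 1] - 1L), as.integer(idx[, 2] - 1L),
                     (params$patch_size - 1L) %/% 2L, params$alpha,
                     if (params$data_term == "gradient") 0L else 1L,
                     sum(fill_region) + 1L)
  out <- array_to_image(res$image)
  attr(out, "iterations") <- res$iterations
  attr(out, "remaining_history") <- res$remaining_history
  out
}
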