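#' Four-band multispectral image container
#'
#' Bundles four aligned single-channel rasters (blue 460 nm, green 525 nm,
#' red 630 nm, NIR 850 nm) with bit-depth metadata and a role tag. Raw and
#' white-reference images hold non-negative integer counts bounded by
#' `2^bit_depth - 1`; calibrated images hold non-negative floating-point
#' reflectance and carry no bit depth.
#'
#' @param bands named list of four numeric matrices, names exactly
#'   `blue`, `green`, `red`, `nir` (any order; stored canonically).
#' @param role one of `"raw"`, `"white"`, `"calibrated"`.
#' @param bit_depth 8 or 16 for `raw`/`white`; must be `NULL` for
#'   `calibrated`.
#' @return an object of class `multispectral_image`.
#' @examples
#' m <- matrix(100, 8, 10)
#' img <- multispectral_image(list(blue = m, green = m, red = m, nir = m),
#'                            role = "raw", bit_depth = 8)
#' dim(img)
#' @export
multispectral_image <- function(bands, role = c("raw", "white", "calibrated"),
                                bit_depth = NULL) {
  role <- match.arg(role)
  if (!is.list(bands) || !setequal(names(bands), PHENOLEAF_BANDS)) {
    abort(paste("missing band: expected exactly", toString(PHENOLEAF_BANDS)),
          class = "phenoleaf_missing_band")
  }
  bands <- bands[PHENOLEAF_BANDS]
  dims <- lapply(bands, dim)
  if (any(!vapply(bands, is.matrix, logical(1))) ||
      length(unique(dims)) != 1L) {
    abort("shape mismatch: all four bands must be identically shaped matrices",
          class = "phenoleaf_shape_mismatch")
  }
  if (role == "calibrated") {
    if (!is.null(bit_depth)) {
      abort("calibrated images are floating point and carry no bit depth",
            class = "phenoleaf_bad_bit_depth")
    }
  } else {
    if (is.null(bit_depth) || !bit_depth %in% c(8, 16)) {
      abort("raw/white images require bit_depth 8 or 16",
            class = "phenoleaf_bad_bit_depth")
    }
    full <- 2^bit_depth - 1
    rng <- range(unlist(lapply(bands, range)))
    if (rng[1] < 0 || rng[2] > full) {
      abort(sprintf("raw/white intensities must lie in [0, %d]", full),
            class = "phenoleaf_intensity_range")
    }
  }
  if (min(unlist(lapply(bands, min))) < 0) {
    abort("band intensities must be non-negative",
          class = "phenoleaf_intensity_range")
  }
  structure(
    list(bands = bands, height = nrow(bands[[1]]), width = ncol(bands[[1]]),
         bit_depth = bit_depth, role = role),
    class = "multispectral_image"
  )
}

#' @export
dim.multispectral_image <- function(x) c(x$height, x$width)

#' @export
print.multispectral_image <- function(x, ...) {
  cat(sprintf("<multispectral_image> %d x %d, role=%s%s, bands: %s\n",
              x$height, x$width, x$role,
              if (is.null(x$bit_depth)) " (float)"
              else sprintf(", %d-bit", x$bit_depth),
              toString(PHENOLEAF_BANDS)))
  invisible(x)
}

#' Extract one band as a matrix
#' @param image a [multispectral_image()].
#' @param band one of `"blue"`, `"green"`, `"red"`, `"nir"`.
#' @return numeric matrix.
#' @export
band <- function(image, band) {
  stopifnot(inherits(image, "multispectral_image"))
  band <- match.arg(band, PHENOLEAF_BANDS)
  image$bands[[band]]
}

#' Read a four-band multispectral TIFF (or four single-band TIFFs)
#'
#' Accepts either a multiband TIFF with at least four planes, or a character
#' vector of four single-band TIFF paths. Planes are mapped to band names via
#' `band_order`; the canonical order is blue, green, red, nir. Integer
#' sources yield `raw`/`white` images with the bit depth inferred from the
#' sample format; float sources yield `calibrated` images.
#'
#' @param path a TIFF path, or a character vector of four single-band paths.
#' @param band_order band names assigning planes/files, default canonical.
#' @param role role of the image (`"raw"`, `"white"` or `"calibrated"`);
#'   default infers `"calibrated"` for float samples and `"raw"` otherwise.
#' @return a [multispectral_image()].
#' @export
read_multispectral <- function(path, band_order = PHENOLEAF_BANDS,
                               role = NULL) {
  if (!setequal(band_order, PHENOLEAF_BANDS)) {
    abort("band_order must be a permutation of blue, green, red, nir",
          class = "phenoleaf_missing_band")
  }
  read_planes <- function(p, all) {
    # as.is=TRUE yields integer counts for integer TIFFs but is not
    # supported for float samples; fall back to native float reading
    tryCatch(tiff::readTIFF(p, all = all, as.is = TRUE, info = TRUE),
             error = function(e) {
               if (grepl("floating point", conditionMessage(e))) {
                 tiff::readTIFF(p, all = all, info = TRUE)
               } else {
                 stop(e)
               }
             })
  }
  if (length(path) == 1L) {
    planes <- read_planes(path, all = TRUE)
    if (length(planes) < 4L) {
      abort(sprintf("missing band: %s holds %d plane(s), need 4",
                    path, length(planes)),
            class = "phenoleaf_missing_band")
    }
    planes <- planes[seq_len(4L)]
  } else if (length(path) == 4L) {
    planes <- lapply(path, function(p) read_planes(p, all = FALSE))
  } else {
    abort("path must be one multiband TIFF or four single-band TIFFs",
          class = "phenoleaf_missing_band")
  }
  if (length(unique(lapply(planes, dim))) != 1L) {
    abort("shape mismatch across band files",
          class = "phenoleaf_shape_mismatch")
  }
  names(planes) <- band_order
  # tiff::readTIFF(as.is = TRUE) returns integer counts (of storage mode
  # integer) for integer TIFFs, and native doubles for float TIFFs
  int_like <- all(vapply(planes, is.integer, logical(1)))
  bps <- attr(planes[[1]], "bits.per.sample")
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    storage.mode(p) <- "double"
    attributes(p) <- list(dim = dim(p))
    p
  })
  if (is.null(role)) role <- if (int_like) "raw" else "calibrated"
  if (role == "calibrated") {
    if (int_like) {
      abort("unsupported sample format: integer TIFF cannot be read as calibrated",
            class = "phenoleaf_sample_format")
    }
    multispectral_image(planes, role = "calibrated")
  } else {
    if (!int_like) {
      abort("unsupported sample format: float TIFF cannot be read as raw/white",
            class = "phenoleaf_sample_format")
    }
    bit_depth <- if (!is.null(bps)) as.integer(bps)
      else if (max(unlist(lapply(planes, max))) > 255) 16L else 8L
    if (!bit_depth %in% c(8L, 16L)) {
      abort(sprintf("unsupported sample format: %d bits per sample", bit_depth),
            class = "phenoleaf_sample_format")
    }
    multispectral_image(planes, role = role, bit_depth = bit_depth)
  }
}

#' Write a multispectral image as a multiband TIFF
#'
#' Planes are stored in the canonical order blue, green, red, nir. Raw and
#' white images are written as unsigned integer TIFFs at their own bit depth;
#' calibrated images as 32-bit float TIFFs (values may exceed 1).
#'
#' @param image a [multispectral_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multispectral <- function(image, path) {
  stopifnot(inherits(image, "multispectral_image"))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L) {
    abort(sprintf("unwritable path: %s", path), class = "phenoleaf_unwritable")
  }
  if (image$role == "calibrated") {
    write_float_tiff(image$bands, path)
  } else {
    full <- 2^image$bit_depth - 1
    tiff::writeTIFF(lapply(image$bands, function(b) b / full), path,
                    bits.per.sample = image$bit_depth)
  }
  invisible(path)
}

# Minimal uncompressed multi-page 32-bit-float TIFF writer (little endian).
# tiff::writeTIFF documents storage of float values outside [0,1] as
# undefined, but calibrated reflectance may reach clip_max; reading back
# still goes through tiff::readTIFF, which handles float samples natively.
write_float_tiff <- function(planes, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  w16(42L)
  n <- length(planes)
  h <- nrow(planes[[1]]); w <- ncol(planes[[1]])
  data_bytes <- 4L * h * w
  n_entries <- 9L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  # layout: header(8) | [pixel data][IFD] per page
  offset <- 8L
  w32(offset + data_bytes)           # offset of first IFD
  for (i in seq_len(n)) {
    # row-major pixel data
    writeBin(as.numeric(t(planes[[i]])), con, size = 4, endian = "little")
    ifd_off <- offset + data_bytes
    entry <- function(tag, type, count, value) {
      w16(tag); w16(type); w32(count); w32(value)
    }
    w16(n_entries)
    entry(256L, 3L, 1L, w)                 # ImageWidth
    entry(257L, 3L, 1L, h)                 # ImageLength
    entry(258L, 3L, 1L, 32L)               # BitsPerSample
    entry(259L, 3L, 1L, 1L)                # Compression: none
    entry(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
    entry(273L, 4L, 1L, offset)            # StripOffsets
    entry(278L, 3L, 1L, h)                 # RowsPerStrip
    entry(279L, 4L, 1L, data_bytes)        # StripByteCounts
    entry(339L, 3L, 1L, 3L)                # SampleFormat: IEEE float
    next_ifd <- if (i < n) ifd_off + ifd_bytes + data_bytes else 0L
    w32(next_ifd)
    offset <- ifd_off + ifd_bytes
  }
  invisible(path)
}

#' Read a sample manifest CSV
#'
#' The manifest maps each sample image to its white reference and its
#' experimental labels. Required columns: `sample_id`, `image_path`,
#' `white_path`, `plant_id`, `plot_id`, `treatment`, `leaf_position`
#' (one of `top`, `bottom`, `unknown`).
#'
#' @param path CSV file path.
#' @return a tibble, one row per sample.
#' @export
read_manifest <- function(path) {
  required <- c("sample_id", "image_path", "white_path", "plant_id",
                "plot_id", "treatment", "leaf_position")
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste("manifest missing column(s):", toString(missing)),
          class = "phenoleaf_manifest_column")
  }
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    abort(paste("duplicate sample_id:", toString(dup)),
          class = "phenoleaf_manifest_duplicate")
  }
  bad <- setdiff(unique(df$leaf_position), c("top", "bottom", "unknown"))
  if (length(bad)) {
    abort(paste("leaf_position must be top/bottom/unknown, got:", toString(bad)),
          class = "phenoleaf_manifest_column")
  }
  tibble::as_tibble(df[required])
}
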