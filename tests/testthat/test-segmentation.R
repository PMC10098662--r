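test_that("greenness_map computes green^2 / (red * blue) with validity flags", {
  c05 <- const_image(0.5)
  gm <- greenness_map(c05)
  expect_true(all(gm$values == 1))
  expect_true(all(gm$valid_mask))

  img <- make_image(matrix(0.25, 4, 4), matrix(0.5, 4, 4),
                    matrix(0.25, 4, 4), matrix(0.6, 4, 4))
  expect_true(all(greenness_map(img)$values == 4))

  dark <- const_image(1e-4)
  expect_false(any(greenness_map(dark, epsilon = 0.01)$valid_mask))

  raw <- const_image(10, role = "raw", bit_depth = 8)
  expect_error(greenness_map(raw), class = "phenoleaf_role_mismatch")
})

test_that("fixed thresholding matches the mask definition", {
  v <- matrix(4, 10, 12)
  valid <- matrix(TRUE, 10, 12)
  valid[, 1:3] <- FALSE
  gm <- structure(list(values = v, kind = "greenness", valid_mask = valid),
                  class = "index_map")
  m <- threshold_leaf(gm, method = "fixed", threshold = 1.5)
  expect_identical(unclass(m)[, ], valid)

  high <- threshold_leaf(gm, method = "fixed", threshold = 10)
  expect_false(any(high))
  expect_true(attr(high, "empty"))
})

test_that("otsu threshold agrees with an exhaustive between-class variance oracle", {
  withr::with_seed(31, {
    vals <- c(rnorm(600, 1, 0.1), rnorm(400, 4, 0.1))
  })
  v <- matrix(vals, 25, 40)
  truth <- matrix(rep(c(FALSE, TRUE), c(600, 400)), 25, 40)
  gm <- structure(list(values = v, kind = "greenness",
                       valid_mask = matrix(TRUE, 25, 40)),
                  class = "index_map")
  m <- threshold_leaf(gm, method = "otsu")
  th <- attr(m, "threshold")
  expect_gt(th, 1.3)
  expect_lt(th, 3.7)
  expect_gte(mask_iou(m, truth), 0.99)

  # oracle: brute-force search over candidate cuts maximising between-class
  # variance; the maximiser is a plateau between the clusters, so compare
  # the variance achieved, not the cut position
  x <- as.vector(v)
  bcv <- function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) return(-Inf)
    length(lo) * length(hi) / length(x)^2 * (mean(lo) - mean(hi))^2
  }
  cuts <- seq(min(x), max(x), length.out = 258)[2:257]
  best <- max(vapply(cuts, bcv, numeric(1)))
  expect_gte(bcv(th), best * (1 - 1e-6))
})

test_that("refine_mask equals a brute-force dilate-then-erode oracle", {
  m <- matrix(FALSE, 20, 24)
  m[5:15, 5:19] <- TRUE
  # carve a 1-px diagonal gap
  for (i in 0:10) m[5 + i, 11] <- FALSE
  brush <- EBImage::makeBrush(5, "disc") > 0
  off <- which(brush, arr.ind = TRUE) - 3L
  maxmin_filter <- function(x, take_max) {
    out <- matrix(!take_max, nrow(x), ncol(x))
    for (r in seq_len(nrow(x))) for (c in seq_len(ncol(x))) {
      rr <- r + off[, 1]; cc <- c + off[, 2]
      keep <- rr >= 1 & rr <= nrow(x) & cc >= 1 & cc <= ncol(x)
      vals <- x[cbind(rr[keep], cc[keep])]
      out[r, c] <- if (take_max) any(vals) else all(vals)
    }
    out
  }
  oracle <- maxmin_filter(maxmin_filter(m, TRUE), FALSE)
  got <- refine_mask(m, radius = 2, min_area = 10)
  expect_identical(unclass(got)[, ], oracle)
  expect_false(any(got & !oracle))
  # gap is bridged
  expect_true(all(got[6:14, 11]))
})

test_that("refine_mask keeps the largest component and enforces min_area", {
  m <- matrix(FALSE, 30, 30)
  m[5:20, 5:20] <- TRUE
  m[27, 27:29] <- TRUE   # isolated 3-px speck
  out <- refine_mask(m, radius = 2, min_area = 100)
  expect_false(any(out[25:30, 25:30]))
  expect_equal(max(EBImage::bwlabel(matrix(as.integer(out), 30))), 1)
  # closing is idempotent on a solid rectangle
  solid <- matrix(FALSE, 20, 20); solid[4:16, 4:16] <- TRUE
  expect_identical(unclass(refine_mask(solid, radius = 2, min_area = 5))[, ],
                   solid)
  expect_error(refine_mask(m * matrix(FALSE, 30, 30), radius = 2),
               class = "phenoleaf_no_leaf")
  expect_error(refine_mask(m, radius = 2, min_area = 1e5),
               class = "phenoleaf_no_leaf")
})

test_that("refined output stays inside the dilation of the input", {
  for (s in 1:5) {
    withr::with_seed(s, {
      m <- matrix(runif(40 * 40) > 0.6, 40, 40)
    })
    m[15:25, 15:25] <- TRUE
    out <- refine_mask(m, radius = 2, min_area = 10)
    dil <- EBImage::dilate(matrix(as.integer(m), 40),
                           EBImage::makeBrush(5, "disc")) > 0
    expect_false(any(out & !dil))
    expect_equal(max(EBImage::bwlabel(matrix(as.integer(out), 40))), 1)
  }
})

test_that("segmentation recovers synthetic leaf masks accurately", {
  for (s in 1:5) {
    sc <- render_scene(quick_scene_params(seed = s))
    cal <- flat_field(sc$raw, sc$white)
    leaf <- refine_mask(threshold_leaf(greenness_map(cal)))
    expect_gte(mask_iou(leaf, sc$truth$leaf_mask), 0.95)
  }
})
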