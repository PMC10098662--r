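test_that("patch priority: confidence and data term behave as defined", {
  # constant image: no isophotes anywhere -> priority 0
  img <- matrix(0.5, 15, 15)
  target <- matrix(FALSE, 15, 15)
  target[, 9:15] <- TRUE
  st <- fill_state(target)
  expect_equal(patch_priority(st, img, c(8, 9)), 0)
  expect_error(patch_priority(st, img, c(8, 3)),
               class = "phenoleaf_not_on_front")

  # vertical unit step crossing a horizontal front orthogonally: D = 1/alpha
  step <- matrix(0, 15, 15)
  step[, 8:15] <- 1
  tgt <- matrix(FALSE, 15, 15)
  tgt[9:15, ] <- TRUE
  st2 <- fill_state(tgt)
  p <- c(9, 8)
  pr <- patch_priority(st2, step, p)
  C_expected <- 36 / 81   # rows 5..8 of the 9x9 patch are filled
  expect_equal(pr, C_expected * 1, tolerance = 1e-12)
  # alpha rescales the data term
  pr2 <- patch_priority(st2, step, p, inpaint_params(alpha = 2))
  expect_equal(pr2, C_expected / 2, tolerance = 1e-12)

  # equal data term, more filled neighbours -> higher priority
  tgt3 <- tgt
  tgt3[9, 4:6] <- FALSE   # extra filled notch inside the patch
  st3 <- fill_state(tgt3)
  pr3 <- patch_priority(st3, step, p)
  expect_equal(pr3, (39 / 81) * 1, tolerance = 1e-12)
  expect_gt(pr3, pr)
})

test_that("best_source_patch finds exact duplicates and breaks ties row-major", {
  h <- 20; w <- 20
  bands <- lapply(1:4, function(i) matrix(0.5, h, w))
  names(bands) <- c("blue", "green", "red", "nir")
  # plant an identical distinctive patch at two locations
  pat <- matrix(seq_len(25) / 25, 5, 5)
  for (b in seq_along(bands)) {
    bands[[b]][3:7, 3:7] <- pat * b / 4
    bands[[b]][12:16, 11:15] <- pat * b / 4
    bands[[b]][9:13, 3:7] <- pat * b / 4  # target area holds the same patch
  }
  img <- multispectral_image(bands, role = "calibrated")
  target <- matrix(FALSE, h, w)
  target[11, 5] <- TRUE   # one unknown pixel in the middle of the third copy
  st <- fill_state(target)
  params <- inpaint_params(patch_size = 5, search_mask = !target)
  res <- best_source_patch(img, c(11, 5), st, params)
  expect_equal(res$ssd, 0)
  # duplicates at centres (5,5), (14,13) and the target's own neighbourhood
  # share SSD 0; smallest row-major index wins
  expect_equal(res$center, c(5, 5))

  # no admissible patch -> named failure
  none <- inpaint_params(patch_size = 5, search_mask = matrix(FALSE, h, w))
  expect_error(best_source_patch(img, c(11, 5), st, none),
               class = "phenoleaf_no_source")
})

test_that("best_source_patch equals an exhaustive SSD oracle on random images", {
  for (s in 1:3) {
    img <- random_image(32, 32, seed = 100 + s)
    withr::with_seed(200 + s, {
      target <- matrix(FALSE, 32, 32)
      tr <- sample(10:22, 1); tc <- sample(10:22, 1)
      target[tr + (-2:2), tc + (-2:2)] <- matrix(runif(25) < 0.5, 5, 5)
    })
    target[tr, tc] <- TRUE
    st <- fill_state(target)
    params <- inpaint_params(patch_size = 5, search_mask = !target)
    res <- best_source_patch(img, c(tr, tc), st, params)

    # oracle: scan every centre whose 5x5 patch avoids the target entirely
    half <- 2
    filled <- !target
    best <- Inf; best_ctr <- NULL
    for (r in 3:30) for (c in 3:30) {
      if (any(target[r + (-2:2), c + (-2:2)])) next
      ssd <- 0
      for (b in c("blue", "green", "red", "nir")) {
        tb <- band(img, b)[tr + (-2:2), tc + (-2:2)]
        sb <- band(img, b)[r + (-2:2), c + (-2:2)]
        fb <- filled[tr + (-2:2), tc + (-2:2)]
        ssd <- ssd + sum(((tb - sb)[fb])^2)
      }
      if (ssd < best) { best <- ssd; best_ctr <- c(r, c) }
    }
    expect_equal(res$ssd, best, tolerance = 1e-12)
    expect_equal(res$center, best_ctr)
  }
})

test_that("inpainting a constant leaf is exact and empty targets are identity", {
  img <- const_image(0.42, h = 24, w = 24)
  leaf <- matrix(TRUE, 24, 24)
  target <- matrix(FALSE, 24, 24)
  target[10:14, ] <- TRUE
  out <- inpaint_exemplar(img, target, leaf)
  expect_true(all(band(out, "nir") == 0.42))
  expect_true(all(band(out, "red") == 0.42))

  none <- inpaint_exemplar(img, matrix(FALSE, 24, 24), leaf)
  expect_identical(none$bands, img$bands)
})

test_that("periodic stripe texture is reconstructed through a diagonal hole", {
  n <- 32
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  stripe <- 0.4 + 0.4 * ((cc %% 8) < 4)   # square wave, amplitude 0.4
  bands <- list(blue = stripe * 0.5, green = stripe, red = stripe * 0.8,
                nir = stripe * 1.2)
  img <- multispectral_image(bands, role = "calibrated")
  rr <- matrix(seq_len(n), n, n)
  hole <- abs(rr - cc) <= 3   # 6-7 px wide diagonal band
  leaf <- matrix(TRUE, n, n)
  out <- inpaint_exemplar(img, hole, leaf)
  for (b in c("green", "nir")) {
    mae <- mean(abs(band(out, b)[hole] - bands[[b]][hole]))
    amplitude <- diff(range(bands[[b]]))
    expect_lte(mae, 0.05 * amplitude)
  }
  # untouched pixels are bit-identical
  expect_identical(band(out, "red")[!hole], bands$red[!hole])
})

test_that("filled values are copies from intact source tissue", {
  img <- random_image(28, 28, seed = 300)
  leaf <- matrix(FALSE, 28, 28)
  leaf[3:26, 3:26] <- TRUE
  target <- matrix(FALSE, 28, 28)
  target[13:15, ] <- TRUE
  out <- inpaint_exemplar(img, target, leaf)
  source_px <- which(leaf & !target)
  src_vals <- sapply(c("blue", "green", "red", "nir"),
                     function(b) band(img, b)[source_px])
  zone <- target & (EBImage::dilate(matrix(as.integer(leaf), 28),
                                    EBImage::makeBrush(9, "disc")) > 0)
  filled_px <- which(zone)
  fill_vals <- sapply(c("blue", "green", "red", "nir"),
                      function(b) band(out, b)[filled_px])
  for (i in seq_along(filled_px)) {
    hit <- colSums(abs(t(src_vals) - fill_vals[i, ])) == 0
    expect_true(any(hit))
  }
  # thread pixels far outside the leaf are blanked to background
  far <- target & !zone
  if (any(far)) expect_true(all(band(out, "nir")[far] == 0))
})

test_that("the fill front shrinks monotonically until completion", {
  sc <- render_scene(quick_scene_params(seed = 13, thread_spacing = 40))
  cal <- flat_field(sc$raw, sc$white)
  leaf <- refine_mask(threshold_leaf(greenness_map(cal)))
  tm <- thread_mask(cal, leaf)
  out <- inpaint_exemplar(cal, tm, leaf)
  hist <- attr(out, "remaining_history")
  expect_true(all(diff(hist) < 0))
  expect_identical(hist[length(hist)], 0L)
  expect_lte(attr(out, "iterations"), sum(tm))
})

test_that("gradient and tensor data terms agree on a straight edge", {
  n <- 21
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  step <- (cc >= 11) * 1.0
  bands <- list(blue = step, green = step, red = step, nir = step)
  img <- multispectral_image(bands, role = "calibrated")
  target <- matrix(FALSE, n, n)
  target[9:13, 6:16] <- TRUE
  leaf <- matrix(TRUE, n, n)
  g <- inpaint_exemplar(img, target, leaf,
                        inpaint_params(patch_size = 5, data_term = "gradient"))
  t <- inpaint_exemplar(img, target, leaf,
                        inpaint_params(patch_size = 5, data_term = "tensor"))
  # both variants restore the straight edge through the hole
  expect_lt(mean(abs(band(g, "nir") - step)), 0.02)
  expect_lt(mean(abs(band(t, "nir") - step)), 0.02)
})
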