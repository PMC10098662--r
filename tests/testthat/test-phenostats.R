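test_that("ndvi_map matches the band ratio and handles limits", {
  img <- make_image(matrix(0.1, 4, 4), matrix(0.2, 4, 4),
                    matrix(0.2, 4, 4), matrix(0.8, 4, 4))
  leaf <- matrix(TRUE, 4, 4)
  nd <- ndvi_map(img, leaf)
  expect_true(all(abs(nd$values - 0.6) < 1e-12))
  expect_true(all(nd$valid_mask))

  eq <- make_image(matrix(0.1, 4, 4), matrix(0.2, 4, 4),
                   matrix(0.3, 4, 4), matrix(0.3, 4, 4))
  expect_true(all(ndvi_map(eq, leaf)$values == 0))

  red0 <- make_image(matrix(0.1, 4, 4), matrix(0.2, 4, 4),
                     matrix(0, 4, 4), matrix(0.5, 4, 4))
  expect_true(all(ndvi_map(red0, leaf)$values == 1))

  expect_error(ndvi_map(img, matrix(FALSE, 4, 4)), class = "phenoleaf_no_leaf")
  raw <- const_image(3, role = "raw", bit_depth = 8)
  expect_error(ndvi_map(raw, leaf), class = "phenoleaf_role_mismatch")
})

test_that("mean_index averages valid pixels only, order-invariantly", {
  v <- matrix(c(0.2, 0.6, 0.9, 0), 2, 2)
  valid <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  m <- structure(list(values = v, kind = "ndvi", valid_mask = valid),
                 class = "index_map")
  expect_equal(mean_index(m), 0.4)
  # permuting the pixels leaves the mean unchanged
  perm <- structure(list(values = v[2:1, ], kind = "ndvi",
                         valid_mask = valid[2:1, ]), class = "index_map")
  expect_equal(mean_index(perm), 0.4)
  empty <- structure(list(values = v, kind = "ndvi",
                          valid_mask = valid & FALSE), class = "index_map")
  expect_error(mean_index(empty), class = "phenoleaf_empty_region")
})

test_that("aggregation averages leaves per plant and per plot", {
  recs <- tibble::tibble(
    sample_id = letters[1:8],
    mean_ndvi = c(0.5, 0.6, 0.7, 0.8, 0.4, 0.6, 0.3, 0.5),
    plant_id = c("p1", "p1", "p2", "p2", "p3", "p3", "p4", "p4"),
    plot_id = c(rep("A", 4), rep("B", 4)),
    treatment = c(rep("high", 4), rep("low", 4)))
  plot_level <- aggregate_ndvi(recs, by = "plot")
  expect_equal(plot_level$mean_ndvi[plot_level$plot_id == "A"], 0.65)
  expect_equal(plot_level$n, c(4L, 4L))

  plant_level <- aggregate_ndvi(recs, by = "plant")
  expect_equal(plant_level$mean_ndvi[plant_level$plant_id == "p1"], 0.55)
  expect_equal(nrow(plant_level), 4)

  # record order does not matter
  shuffled <- recs[c(5, 2, 8, 1, 7, 3, 6, 4), ]
  expect_equal(dplyr::arrange(aggregate_ndvi(shuffled, "plot"), plot_id),
               dplyr::arrange(plot_level, plot_id))

  recs$plot_id[1] <- NA
  expect_error(aggregate_ndvi(recs, by = "plot"), regexp = "plot_id")
})

test_that("two-sample t-test matches closed-form pooled arithmetic", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  tt <- two_sample_ttest(a, b, variant = "student")
  # oracle: pooled-variance arithmetic plus the reference t CDF
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 6)
  expect_equal(tt$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(tt$statistic, -2.1909, tolerance = 1e-4)
  expect_equal(tt$df, 6)
  expect_equal(tt$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(tt$p_value, 0.0710, tolerance = 1e-3)
  expect_equal(tt$estimate, -2)

  td <- tidy(tt)
  expect_equal(td$statistic, t_oracle)
  expect_equal(glance(tt)$n1, 4)
})

test_that("t-test conventions for identical and degenerate samples", {
  x <- c(1, 2, 3)
  same <- two_sample_ttest(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  flat_eq <- two_sample_ttest(c(2, 2), c(2, 2))
  expect_equal(flat_eq$p_value, 1)
  expect_true(flat_eq$degenerate)
  flat_ne <- two_sample_ttest(c(2, 2), c(3, 3))
  expect_equal(flat_ne$p_value, 0)
  expect_true(flat_ne$degenerate)
})

test_that("t statistic and p are invariant to a common location shift", {
  withr::with_seed(51, {
    a <- rnorm(8, 0.6, 0.05)
    b <- rnorm(8, 0.7, 0.05)
  })
  t1 <- two_sample_ttest(a, b)
  t2 <- two_sample_ttest(a + 3, b + 3)
  expect_equal(t1$statistic, t2$statistic, tolerance = 1e-10)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-10)
  tw <- two_sample_ttest(a, b, variant = "welch")
  expect_lt(abs(tw$df - 14), 14)  # Welch df between min(n)-1 and n1+n2-2
})

test_that("OLS matches the hand-solved normal equations", {
  fit <- ols_fit(c(0, 1, 2), c(0, 1, 1))
  expect_equal(fit$estimate, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 1 / 6, tolerance = 1e-12)
  expect_equal(fit$r_squared, 0.75, tolerance = 1e-12)

  exact <- ols_fit(0:5, 2 * (0:5) + 1)
  expect_equal(exact$estimate, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)

  flat <- ols_fit(0:4, rep(3, 5))
  expect_equal(flat$estimate, 0)
  expect_equal(flat$r_squared, 0)

  expect_error(ols_fit(rep(1, 4), 1:4), class = "phenoleaf_constant_x")
  expect_equal(glance(exact)$r.squared, 1)
  expect_equal(tidy(exact)$estimate, c(1, 2))
})
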