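#' NDVI map of a calibrated leaf image
#'
#' `NDVI = (NIR - Red) / (NIR + Red)` per pixel, restricted to the leaf
#' mask. The denominator is floored at `epsilon`; pixels below the floor
#' are flagged invalid. Values are clamped to `[-1, 1]`.
#'
#' @param cal calibrated [multispectral_image()].
#' @param leaf logical leaf mask.
#' @param epsilon denominator floor on reflectance scale (default 1e-6).
#' @return an `index_map` of kind `ndvi`.
#' @export
ndvi_map <- function(cal, leaf, epsilon = 1e-6) {
  stopifnot(inherits(cal, "multispectral_image"), is.matrix(leaf))
  if (cal$role != "calibrated") {
    abort("ndvi_map expects a calibrated image",
          class = "phenoleaf_role_mismatch")
  }
  if (!any(leaf)) abort("leaf mask empty", class = "phenoleaf_no_leaf")
  s <- cal$bands$nir + cal$bands$red
  valid <- leaf & (s >= epsilon)
  values <- pmin(pmax((cal$bands$nir - cal$bands$red) / pmax(s, epsilon),
                      -1), 1)
  index_map(values, "ndvi", valid)
}

#' Mean of an index map over its valid pixels
#' @param map an `index_map`.
#' @return scalar mean.
#' @export
mean_index <- function(map) {
  stopifnot(inherits(map, "index_map"))
  v <- map$values[map$valid_mask]
  if (!length(v)) abort("no valid pixels", class = "phenoleaf_empty_region")
  mean(v)
}

#' Aggregate per-leaf records to plant or plot level
#'
#' Unweighted mean of `mean_ndvi` per grouping key, mirroring the
#' experimental workflow: per plant, top and bottom leaves are averaged; per
#' plot, the four imaged leaves are averaged to represent the plot.
#'
#' @param records tibble with at least `mean_ndvi` and the grouping key
#'   (`plant_id` or `plot_id`); a `treatment` column, if present, is carried
#'   through (assumed constant within key).
#' @param by `"plant"` or `"plot"`.
#' @return tibble with the key, `mean_ndvi`, `n`, and `treatment` if
#'   available.
#' @export
aggregate_ndvi <- function(records, by = c("plant", "plot")) {
  by <- match.arg(by)
  key <- paste0(by, "_id")
  if (!nrow(records)) abort("no records to aggregate")
  if (!key %in% names(records) || anyNA(records[[key]])) {
    abort(sprintf("missing grouping key '%s' on some record", key))
  }
  out <- records |>
    dplyr::group_by(.data[[key]]) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of("treatment"), dplyr::first),
      mean_ndvi = mean(.data$mean_ndvi),
      n = dplyr::n(),
      .groups = "drop"
    )
  out
}

#' Two-sample t-test on group means
#'
#' Student's pooled-variance test by default (the conventional reading of a
#' plain "two-sample t-test"); Welch's unequal-variance test is available
#' for robustness. Degenerate inputs follow fixed conventions: zero
#' variance in both samples gives `p = 1` when the means are equal and
#' `p = 0` (flagged) when they differ.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant `"student"` (default) or `"welch"`.
#' @return a `leaf_ttest` object (see [tidy()], [glance()]): statistic,
#'   `df`, two-sided `p_value`, `estimate` (`mean(a) - mean(b)`),
#'   `n_per_group`, `degenerate` flag.
#' @examples
#' two_sample_ttest(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
two_sample_ttest <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2, length(b) >= 2)
  estimate <- mean(a) - mean(b)
  degenerate <- FALSE
  if (var(a) == 0 && var(b) == 0) {
    degenerate <- TRUE
    statistic <- if (estimate == 0) 0 else sign(estimate) * Inf
    p_value <- if (estimate == 0) 1 else 0
    df <- if (variant == "student") length(a) + length(b) - 2 else NA_real_
  } else {
    ht <- stats::t.test(a, b, var.equal = variant == "student")
    statistic <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p_value <- ht$p.value
  }
  structure(list(kind = "ttest", variant = variant, statistic = statistic,
                 p_value = p_value, df = df, estimate = estimate,
                 n_per_group = c(length(a), length(b)),
                 degenerate = degenerate,
                 data = list(a = a, b = b)),
            class = "leaf_ttest")
}

#' @export
print.leaf_ttest <- function(x, ...) {
  cat(sprintf(
    "Two-sample t-test (%s): t = %.4f, df = %s, p = %.4g, diff = %.4f%s\n",
    x$variant, x$statistic, format(x$df), x$p_value, x$estimate,
    if (x$degenerate) " [degenerate input]" else ""))
  invisible(x)
}

#' @rdname two_sample_ttest
#' @param x a `leaf_ttest` object.
#' @param ... unused.
#' @export
tidy.leaf_ttest <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, statistic = x$statistic,
                 p.value = x$p_value, df = x$df,
                 method = paste0("two-sample t-test (", x$variant, ")"))
}

#' @rdname two_sample_ttest
#' @export
glance.leaf_ttest <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value, df = x$df,
                 n1 = x$n_per_group[1], n2 = x$n_per_group[2],
                 degenerate = x$degenerate)
}

#' Ordinary least squares fit of an index against a reference measurement
#'
#' Simple linear regression (e.g. whole-plant mean NDVI against
#' laboratory-measured nitrogen content), reporting slope, intercept and
#' `R^2 = 1 - SSres / SStot`.
#'
#' @param x,y numeric vectors of equal length >= 3; `x` must not be
#'   constant.
#' @return a `leaf_ols` object (see [tidy()], [glance()]).
#' @examples
#' ols_fit(0:3, 2 * (0:3) + 1)
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0) abort("constant x: slope undefined",
                         class = "phenoleaf_constant_x")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  cf <- suppressWarnings(summary(fit))$coefficients  # perfect fits warn
  structure(list(kind = "ols",
                 estimate = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 statistic = if (nrow(cf) > 1) cf[2, "t value"] else NA_real_,
                 p_value = if (nrow(cf) > 1) cf[2, "Pr(>|t|)"] else NA_real_,
                 df = unname(fit$df.residual),
                 r_squared = r2, n = length(x), fit = fit),
            class = "leaf_ols")
}

#' @export
print.leaf_ols <- function(x, ...) {
  cat(sprintf("OLS fit: slope = %.4f, intercept = %.4f, R^2 = %.4f (n = %d)\n",
              x$estimate, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @rdname ols_fit
#' @param x a `leaf_ols` object (for methods).
#' @param ... unused.
#' @export
tidy.leaf_ols <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = c(x$intercept, x$estimate))
}

#' @rdname ols_fit
#' @export
glance.leaf_ols <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, statistic = x$statistic,
                 p.value = x$p_value, df.residual = x$df, nobs = x$n)
}
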