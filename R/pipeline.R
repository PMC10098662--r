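default_config <- function() {
  list(
    calibration = list(epsilon = 1, clip_max = 2),
    segmentation = list(method = "otsu", threshold = 1.5, radius = 2,
                        min_area = NULL, greenness_epsilon = 0.01),
    gabor = list(wavelength = 5, aspect_ratio = 0.1, bandwidth_octaves = 1,
                 phase_offset = 0, dc_correct = TRUE),
    threads = list(orientations = c(45, 135), rel_threshold = 0.25,
                   dilate_radius = 1, band = "nir"),
    inpaint = list(patch_size = 9, data_term = "gradient", alpha = 1),
    stats = list(variant = "student", level = "plot"),
    simulate = list(),
    seed = 1L,
    keep_intermediates = FALSE,
    log_level = "info"
  )
}

#' Pipeline configuration
#'
#' Builds the effective configuration by merging user settings into the
#' package defaults. Unknown keys (top level or within a module block) are
#' rejected rather than silently ignored. The `simulate` block holds
#' [scene_params()] overrides for the `simulate` workflow.
#'
#' @param ... named top-level settings or module blocks (named lists), e.g.
#'   `segmentation = list(method = "fixed", threshold = 1.5)`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    abort(paste("unknown config key(s):", toString(unknown)),
          class = "phenoleaf_config_key")
  }
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && k != "simulate") {
      bad <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(bad)) {
        abort(paste0("unknown config key(s) in '", k, "': ", toString(bad)),
              class = "phenoleaf_config_key")
      }
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return for `read_config`, a validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw %||% list())
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Process one leaf image through the five imaging stages
#'
#' Calibrate, segment, detect threads, inpaint, and extract whole-leaf
#' NDVI, in the fixed acquisition-pipeline order. This is the in-memory
#' core behind [run_sample()].
#'
#' @param raw,white raw and white-reference [multispectral_image()]s.
#' @param config a [pipeline_config()].
#' @return list: `mean_ndvi`, `leaf_area_px`, `thread_coverage`,
#'   `threshold` (segmentation threshold used), and the intermediate
#'   objects `cal`, `inpainted`, `leaf_mask`, `thread_mask`, `ndvi`.
#' @export
process_leaf <- function(raw, white, config = pipeline_config()) {
  stage <- "calibration"
  result <- tryCatch({
    cal <- flat_field(raw, white, epsilon = config$calibration$epsilon,
                      clip_max = config$calibration$clip_max)
    stage <- "segmentation"
    gm <- greenness_map(cal, epsilon = config$segmentation$greenness_epsilon)
    leaf <- threshold_leaf(gm, method = config$segmentation$method,
                           threshold = config$segmentation$threshold)
    thr_used <- attr(leaf, "threshold")
    leaf <- refine_mask(leaf, radius = config$segmentation$radius,
                        min_area = config$segmentation$min_area)
    stage <- "threads"
    gp <- gabor_params(wavelength = config$gabor$wavelength,
                       aspect_ratio = config$gabor$aspect_ratio,
                       bandwidth_octaves = config$gabor$bandwidth_octaves,
                       phase_offset = config$gabor$phase_offset,
                       dc_correct = config$gabor$dc_correct)
    tm <- thread_mask(cal, leaf, orientations = config$threads$orientations,
                      params = gp, rel_threshold = config$threads$rel_threshold,
                      dilate_radius = config$threads$dilate_radius,
                      band = config$threads$band)
    stage <- "inpaint"
    ip <- inpaint_params(patch_size = config$inpaint$patch_size,
                         data_term = config$inpaint$data_term,
                         alpha = config$inpaint$alpha)
    filled <- inpaint_exemplar(cal, tm, leaf, ip)
    stage <- "ndvi"
    nd <- ndvi_map(filled, leaf)
    list(mean_ndvi = mean_index(nd), leaf_area_px = sum(leaf),
         thread_coverage = attr(tm, "coverage"), threshold = thr_used,
         cal = cal, inpainted = filled, leaf_mask = leaf, thread_mask = tm,
         ndvi = nd)
  }, error = function(e) {
    abort(paste0("stage '", stage, "': ", conditionMessage(e)),
          class = "phenoleaf_stage_error", stage = stage, parent = e)
  })
  result
}

#' Run the pipeline for one manifest row
#'
#' @param row one-row tibble (or list) with `sample_id`, `image_path`,
#'   `white_path` and the experimental labels.
#' @param config a [pipeline_config()].
#' @param out_dir if non-`NULL` and `config$keep_intermediates` is `TRUE`,
#'   intermediate rasters are written there as
#'   `<sample_id>.<stage>.tiff`.
#' @return one-row tibble: `sample_id`, `mean_ndvi`, `leaf_area_px`,
#'   `thread_coverage`, `treatment`, `plot_id`, `plant_id`,
#'   `leaf_position`.
#' @export
run_sample <- function(row, config = pipeline_config(), out_dir = NULL) {
  raw <- read_multispectral(row$image_path, role = "raw")
  white <- read_multispectral(row$white_path, role = "white")
  res <- process_leaf(raw, white, config)
  if (isTRUE(config$keep_intermediates) && !is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_multispectral(res$cal, file.path(out_dir, paste0(row$sample_id, ".cal.tiff")))
    write_multispectral(res$inpainted, file.path(out_dir, paste0(row$sample_id, ".inpainted.tiff")))
    tiff::writeTIFF(res$leaf_mask * 1, file.path(out_dir, paste0(row$sample_id, ".leafmask.tiff")), bits.per.sample = 8)
    tiff::writeTIFF(res$thread_mask * 1, file.path(out_dir, paste0(row$sample_id, ".threadmask.tiff")), bits.per.sample = 8)
  }
  tibble::tibble(sample_id = row$sample_id, mean_ndvi = res$mean_ndvi,
                 leaf_area_px = res$leaf_area_px,
                 thread_coverage = res$thread_coverage,
                 treatment = row$treatment %||% NA_character_,
                 plot_id = row$plot_id %||% NA_character_,
                 plant_id = row$plant_id %||% NA_character_,
                 leaf_position = row$leaf_position %||% "unknown")
}

#' Run the full pipeline over a manifest
#'
#' Processes every sample (continuing past per-sample failures), then runs
#' the treatment-separation statistics at the configured aggregation level
#' (`"leaf"`, `"plant"` or `"plot"`). With fewer than two treatments, or
#' fewer than two units per group, the statistics are skipped with a
#' warning.
#'
#' @param manifest manifest CSV path or tibble (see [read_manifest()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, `records.csv`,
#'   `stats.csv` and the effective `config.yaml` are written there.
#' @return list: `records` tibble, `stats` tibble (zero rows if skipped),
#'   `errors` tibble (`sample_id`, `stage`, `message`).
#' @export
run_experiment <- function(manifest, config = pipeline_config(),
                           out_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  rows <- split(manifest, seq_len(nrow(manifest)))
  records <- list(); errors <- list()
  for (row in rows) {
    rec <- tryCatch(run_sample(row, config, out_dir), error = function(e) e)
    if (inherits(rec, "error")) {
      errors[[length(errors) + 1L]] <- tibble::tibble(
        sample_id = row$sample_id,
        stage = rec$stage %||% "unknown",
        message = conditionMessage(rec))
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  records <- dplyr::bind_rows(records)
  errors <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(sample_id = character(), stage = character(),
                   message = character())
  stats_tbl <- experiment_stats(records, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(records, file.path(out_dir, "records.csv"))
    readr::write_csv(stats_tbl, file.path(out_dir, "stats.csv"))
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  list(records = records, stats = stats_tbl, errors = errors)
}

experiment_stats <- function(records, config) {
  empty <- tibble::tibble(kind = character(), level = character(),
                          group_a = character(), group_b = character(),
                          statistic = double(), df = double(),
                          p_value = double(), estimate = double(),
                          n_a = integer(), n_b = integer())
  if (!nrow(records) || !"treatment" %in% names(records)) return(empty)
  level <- config$stats$level
  unit <- switch(level,
                 leaf = records,
                 plant = aggregate_ndvi(records, "plant"),
                 plot = aggregate_ndvi(records, "plot"),
                 abort("stats level must be leaf, plant or plot"))
  groups <- unique(unit$treatment)
  groups <- groups[!is.na(groups)]
  if (length(groups) < 2) {
    warning("fewer than two treatment groups: statistics skipped")
    return(empty)
  }
  pairs <- utils::combn(sort(groups), 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    a <- unit$mean_ndvi[unit$treatment == pr[1]]
    b <- unit$mean_ndvi[unit$treatment == pr[2]]
    if (length(a) < 2 || length(b) < 2) {
      warning(sprintf("fewer than 2 samples per group (%s vs %s): skipped",
                      pr[1], pr[2]))
      return(NULL)
    }
    tt <- two_sample_ttest(a, b, variant = config$stats$variant)
    tibble::tibble(kind = "ttest", level = level, group_a = pr[1],
                   group_b = pr[2], statistic = tt$statistic, df = tt$df,
                   p_value = tt$p_value, estimate = tt$estimate,
                   n_a = length(a), n_b = length(b))
  })
  dplyr::bind_rows(c(list(empty), out))
}
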