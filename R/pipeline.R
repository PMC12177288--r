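# End-to-end orchestration: one slice through the full measurement chain,
# and batches of slices into group comparisons.

#' Pipeline run configuration
#'
#' Collects every supervised choice of the analysis into one recorded
#' parameter set: input source (an image file or a generator preset),
#' geometry source, threshold method, vessel filters, radial step,
#' enlargement radii and exclusion cutoff. Input sources are mutually
#' exclusive.
#'
#' @param image_path path to a TIFF/PNG cross-section (exclusive with
#'   `preset`).
#' @param preset generator preset name (exclusive with `image_path`).
#' @param seed generator seed (synthetic input only).
#' @param group group label override.
#' @param geometry `"auto"` or a list with `pith_polygon`/`outer_polygon`
#'   matrices (or a path to a polygons JSON with elements `pith`, `outer`).
#' @param threshold_method `"otsu"` or `"fixed"`; `threshold_value` for fixed.
#' @param min_area_px,max_area_px,min_circularity,max_circularity vessel
#'   particle filters (see [detect_vessels()]).
#' @param exclude_ids,include_polygons manual edits (see
#'   [apply_manual_edits()]).
#' @param min_speck_px fiber-mask speck removal (default 0: retain noise).
#' @param step_px radial increment (default 10).
#' @param x_list neighbourhood enlargement radii (default 10, 15, 20, 25).
#' @param min_intersect_px YES-vessel cutoff (default 1 px).
#' @param fiber_exclusion_pct radial fiber-profile exclusion cutoff
#'   (default 0.5% of xylem area).
#' @param out_dir if non-NULL, all result tables, masks and a JSON summary
#'   are written there.
#' @return an object of class `run_config`.
#' @export
run_config <- function(image_path = NULL, preset = NULL, seed = 1L,
                       group = NULL,
                       geometry = "auto",
                       threshold_method = "otsu", threshold_value = NULL,
                       min_area_px = 200, max_area_px = Inf,
                       min_circularity = 0.3, max_circularity = 1.2,
                       exclude_ids = integer(0), include_polygons = list(),
                       min_speck_px = 0L,
                       step_px = 10L, x_list = c(10, 15, 20, 25),
                       min_intersect_px = 1,
                       fiber_exclusion_pct = 0.5,
                       out_dir = NULL) {
  st <- "run_config"
  assert_that(xor(is.null(image_path), is.null(preset)), st,
              "exactly one of image_path or preset must be given")
  assert_that(step_px >= 1, st, "step_px must be >= 1")
  assert_that(length(x_list) > 0 && all(x_list >= 0), st,
              "x_list must be non-empty and non-negative")
  assert_that(fiber_exclusion_pct >= 0, st,
              "fiber_exclusion_pct must be non-negative")
  structure(list(
    image_path = image_path, preset = preset, seed = as.integer(seed),
    group = group, geometry = geometry,
    threshold_method = threshold_method, threshold_value = threshold_value,
    min_area_px = min_area_px, max_area_px = max_area_px,
    min_circularity = min_circularity, max_circularity = max_circularity,
    exclude_ids = exclude_ids, include_polygons = include_polygons,
    min_speck_px = min_speck_px,
    step_px = as.integer(step_px), x_list = x_list,
    min_intersect_px = min_intersect_px,
    fiber_exclusion_pct = fiber_exclusion_pct,
    out_dir = out_dir
  ), class = "run_config")
}

#' Run the full measurement chain on one slice
#'
#' Executes segmentation, percent-area metrics, radial profiles with the
#' 95% threshold, and the vessel-fiber neighbourhood association on one
#' cross-section (read from file or generated synthetically), logging every
#' stage parameter. Deterministic given the configuration.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage messages.
#' @return object of class `slice_result`: `metrics` (one-row data frame),
#'   `radial` (vessel and fiber `radial_profile`s plus their thresholds),
#'   `association` (records and summaries), the intermediate masks and, for
#'   synthetic input, the generator `truth`.
#' @export
run_slice <- function(config, quiet = TRUE) {
  st <- "run_slice"
  say <- function(...) if (!quiet) message("[run_slice] ", ...)
  truth <- NULL
  if (!is.null(config$preset)) {
    scfg <- synth_preset(config$preset, seed = config$seed)
    gen <- generate_cross_section(scfg)
    image <- gen$section
    truth <- gen$truth
    say("generated preset '", config$preset, "' seed ", config$seed)
  } else {
    image <- read_cross_section(config$image_path)
    say("read ", config$image_path)
  }
  if (!is.null(config$group)) image$group <- config$group

  geometry <- if (identical(config$geometry, "auto")) {
    delineate_geometry(image, mode = "auto")
  } else {
    geo <- config$geometry
    if (is.character(geo)) geo <- read_polygons_json(geo)
    assert_that(is.list(geo) && all(c("pith", "outer") %in% names(geo)) ||
                  all(c("pith_polygon", "outer_polygon") %in% names(geo)),
                st, "geometry must be 'auto' or hold pith and outer polygons")
    delineate_geometry(image, mode = "polygons",
                       pith_polygon = geo$pith %||% geo$pith_polygon,
                       outer_polygon = geo$outer %||% geo$outer_polygon)
  }
  say("xylem area ", geometry$xylem_area_px, " px")

  air <- threshold_air(image, method = config$threshold_method,
                       fixed_value = config$threshold_value)
  say("air threshold ", format(attr(air, "threshold")))

  vessels <- detect_vessels(air, geometry,
                            min_area_px = config$min_area_px,
                            max_area_px = config$max_area_px,
                            min_circularity = config$min_circularity,
                            max_circularity = config$max_circularity)
  if (length(config$exclude_ids) > 0 || length(config$include_polygons) > 0) {
    vessels <- apply_manual_edits(vessels, config$exclude_ids,
                                  config$include_polygons, geometry)
  }
  say(nrow(vessels$vessels), " embolized vessels")
  fibers <- derive_fiber_mask(air, vessels, geometry,
                              min_speck_px = config$min_speck_px)

  metrics <- slice_metrics(image, vessels, fibers, geometry)

  regions <- radial_increments(geometry, step_px = config$step_px)
  vmask <- vessels$label_map > 0L
  prof_v <- cumulative_profile(regions, vmask, geometry, "vessels")
  prof_f <- cumulative_profile(regions, fibers$mask, geometry, "fibers",
                               exclusion_cutoff_pct = config$fiber_exclusion_pct)
  thr_v <- if (prof_v$excluded) NA_real_ else threshold95(prof_v)
  thr_f <- if (prof_f$excluded) NA_real_ else threshold95(prof_f)

  assoc <- fiber_association(vessels, fibers, geometry,
                             x_list = config$x_list,
                             min_intersect_px = config$min_intersect_px,
                             sample_id = image$sample_id)

  # the hash covers the analysis parameters, not where results are written
  hcfg <- config
  hcfg$out_dir <- NULL
  result <- structure(list(
    config = config,
    config_hash = config_hash(hcfg),
    sample_id = image$sample_id,
    group = image$group,
    metrics = metrics,
    geometry = geometry,
    air_mask = air,
    vessels = vessels,
    fibers = fibers,
    radial = list(vessels = prof_v, fibers = prof_f,
                  threshold95_vessels = thr_v, threshold95_fibers = thr_f),
    association = assoc,
    truth = truth
  ), class = "slice_result")
  if (!is.null(config$out_dir)) write_slice_result(result, config$out_dir)
  result
}

#' @export
print.slice_result <- function(x, ...) {
  cat("<slice_result>", x$sample_id, "(", x$group, ") hash",
      x$config_hash, "\n")
  cat(sprintf("  PA_vess = %.3f%%  PA_fibers = %.3f%%  (%d vessels)\n",
              x$metrics$pa_vess, x$metrics$pa_fibers,
              x$metrics$n_embolized_vessels))
  cat(sprintf("  threshold95: vessels %s | fibers %s\n",
              format(x$radial$threshold95_vessels),
              format(x$radial$threshold95_fibers)))
  invisible(x)
}

write_slice_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  cfg$out_dir <- NULL
  pre <- file.path(out_dir, result$sample_id)
  write_csv_stamped(result$metrics, paste0(pre, "_metrics.csv"), cfg)
  prof <- rbind(
    cbind(component_kind = "vessels", result$radial$vessels$steps),
    cbind(component_kind = "fibers", result$radial$fibers$steps)
  )
  prof <- cbind(sample_id = result$sample_id, prof)
  write_csv_stamped(prof, paste0(pre, "_radial.csv"), cfg)
  write_csv_stamped(result$association$records, paste0(pre, "_assoc_records.csv"), cfg)
  write_csv_stamped(result$association$summaries, paste0(pre, "_assoc_summary.csv"), cfg)
  write_csv_stamped(result$vessels$vessels, paste0(pre, "_vessels.csv"), cfg)
  if (max(result$vessels$label_map) <= 255) {
    write_mask_tiff(result$vessels$label_map, paste0(pre, "_vessel_labels.tif"))
  }
  write_mask_tiff(result$fibers$mask, paste0(pre, "_fiber_mask.tif"))
  summary <- list(
    config_hash = result$config_hash,
    sample_id = result$sample_id,
    group = result$group,
    pa_vess = result$metrics$pa_vess,
    pa_fibers = result$metrics$pa_fibers,
    threshold95_vessels = result$radial$threshold95_vessels,
    threshold95_fibers = result$radial$threshold95_fibers,
    fiber_profile_excluded = result$radial$fibers$excluded
  )
  jsonlite::write_json(summary, paste0(pre, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Batch analysis and group comparison
#'
#' Runs [run_slice()] over a list of configurations, assembles the tidy
#' per-replicate table (`sample_id`, `group`, `metric`, `value`) for the
#' requested metrics, applies the reporting rules (groups with fewer than
#' two replicates are excluded with a warning; excluded radial fiber
#' profiles yield `NA` thresholds), and runs the configured comparison for
#' each metric.
#'
#' @param configs list of [run_config()] objects.
#' @param metrics metrics to compare; any of `"pa_vess"`, `"pa_fibers"`,
#'   `"threshold95_vessels"`, `"threshold95_fibers"`, `"pct_yes"`,
#'   `"fiber_area_ratio"` (the latter two at the first enlargement radius).
#' @param test `"anova"` (with `posthoc`) or `"kruskal"`.
#' @param posthoc,alpha,transform,k_ratio passed to [anova_posthoc()] /
#'   [kruskal_dunn()].
#' @return list with `table` (tidy long data frame), `results` (one
#'   `comparison_result` per metric) and `slices` (the slice results).
#' @export
batch_compare <- function(configs, metrics = c("pa_vess", "pa_fibers"),
                          test = c("anova", "kruskal"),
                          posthoc = "waller_duncan", alpha = 0.05,
                          transform = "none", k_ratio = 100) {
  test <- match.arg(test)
  st <- "batch_compare"
  assert_that(length(configs) >= 2, st, "need at least two configurations")
  slices <- lapply(configs, run_slice)
  rows <- list()
  for (s in slices) {
    vals <- c(
      pa_vess = s$metrics$pa_vess,
      pa_fibers = s$metrics$pa_fibers,
      threshold95_vessels = s$radial$threshold95_vessels,
      threshold95_fibers = s$radial$threshold95_fibers,
      pct_yes = s$association$summaries$pct_yes[1],
      fiber_area_ratio = s$association$summaries$median_fiber_area_ratio[1]
    )
    for (m in metrics) {
      assert_that(m %in% names(vals), st, paste0("unknown metric '", m, "'"))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s$sample_id, group = s$group, metric = m,
        value = unname(vals[m]), stringsAsFactors = FALSE
      )
    }
  }
  table <- do.call(rbind, rows)
  assert_that(length(unique(table$group)) >= 2, st,
              "need at least 2 groups represented")
  # exclusion reporting
  cnt <- table(unique(table[c("sample_id", "group")])$group)
  small <- names(cnt)[cnt < 2]
  if (length(small) > 0) {
    warning("groups with fewer than 2 replicates excluded from comparison: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  results <- list()
  for (m in metrics) {
    ok <- sum(!is.na(table$value[table$metric == m]))
    assert_that(ok > 0, st, paste0("metric '", m, "' has no values"))
    results[[m]] <- if (test == "anova") {
      anova_posthoc(table, m, posthoc = posthoc, alpha = alpha,
                    transform = transform, k_ratio = k_ratio)
    } else {
      kruskal_dunn(table, m, alpha = alpha)
    }
  }
  list(table = table, results = results, slices = slices)
}
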