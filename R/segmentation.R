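# Air-mask thresholding and vessel/fiber segmentation.

#' Threshold air-filled pixels
#'
#' Marks the low-intensity (air-filled) phase of a cross-section. Air lumina
#' are the dark phase in propagation-based phase-contrast reconstructions;
#' set `invert = TRUE` for reconstructions with the opposite polarity.
#'
#' @param image a [cross_section()].
#' @param method `"otsu"` (automatic, histogram-based) or `"fixed"`.
#' @param fixed_value threshold gray value, required for `method = "fixed"`;
#'   must lie within the image intensity range.
#' @param invert if `TRUE`, air is the bright phase.
#' @return logical matrix marking pixels strictly below (above, if inverted)
#'   the threshold, with attributes `threshold` and `method`.
#' @export
threshold_air <- function(image, method = c("otsu", "fixed"),
                          fixed_value = NULL, invert = FALSE) {
  method <- match.arg(method)
  st <- "threshold_air"
  px <- image$pixels
  rng <- range(px)
  if (method == "otsu") {
    assert_that(diff(rng) > 0, st,
                "Otsu thresholding failed: constant image (no bimodality)")
    thr <- as.numeric(EBImage::otsu(EBImage::Image(px), range = rng,
                                    levels = 256L))
  } else {
    assert_that(is.numeric(fixed_value) && length(fixed_value) == 1, st,
                "method 'fixed' requires a single numeric fixed_value")
    assert_that(fixed_value >= rng[1] && fixed_value <= rng[2], st,
                sprintf("fixed threshold %.4g outside image range [%.4g, %.4g]",
                        fixed_value, rng[1], rng[2]))
    thr <- fixed_value
  }
  mask <- if (invert) px > thr else px < thr
  attr(mask, "threshold") <- thr
  attr(mask, "method") <- method
  mask
}

# shape statistics for every label of a label map
region_stats <- function(lab, nlab) {
  if (nlab == 0) {
    return(data.frame(vessel_id = integer(0), area_px = integer(0),
                      perimeter_px = numeric(0), circularity = numeric(0),
                      centroid_r = numeric(0), centroid_c = numeric(0)))
  }
  area <- tabulate(lab[lab > 0L], nbins = nlab)
  per <- contour_perimeters(lab, nlab)
  idx <- which(lab > 0L, arr.ind = TRUE)
  ids <- lab[lab > 0L]
  cr <- tapply(idx[, 1] - 1, ids, mean)
  cc <- tapply(idx[, 2] - 1, ids, mean)
  data.frame(
    vessel_id = seq_len(nlab),
    area_px = area,
    perimeter_px = per,
    circularity = 4 * pi * area / per^2,
    centroid_r = as.numeric(cr),
    centroid_c = as.numeric(cc)
  )
}

new_vessel_set <- function(df, label_map) {
  structure(list(
    vessels = df,
    label_map = label_map,
    total_embolized_vessel_area_px = sum(df$area_px)
  ), class = "vessel_set")
}

#' @export
print.vessel_set <- function(x, ...) {
  cat("<vessel_set>", nrow(x$vessels), "vessels,",
      x$total_embolized_vessel_area_px, "px total\n")
  invisible(x)
}

#' Detect embolized vessels by particle analysis
#'
#' Labels 8-connected components of the air mask inside the xylem annulus
#' and keeps those passing user-defined size and circularity filters, the
#' digital analogue of particle analysis with size/circularity cut-offs.
#' Circularity is \eqn{4\pi A / P^2} with `P` the polygonal length of the
#' outer contour traced through boundary pixel centres. Labels are assigned
#' in raster-scan order of each component's first pixel.
#'
#' @param air_mask logical matrix from [threshold_air()].
#' @param geometry a `xylem_geometry`.
#' @param min_area_px,max_area_px area filter, px. The default 200 px
#'   corresponds to a lumen diameter of about 16 um at 1 um/px.
#' @param min_circularity,max_circularity circularity filter; digitisation
#'   can push near-circular regions slightly above 1.
#' @param connectivity 4 or 8 (default 8, matching common particle analysis).
#' @return a `vessel_set`: data frame of per-vessel statistics
#'   (`vessel_id`, `area_px`, `perimeter_px`, `circularity`, `centroid_r`,
#'   `centroid_c`), the integer label map, and the total embolized area.
#' @export
detect_vessels <- function(air_mask, geometry, min_area_px = 200,
                           max_area_px = Inf, min_circularity = 0.3,
                           max_circularity = 1.2, connectivity = 8L) {
  st <- "detect_vessels"
  assert_that(min_area_px <= max_area_px, st,
              "min_area_px must not exceed max_area_px")
  assert_that(min_circularity <= max_circularity, st,
              "min_circularity must not exceed max_circularity")
  m <- as_mask(air_mask, st) & geometry$xylem_mask
  lab <- cc_label(m, as.integer(connectivity))
  nlab <- max(lab)
  stats <- region_stats(lab, nlab)
  keep <- stats$area_px >= min_area_px & stats$area_px <= max_area_px &
    stats$circularity >= min_circularity & stats$circularity <= max_circularity
  kept <- stats[keep, , drop = FALSE]
  # relabel kept components 1..k preserving raster order
  map <- integer(nlab)
  map[kept$vessel_id] <- seq_len(nrow(kept))
  new_lab <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0L
  new_lab[pos] <- map[lab[pos]]
  kept$vessel_id <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  new_vessel_set(kept, new_lab)
}

#' Apply manual vessel edits
#'
#' Mirrors the manual-observation step of supervised particle analysis:
#' removes falsely detected vessels by id and appends user-traced polygon
#' regions as new vessels. Included polygons are rasterised with the
#' pixel-centre rule; their perimeter (hence circularity) is that of the
#' polygon itself.
#'
#' @param vessels a `vessel_set`.
#' @param exclude_ids integer ids to drop (must exist).
#' @param include_polygons list of 0-based (row, col) vertex matrices.
#' @param geometry a `xylem_geometry`; included regions must lie inside the
#'   xylem and must not overlap existing vessels.
#' @return the edited `vessel_set`.
#' @export
apply_manual_edits <- function(vessels, exclude_ids = integer(0),
                               include_polygons = list(), geometry) {
  st <- "apply_manual_edits"
  df <- vessels$vessels
  lab <- vessels$label_map
  assert_that(all(exclude_ids %in% df$vessel_id), st,
              "exclude_ids must be a subset of existing vessel ids")
  if (length(exclude_ids) > 0) {
    lab[matrix(lab %in% exclude_ids, nrow(lab), ncol(lab))] <- 0L
    df <- df[!df$vessel_id %in% exclude_ids, , drop = FALSE]
  }
  next_id <- if (nrow(df) > 0) max(df$vessel_id) else 0L
  for (poly in include_polygons) {
    check_polygon(poly, nrow(lab), ncol(lab), "included")
    m <- rasterize_polygon(poly, nrow(lab), ncol(lab))
    assert_that(sum(m) > 0, st, "an included polygon rasterises to no pixels")
    assert_that(all(geometry$xylem_mask[m]), st,
                "an included region lies outside the xylem annulus")
    assert_that(all(lab[m] == 0L), st,
                "an included region overlaps an existing vessel")
    next_id <- next_id + 1L
    lab[m] <- next_id
    idx <- which(m, arr.ind = TRUE)
    per <- polygon_perimeter(poly[, 1], poly[, 2])
    df <- rbind(df, data.frame(
      vessel_id = next_id, area_px = sum(m), perimeter_px = per,
      circularity = 4 * pi * sum(m) / per^2,
      centroid_r = mean(idx[, 1] - 1), centroid_c = mean(idx[, 2] - 1)
    ))
  }
  # disjointness holds by construction (overlaps rejected above); re-validate
  assert_that(sum(lab > 0L) == sum(df$area_px), st,
              "internal error: vessel pixel sets are not disjoint")
  rownames(df) <- NULL
  new_vessel_set(df, lab)
}

#' Derive the air-filled fiber mask
#'
#' Air-filled fibers are all thresholded (air) pixels in the xylem that
#' remain after subtracting the vessel regions: an area-based definition
#' that avoids per-cell centroid detection, which is unreliable for
#' small-lumen fibers. With `min_speck_px = 0` (the default) isolated noise
#' pixels are retained.
#'
#' @param air_mask logical matrix from [threshold_air()].
#' @param vessels a `vessel_set` whose pixels are removed.
#' @param geometry a `xylem_geometry`.
#' @param min_speck_px if positive, 8-connected components smaller than this
#'   are removed from the fiber mask.
#' @return a `fiber_mask`: list with the logical `mask` and its `area_px`.
#' @export
derive_fiber_mask <- function(air_mask, vessels, geometry, min_speck_px = 0L) {
  st <- "derive_fiber_mask"
  air <- as_mask(air_mask, st)
  core <- air & geometry$xylem_mask
  vpix <- vessels$label_map > 0L
  if (!all(core[vpix])) {
    warning("some vessel pixels are not air-filled xylem pixels ",
            "(manual inclusions?); they are still subtracted", call. = FALSE)
  }
  mask <- core & !vpix
  if (min_speck_px > 0) {
    lab <- cc_label(mask, 8L)
    if (max(lab) > 0) {
      area <- tabulate(lab[lab > 0L], nbins = max(lab))
      drop <- which(area < min_speck_px)
      if (length(drop) > 0) {
        mask[matrix(lab %in% drop, nrow(mask), ncol(mask))] <- FALSE
      }
    }
  }
  structure(list(mask = mask, area_px = sum(mask)), class = "fiber_mask")
}

#' @export
print.fiber_mask <- function(x, ...) {
  cat("<fiber_mask>", x$area_px, "px\n")
  invisible(x)
}
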