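# Per-vessel spatial association between embolized vessels and air-filled
# fibers via Euclidean region enlargement and intersection.

#' Euclidean enlargement of a pixel region
#'
#' All pixels of the clip mask whose Euclidean distance to the nearest
#' region pixel is at most `x_px`. Distances are exact (integer squared
#' distances), so the result equals brute-force per-pixel nearest-distance
#' computation.
#'
#' @param region logical matrix marking the region.
#' @param x_px enlargement radius in pixels (`x_px = 0` returns the region).
#' @param clip_mask optional logical matrix restricting the result.
#' @return logical matrix of the enlarged region.
#' @export
enlarge_region <- function(region, x_px, clip_mask = NULL) {
  st <- "enlarge_region"
  region <- as_mask(region, st)
  assert_that(is.numeric(x_px) && x_px >= 0, st, "x_px must be >= 0")
  if (!any(region)) {
    warning("enlarge_region: empty input region", call. = FALSE)
    out <- region
    if (!is.null(clip_mask)) out <- out & clip_mask
    return(out)
  }
  if (x_px == 0) {
    out <- region
  } else {
    # work on a padded bounding box; the enlargement cannot escape it
    bb <- mask_bbox(region, pad = ceiling(x_px) + 1L)
    sub <- region[bb$r[1]:bb$r[2], bb$c[1]:bb$c[2], drop = FALSE]
    d2 <- edt_sq(sub)
    out <- matrix(FALSE, nrow(region), ncol(region))
    out[bb$r[1]:bb$r[2], bb$c[1]:bb$c[2]] <- d2 <= x_px^2
  }
  if (!is.null(clip_mask)) out <- out & as_mask(clip_mask, st)
  out
}

#' Vessel-fiber neighbourhood association
#'
#' For every embolized vessel and every enlargement radius, enlarges the
#' vessel region by `x` pixels (Euclidean), clips to the xylem, removes the
#' vessel's own pixels (the annulus-only convention keeps the area ratio in
#' `[0, 1]`), and intersects with the air-filled fiber mask. Overlapping
#' neighbourhoods of nearby vessels are evaluated independently, so a fiber
#' pixel may count for several vessels.
#'
#' @param vessels a `vessel_set` of embolized vessels.
#' @param fibers a `fiber_mask`.
#' @param geometry a `xylem_geometry`.
#' @param x_list enlargement radii in pixels (default 10, 15, 20, 25).
#' @param min_intersect_px minimum intersected fiber area (px) for a vessel
#'   to count as YES (default 1: any air-filled fiber pixel within reach).
#' @param sample_id sample identifier carried into the output tables.
#' @return list with `records` (one row per vessel x enlargement:
#'   `sample_id`, `vessel_id`, `enlargement_px`, `enlarged_area_px`,
#'   `intersect_fiber_area_px`, `fiber_area_ratio`, `has_fibers`) and
#'   `summaries` (per enlargement: `n_yes`, `n_no`, `pct_yes`,
#'   `median_fiber_area_ratio`).
#' @export
fiber_association <- function(vessels, fibers, geometry,
                              x_list = c(10, 15, 20, 25),
                              min_intersect_px = 1,
                              sample_id = "sample") {
  st <- "fiber_association"
  assert_that(length(x_list) > 0, st, "x_list must be non-empty")
  assert_that(all(dim(vessels$label_map) == dim(fibers$mask)), st,
              "vessel and fiber masks are not aligned")
  lab <- vessels$label_map
  xylem <- geometry$xylem_mask
  fmask <- fibers$mask
  xmax <- max(x_list)
  rec <- list()
  for (v in vessels$vessels$vessel_id) {
    vmask <- lab == v
    bb <- mask_bbox(vmask, pad = ceiling(xmax) + 1L)
    rs <- bb$r[1]:bb$r[2]; cs <- bb$c[1]:bb$c[2]
    d2 <- edt_sq(vmask[rs, cs, drop = FALSE])
    sub_x <- xylem[rs, cs, drop = FALSE]
    sub_f <- fmask[rs, cs, drop = FALSE]
    sub_v <- vmask[rs, cs, drop = FALSE]
    for (x in x_list) {
      ann <- (d2 <= x^2) & !sub_v & sub_x
      inter <- sum(ann & sub_f)
      enl <- sum(ann)
      rec[[length(rec) + 1L]] <- data.frame(
        sample_id = sample_id, vessel_id = v, enlargement_px = x,
        enlarged_area_px = enl, intersect_fiber_area_px = inter,
        fiber_area_ratio = if (enl > 0) inter / enl else 0,
        has_fibers = inter >= min_intersect_px
      )
    }
  }
  records <- if (length(rec) > 0) do.call(rbind, rec) else data.frame(
    sample_id = character(0), vessel_id = integer(0),
    enlargement_px = numeric(0), enlarged_area_px = integer(0),
    intersect_fiber_area_px = integer(0), fiber_area_ratio = numeric(0),
    has_fibers = logical(0)
  )
  summaries <- do.call(rbind, lapply(x_list, function(x) {
    r <- records[records$enlargement_px == x, , drop = FALSE]
    n_yes <- sum(r$has_fibers)
    n_no <- nrow(r) - n_yes
    data.frame(
      sample_id = sample_id, enlargement_px = x, n_yes = n_yes, n_no = n_no,
      pct_yes = if (nrow(r) > 0) 100 * n_yes / nrow(r) else NA_real_,
      median_fiber_area_ratio = if (nrow(r) > 0) median(r$fiber_area_ratio)
      else NA_real_
    )
  }))
  list(records = records, summaries = summaries)
}
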