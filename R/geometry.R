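# Cross-section container and pith/xylem geometry delineation.

#' Cross-section image container
#'
#' A single-channel grayscale stem cross-section. Pixels are stored as a
#' numeric matrix in (row, col) order; polygon and centroid coordinates
#' throughout the package are 0-based (row, col) with pixel-centre semantics.
#'
#' @param pixels numeric matrix of intensities (any finite range; microCT
#'   reconstructions read from 8/16-bit files are scaled to `[0, 1]`).
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param sample_id,group sample annotation; `group` is one of CTR, FDD,
#'   SDD, R_FDD, R_SDD or "unknown".
#' @return an object of class `cross_section`.
#' @export
cross_section <- function(pixels, pixel_size_um = 1.0,
                          sample_id = "sample", group = "unknown") {
  st <- "cross_section"
  assert_that(is.matrix(pixels) && is.numeric(pixels), st,
              "pixels must be a numeric matrix")
  assert_that(nrow(pixels) >= 64 && ncol(pixels) >= 64, st,
              "image must be at least 64 x 64 pixels")
  assert_that(all(is.finite(pixels)), st, "intensities must be finite")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 sample_id = sample_id, group = group),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat("<cross_section>", x$sample_id, "(", x$group, ")",
      nrow(x$pixels), "x", ncol(x$pixels), "px @", x$pixel_size_um, "um/px\n")
  invisible(x)
}

new_xylem_geometry <- function(pith_mask, xylem_mask,
                               inner_boundary = NULL, outer_boundary = NULL) {
  structure(list(
    pith_mask = pith_mask,
    xylem_mask = xylem_mask,
    xylem_area_px = sum(xylem_mask),
    inner_boundary = inner_boundary,
    outer_boundary = outer_boundary
  ), class = "xylem_geometry")
}

#' @export
print.xylem_geometry <- function(x, ...) {
  cat("<xylem_geometry> pith:", sum(x$pith_mask), "px | xylem:",
      x$xylem_area_px, "px\n")
  invisible(x)
}

# boundary polygon (0-based row/col) of a mask via marching-squares contour
mask_boundary_polygon <- function(mask) {
  cl <- grDevices::contourLines(
    x = seq_len(nrow(mask)) - 1, y = seq_len(ncol(mask)) - 1,
    z = mask + 0, levels = 0.5
  )
  if (length(cl) == 0) return(NULL)
  len <- vapply(cl, function(p) length(p$x), 0L)
  p <- cl[[which.max(len)]]
  cbind(p$x, p$y)
}

check_polygon <- function(poly, nr, nc, what) {
  st <- "delineate_geometry"
  assert_that(is.matrix(poly) && ncol(poly) == 2 && nrow(poly) >= 3, st,
              paste0(what, " polygon must be a matrix of >= 3 (row, col) vertices"))
  assert_that(all(is.finite(poly)), st, paste0(what, " polygon has non-finite vertices"))
  assert_that(all(poly[, 1] >= -0.5 & poly[, 1] <= nr - 0.5 &
                    poly[, 2] >= -0.5 & poly[, 2] <= nc - 0.5), st,
              paste0(what, " polygon extends outside the image bounds"))
  assert_that(!polygon_self_intersects(poly[, 1], poly[, 2]), st,
              paste0(what, " polygon is self-intersecting"))
  invisible(poly)
}

#' Delineate pith and xylem geometry
#'
#' Builds the pith mask and the xylem annulus that is the denominator of the
#' percent-embolized-area metrics. In `polygons` mode the user supplies the
#' pith/xylem and xylem/cambium boundary polygons (as traced in supervised
#' image analysis); they are rasterised with the pixel-centre-in-polygon
#' rule. In `auto` mode, suitable for near-circular anatomy, the stem is the
#' filled largest bright-tissue component and the pith is the filled central
#' low-intensity blob.
#'
#' @param image a [cross_section()].
#' @param mode `"polygons"` or `"auto"`.
#' @param pith_polygon,outer_polygon matrices of 0-based (row, col) vertices
#'   (required in `polygons` mode).
#' @return an object of class `xylem_geometry` with fields `pith_mask`,
#'   `xylem_mask`, `xylem_area_px`, `inner_boundary`, `outer_boundary`.
#' @export
delineate_geometry <- function(image, mode = c("auto", "polygons"),
                               pith_polygon = NULL, outer_polygon = NULL) {
  mode <- match.arg(mode)
  st <- "delineate_geometry"
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  if (mode == "polygons") {
    assert_that(!is.null(pith_polygon) && !is.null(outer_polygon), st,
                "polygons mode requires both pith_polygon and outer_polygon")
    check_polygon(pith_polygon, nr, nc, "pith")
    check_polygon(outer_polygon, nr, nc, "outer")
    pith <- rasterize_polygon(pith_polygon, nr, nc)
    stem <- rasterize_polygon(outer_polygon, nr, nc)
    assert_that(sum(pith) > 0 && sum(stem) > 0, st,
                "a boundary polygon rasterises to an empty mask")
    assert_that(all(stem[pith]), st,
                "the pith polygon must lie inside the outer polygon")
    assert_that(sum(stem) > sum(pith), st,
                "degenerate geometry: inner boundary must be strictly inside the outer boundary")
    xylem <- stem & !pith
    return(new_xylem_geometry(pith, xylem, pith_polygon, outer_polygon))
  }
  # auto mode: intensity-based, assumes bright cell walls on a darker
  # background and a low-texture water-filled pith around the image centre
  rng <- range(px)
  assert_that(diff(rng) > 0, st, "auto fit failure: constant image")
  thr <- as.numeric(EBImage::otsu(EBImage::Image(px), range = rng,
                                  levels = 256L))
  bright <- px > thr
  solid <- EBImage::closing(EBImage::Image(bright + 0),
                            EBImage::makeBrush(5, "disc")) > 0.5
  solid <- EBImage::fillHull(EBImage::Image(solid + 0)) > 0.5
  lab <- cc_label(matrix(as.logical(solid), nr, nc), 8L)
  assert_that(max(lab) > 0, st, "auto fit failure: no tissue found")
  stem <- lab == which.max(tabulate(lab[lab > 0]))
  # pith: the non-wall region containing the stem centroid. A second Otsu on
  # the stem's non-air intensities separates lumina/pith from the brighter
  # walls; a small opening cuts off thin water-filled rays that touch the
  # pith boundary before hole-filling.
  idx <- which(stem, arr.ind = TRUE)
  cen <- round(colMeans(idx))
  vals <- px[stem & px > thr]
  assert_that(length(vals) > 1 && diff(range(vals)) > 0, st,
              "auto fit failure: no wall/lumen contrast inside the stem")
  thr2 <- as.numeric(EBImage::otsu(EBImage::Image(matrix(vals)),
                                   range = range(vals), levels = 256L))
  labd <- cc_label(stem & px < thr2, 8L)
  pid <- labd[cen[1], cen[2]]
  assert_that(pid > 0, st,
              "auto fit failure: no low-intensity pith at the stem centre")
  opened <- EBImage::opening(EBImage::Image((labd == pid) + 0),
                             EBImage::makeBrush(7, "disc")) > 0.5
  # the opening may leave detached fragments (lumina once linked through
  # thin rays); keep only the piece containing the stem centroid
  labp <- cc_label(matrix(as.logical(opened), nr, nc), 8L)
  pid2 <- labp[cen[1], cen[2]]
  assert_that(pid2 > 0, st,
              "auto fit failure: pith vanished during morphological cleanup")
  pith <- EBImage::fillHull(EBImage::Image((labp == pid2) + 0)) > 0.5
  pith <- matrix(as.logical(pith), nr, nc)
  assert_that(sum(pith) > 0, st, "auto fit failure: empty pith after cleanup")
  xylem <- stem & !pith
  assert_that(sum(xylem) > 0, st, "auto fit failure: empty xylem annulus")
  new_xylem_geometry(pith, xylem,
                     inner_boundary = mask_boundary_polygon(pith),
                     outer_boundary = mask_boundary_polygon(stem))
}
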