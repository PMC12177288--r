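# Percent-embolized-area metrics over the xylem annulus.

#' Percent embolized vessel area
#'
#' \eqn{PA_{vess} = 100 \times} (embolized vessel area) / (total xylem
#' area). The pith is excluded from the denominator; the xylem annulus is
#' the sole denominator of both PA metrics.
#'
#' @param vessels a `vessel_set` of embolized vessels.
#' @param geometry a `xylem_geometry`.
#' @return percentage (full floating precision; round only for reporting).
#' @export
pa_vess <- function(vessels, geometry) {
  assert_that(geometry$xylem_area_px > 0, "pa_vess",
              "zero xylem area: cannot normalise")
  100 * vessels$total_embolized_vessel_area_px / geometry$xylem_area_px
}

#' Percent air-filled fiber area
#'
#' \eqn{PA_{fibers} = 100 \times} (air-filled fiber area) / (total xylem
#' area).
#'
#' @param fibers a `fiber_mask`.
#' @param geometry a `xylem_geometry`.
#' @return percentage.
#' @export
pa_fibers <- function(fibers, geometry) {
  assert_that(geometry$xylem_area_px > 0, "pa_fibers",
              "zero xylem area: cannot normalise")
  100 * fibers$area_px / geometry$xylem_area_px
}

#' Per-slice metric record
#'
#' Collects the two PA metrics and their underlying areas for one analysed
#' cross-section into a tidy one-row data frame.
#'
#' @param image a [cross_section()].
#' @param vessels a `vessel_set`.
#' @param fibers a `fiber_mask`.
#' @param geometry a `xylem_geometry`.
#' @return one-row data frame with `sample_id`, `group`, `pa_vess`,
#'   `pa_fibers`, the pixel areas and the embolized vessel count.
#' @export
slice_metrics <- function(image, vessels, fibers, geometry) {
  data.frame(
    sample_id = image$sample_id,
    group = image$group,
    pa_vess = pa_vess(vessels, geometry),
    pa_fibers = pa_fibers(fibers, geometry),
    xylem_area_px = geometry$xylem_area_px,
    embolized_vessel_area_px = vessels$total_embolized_vessel_area_px,
    airfilled_fiber_area_px = fibers$area_px,
    n_embolized_vessels = nrow(vessels$vessels),
    stringsAsFactors = FALSE
  )
}
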