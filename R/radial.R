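# Radial (pith -> cambium) distribution of an air-filled component via
# incremental outward enlargement of the inner xylem boundary, and the 95%
# cumulative-area threshold.

#' Nested radial increment regions
#'
#' Formalises "enlarging the inner xylem ROI outward" as a Euclidean
#' distance transform from the pith: region *k* contains the xylem pixels
#' whose distance to the nearest pith pixel is at most `k * step_px`,
#' clipped to the xylem annulus. The sequence is nested and stops at the
#' first region covering the whole xylem.
#'
#' @param geometry a `xylem_geometry`.
#' @param step_px enlargement increment in pixels (default 10).
#' @return object of class `radial_regions`: list of nested logical masks
#'   plus per-step covered areas and covered percent of xylem area.
#' @export
radial_increments <- function(geometry, step_px = 10L) {
  st <- "radial_increments"
  assert_that(step_px >= 1, st, "step_px must be >= 1")
  assert_that(sum(geometry$xylem_mask) > 0, st, "degenerate geometry: empty xylem")
  assert_that(sum(geometry$pith_mask) > 0, st, "degenerate geometry: empty pith")
  d2 <- edt_sq(geometry$pith_mask)
  xmask <- geometry$xylem_mask
  dmax2 <- max(d2[xmask])
  kmax <- 1L
  while ((kmax * step_px)^2 < dmax2) kmax <- kmax + 1L
  masks <- vector("list", kmax)
  covered <- integer(kmax)
  for (k in seq_len(kmax)) {
    masks[[k]] <- xmask & (d2 <= (k * step_px)^2)
    covered[k] <- sum(masks[[k]])
  }
  structure(list(
    masks = masks,
    step_px = as.integer(step_px),
    covered_area_px = covered,
    covered_fraction_pct = 100 * covered / geometry$xylem_area_px
  ), class = "radial_regions")
}

#' Cumulative radial profile of a component
#'
#' Measures, for each radial increment, the covered xylem area and the
#' component area it contains, and the cumulative percent of total component
#' area. Profiles of components whose total area is zero, or of fiber
#' components below the exclusion cutoff (replicates with total air-filled
#' fiber area under 0.5% of xylem area are not measured), are flagged
#' excluded.
#'
#' @param regions a `radial_regions` from [radial_increments()].
#' @param component_mask logical matrix (must lie inside the xylem).
#' @param geometry a `xylem_geometry`.
#' @param component_kind `"vessels"` or `"fibers"`.
#' @param exclusion_cutoff_pct percent-of-xylem-area cutoff below which a
#'   fiber profile is excluded (default 0.5 for fibers, 0 for vessels).
#' @return object of class `radial_profile` with a per-step data frame
#'   (`step_index`, `covered_xylem_area_px`, `covered_fraction_pct`,
#'   `component_area_in_step_px`, `cumulative_component_pct`), the component
#'   kind and the exclusion status.
#' @export
cumulative_profile <- function(regions, component_mask, geometry,
                               component_kind = c("vessels", "fibers"),
                               exclusion_cutoff_pct = NULL) {
  component_kind <- match.arg(component_kind)
  st <- "cumulative_profile"
  comp <- as_mask(component_mask, st)
  assert_that(all(geometry$xylem_mask[comp]), st,
              "component mask must lie inside the xylem annulus")
  if (is.null(exclusion_cutoff_pct)) {
    exclusion_cutoff_pct <- if (component_kind == "fibers") 0.5 else 0
  }
  total <- sum(comp)
  k <- length(regions$masks)
  cum_area <- vapply(regions$masks, function(m) sum(comp & m), 0L)
  in_step <- diff(c(0L, cum_area))
  steps <- data.frame(
    step_index = seq_len(k),
    covered_xylem_area_px = regions$covered_area_px,
    covered_fraction_pct = regions$covered_fraction_pct,
    component_area_in_step_px = in_step,
    cumulative_component_pct = if (total > 0) 100 * cum_area / total else
      rep(NA_real_, k)
  )
  pa <- 100 * total / geometry$xylem_area_px
  excluded <- FALSE
  reason <- NA_character_
  if (total == 0) {
    excluded <- TRUE
    reason <- "empty component"
  } else if (pa < exclusion_cutoff_pct) {
    excluded <- TRUE
    reason <- sprintf("component area %.3f%% of xylem below the %.1f%% cutoff",
                      pa, exclusion_cutoff_pct)
  }
  structure(list(
    steps = steps,
    step_px = regions$step_px,
    component_kind = component_kind,
    component_area_px = total,
    component_pct_of_xylem = pa,
    excluded = excluded,
    exclusion_reason = reason
  ), class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat("<radial_profile>", x$component_kind, "|", nrow(x$steps), "steps of",
      x$step_px, "px |", x$component_area_px, "component px\n")
  if (x$excluded) cat("  EXCLUDED:", x$exclusion_reason, "\n")
  invisible(x)
}

#' Radial 95% cumulative-area threshold
#'
#' The percent of covered xylem area at the first radial step whose
#' cumulative component area reaches 95% of the total: small values mean
#' the component concentrates toward the pith. The threshold is
#' step-quantised by default; `interpolate = TRUE` interpolates linearly in
#' covered fraction between the bracketing steps.
#'
#' @param profile a `radial_profile`.
#' @param prob cumulative percent defining the threshold (default 95).
#' @param interpolate interpolate between steps instead of quantising.
#' @return percent of covered xylem area, or `NA` (with a warning) for an
#'   excluded profile.
#' @export
threshold95 <- function(profile, prob = 95, interpolate = FALSE) {
  if (profile$excluded) {
    warning("radial profile is excluded (", profile$exclusion_reason,
            "); threshold is NA", call. = FALSE)
    return(NA_real_)
  }
  s <- profile$steps
  k <- which(s$cumulative_component_pct >= prob)[1]
  if (!interpolate || k == 1L) return(s$covered_fraction_pct[k])
  c0 <- s$cumulative_component_pct[k - 1]
  c1 <- s$cumulative_component_pct[k]
  f0 <- s$covered_fraction_pct[k - 1]
  f1 <- s$covered_fraction_pct[k]
  if (c1 == c0) return(f1)
  f0 + (prob - c0) / (c1 - c0) * (f1 - f0)
}
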