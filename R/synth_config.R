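#' Synthetic cross-section configuration
#'
#' Parameters of the synthetic poplar-like stem cross-section generator. The
#' generator draws a circular pith, a xylem annulus bounded by a thin solid
#' outer band (cambium side), large round vessel lumina, a hexagonal lattice
#' of small fiber lumina interrupted by radial parenchyma rays, and renders
#' air-filled lumina darker than water-filled ones, as in propagation-based
#' phase-contrast microCT at about 1 um/px.
#'
#' @param image_size_px side of the square image, pixels.
#' @param pixel_size_um physical pixel size (default 1 um/px).
#' @param pith_radius_px radius of the central pith disk.
#' @param xylem_outer_radius_px outer radius of the xylem annulus.
#' @param vessel_count number of vessel lumina to place.
#' @param vessel_radius_px_range min and max vessel lumen radius.
#' @param fiber_cell_pitch_px spacing of the hexagonal fiber lattice.
#' @param fiber_lumen_radius_px radius of a fiber lumen.
#' @param ray_count,ray_width_px number and width of parenchyma rays (kept
#'   water-filled; fiber lumina are not placed on rays).
#' @param frac_vessels_embolized target embolized-vessel area as a fraction
#'   of total xylem area (the ground-truth PA_vess / 100).
#' @param frac_fibers_airfilled target air-filled-fiber area as a fraction of
#'   total xylem area (the ground-truth PA_fibers / 100).
#' @param radial_target_vessels,radial_target_fibers either `"uniform"` or
#'   the percent of covered xylem area (pith outward) at which the cumulative
#'   area of the placed component should reach 95%.
#' @param gray_levels named list with `air`, `water`, `wall` mean gray values
#'   in `[0, 1]`; air must be darkest, walls brightest.
#' @param noise_sd standard deviation of additive Gaussian gray noise.
#' @param edge_enhance logical; apply a mild unsharp mask emulating
#'   propagation-based phase-contrast edge enhancement.
#' @param fiber_fill_mode `"patch"` places air-filled fibers as contiguous
#'   clusters of lattice cells (clustered inner-xylem emptying);
#'   `"random"` picks lattice cells independently.
#' @param fiber_patch_size number of lattice cells per contiguous patch.
#' @param seed integer RNG seed; generation is fully deterministic given the
#'   configuration.
#' @return an object of class `synth_config`.
#' @seealso [synth_preset()], [generate_cross_section()]
#' @export
synth_config <- function(image_size_px = 512L,
                         pixel_size_um = 1.0,
                         pith_radius_px = 55,
                         xylem_outer_radius_px = 235,
                         vessel_count = 30L,
                         vessel_radius_px_range = c(14, 22),
                         fiber_cell_pitch_px = 8,
                         fiber_lumen_radius_px = 2.5,
                         ray_count = 16L,
                         ray_width_px = 2,
                         frac_vessels_embolized = 0,
                         frac_fibers_airfilled = 0,
                         radial_target_vessels = "uniform",
                         radial_target_fibers = "uniform",
                         gray_levels = list(air = 0.15, water = 0.65, wall = 0.88),
                         noise_sd = 0.02,
                         edge_enhance = FALSE,
                         fiber_fill_mode = c("patch", "random"),
                         fiber_patch_size = 12L,
                         seed = 1L) {
  fiber_fill_mode <- match.arg(fiber_fill_mode)
  cfg <- list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    pith_radius_px = pith_radius_px,
    xylem_outer_radius_px = xylem_outer_radius_px,
    vessel_count = as.integer(vessel_count),
    vessel_radius_px_range = as.numeric(vessel_radius_px_range),
    fiber_cell_pitch_px = fiber_cell_pitch_px,
    fiber_lumen_radius_px = fiber_lumen_radius_px,
    ray_count = as.integer(ray_count),
    ray_width_px = ray_width_px,
    frac_vessels_embolized = frac_vessels_embolized,
    frac_fibers_airfilled = frac_fibers_airfilled,
    radial_target_vessels = radial_target_vessels,
    radial_target_fibers = radial_target_fibers,
    gray_levels = gray_levels,
    noise_sd = noise_sd,
    edge_enhance = isTRUE(edge_enhance),
    fiber_fill_mode = fiber_fill_mode,
    fiber_patch_size = as.integer(fiber_patch_size),
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  st <- "synth_config"
  assert_that(cfg$pith_radius_px < cfg$xylem_outer_radius_px, st,
              "pith_radius_px must be smaller than xylem_outer_radius_px")
  assert_that(cfg$xylem_outer_radius_px < cfg$image_size_px / 2, st,
              "xylem_outer_radius_px must be smaller than image_size_px / 2")
  assert_that(cfg$frac_vessels_embolized >= 0 && cfg$frac_vessels_embolized <= 1,
              st, "frac_vessels_embolized must be in [0, 1]")
  assert_that(cfg$frac_fibers_airfilled >= 0 && cfg$frac_fibers_airfilled <= 1,
              st, "frac_fibers_airfilled must be in [0, 1]")
  g <- cfg$gray_levels
  assert_that(g$air < g$water && g$water < g$wall, st,
              "gray levels must satisfy air < water < wall (air is darkest)")
  assert_that(cfg$vessel_radius_px_range[1] <= cfg$vessel_radius_px_range[2],
              st, "vessel_radius_px_range must be ordered (min, max)")
  for (tgt in c(cfg$radial_target_vessels, cfg$radial_target_fibers)) {
    ok <- identical(tgt, "uniform") ||
      (is.numeric(tgt) && tgt > 0 && tgt <= 100)
    assert_that(ok, st, "radial targets must be 'uniform' or in (0, 100]")
  }
  assert_that(cfg$noise_sd >= 0, st, "noise_sd must be non-negative")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>", x$image_size_px, "x", x$image_size_px, "px @",
      x$pixel_size_um, "um/px\n")
  cat("  pith r =", x$pith_radius_px, "| xylem outer r =",
      x$xylem_outer_radius_px, "| vessels:", x$vessel_count, "\n")
  cat("  target PA_vess =", 100 * x$frac_vessels_embolized,
      "% | target PA_fibers =", 100 * x$frac_fibers_airfilled, "%\n")
  cat("  radial targets: vessels =", format(x$radial_target_vessels),
      "| fibers =", format(x$radial_target_fibers), "\n")
  invisible(x)
}

#' Named generator presets pinned to the study groups
#'
#' Presets whose ground-truth area fractions equal the reported group means
#' for well-watered controls (`ctr`), fast- and slow-developed drought
#' (`fdd`, `sdd`), the corresponding 24-h recovery groups (`r_fdd`,
#' `r_sdd`), plus a `pooled` preset carrying the all-treatment radial
#' placement targets (95% of embolized vessel area within the first 68.0% of
#' covered xylem area, 95% of air-filled fiber area within the first 55.1%).
#' Presets are read from the packaged `presets.yaml`.
#'
#' @param name one of `"ctr"`, `"fdd"`, `"sdd"`, `"r_fdd"`, `"r_sdd"`,
#'   `"pooled"`.
#' @param seed RNG seed for the generated replicate.
#' @param ... overrides passed on to [synth_config()].
#' @return a `synth_config` with a `group` attribute.
#' @export
synth_preset <- function(name, seed = 1L, ...) {
  presets <- yaml::read_yaml(system.file("extdata", "presets.yaml",
                                         package = "xylemCT"))
  if (!name %in% names(presets)) {
    stop_xct("synth_preset", "unknown preset '", name, "'; available: ",
             paste(names(presets), collapse = ", "))
  }
  p <- presets[[name]]
  args <- list(
    frac_vessels_embolized = p$frac_vessels_embolized,
    frac_fibers_airfilled = p$frac_fibers_airfilled,
    radial_target_vessels = p$radial_target_vessels,
    radial_target_fibers = p$radial_target_fibers,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  cfg <- do.call(synth_config, args)
  attr(cfg, "group") <- p$group
  attr(cfg, "preset") <- name
  cfg
}
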