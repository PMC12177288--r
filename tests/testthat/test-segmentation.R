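test_that("fixed thresholding marks exactly the pixels strictly below the cut", {
  px <- matrix(200, 64, 64)
  px[1, 1] <- 10
  img <- cross_section(px)
  m <- threshold_air(img, method = "fixed", fixed_value = 100)
  expect_equal(sum(m), 1)
  expect_true(m[1, 1])
  expect_equal(attr(m, "threshold"), 100)
  # boundary is exclusive: a pixel at the threshold is not air
  px[2, 2] <- 100
  m2 <- threshold_air(cross_section(px), method = "fixed", fixed_value = 100)
  expect_false(m2[2, 2])
})

test_that("otsu fails explicitly on a constant image", {
  img <- cross_section(matrix(0.5, 64, 64))
  expect_error(threshold_air(img, method = "otsu"), "constant image")
})

test_that("an all-water synthetic slice thresholds to an empty xylem mask", {
  cfg <- small_config(seed = 3, frac_vessels_embolized = 0,
                      frac_fibers_airfilled = 0)
  gen <- generate_cross_section(cfg)
  g <- cfg$gray_levels
  m <- threshold_air(gen$section, method = "fixed",
                     fixed_value = (g$air + g$water) / 2)
  expect_equal(sum(m & gen$truth$xylem_mask), 0)
})

test_that("otsu on a noise-free synthetic slice reproduces the truth exactly", {
  cfg <- small_config(seed = 9, frac_vessels_embolized = 0.08,
                      frac_fibers_airfilled = 0.04, noise_sd = 0)
  gen <- generate_cross_section(cfg)
  tr <- gen$truth
  m <- threshold_air(gen$section, method = "otsu")
  emb <- tr$vessel_label_map > 0 &
    matrix(tr$vessel_label_map %in% tr$embolized_vessel_ids, 192, 192)
  expect_identical(m & tr$xylem_mask, emb | tr$airfilled_fiber_mask)
})

test_that("polygon geometry matches an independent point-in-polygon oracle", {
  n <- 256
  pith_poly <- circle_polygon(127.5, 127.5, 20)
  outer_poly <- circle_polygon(127.5, 127.5, 100)
  img <- cross_section(matrix(runif(n * n), n, n))
  geo <- delineate_geometry(img, mode = "polygons",
                            pith_polygon = pith_poly,
                            outer_polygon = outer_poly)
  # oracle: mgcv::in.out on every pixel centre
  g <- expand.grid(r = seq_len(n) - 1, c = seq_len(n) - 1)
  inn <- mgcv::in.out(rbind(pith_poly, pith_poly[1, ]), cbind(g$r, g$c))
  out <- mgcv::in.out(rbind(outer_poly, outer_poly[1, ]), cbind(g$r, g$c))
  expect_equal(geo$xylem_area_px, sum(out & !inn))
  expect_equal(sum(geo$pith_mask), sum(inn))
})

test_that("degenerate or invalid polygons are rejected", {
  img <- cross_section(matrix(runif(128 * 128), 128, 128))
  poly <- circle_polygon(63.5, 63.5, 30)
  expect_error(
    delineate_geometry(img, mode = "polygons", pith_polygon = poly,
                       outer_polygon = poly),
    "strictly inside")
  bowtie <- cbind(c(10, 40, 10, 40), c(10, 40, 40, 10))
  expect_error(
    delineate_geometry(img, mode = "polygons", pith_polygon = bowtie,
                       outer_polygon = circle_polygon(63.5, 63.5, 50)),
    "self-intersecting")
  expect_error(
    delineate_geometry(img, mode = "polygons", pith_polygon = poly,
                       outer_polygon = circle_polygon(63.5, 63.5, 200)),
    "outside the image")
})

test_that("auto geometry recovers the generated annulus within 1%", {
  gen <- generate_cross_section(small_config(
    seed = 13, frac_vessels_embolized = 0.08, frac_fibers_airfilled = 0.03))
  geo <- delineate_geometry(gen$section, mode = "auto")
  expect_lt(abs(geo$xylem_area_px - sum(gen$truth$xylem_mask)) /
              sum(gen$truth$xylem_mask), 0.01)
})

test_that("vessel detection matches a flood-fill oracle and filters size", {
  n <- 64
  mask <- disk_mask(n, 20, 20, 8) | disk_mask(n, 45, 40, 8)
  mask[5, 60] <- TRUE  # 1-px speck
  geo <- xylemCT:::new_xylem_geometry(
    matrix(FALSE, n, n), matrix(TRUE, n, n))
  vs <- detect_vessels(mask, geo, min_area_px = 50, min_circularity = 0,
                       max_circularity = 2)
  expect_equal(nrow(vs$vessels), 2)
  oracle_areas <- sort(brute_flood_areas(mask), decreasing = TRUE)[1:2]
  expect_equal(sort(vs$vessels$area_px, decreasing = TRUE), oracle_areas)
  # empty mask is a valid input
  vs0 <- detect_vessels(matrix(FALSE, n, n), geo)
  expect_equal(nrow(vs0$vessels), 0)
  expect_equal(vs0$total_embolized_vessel_area_px, 0)
})

test_that("vessel detection on a noise-free preset recovers truth pixel sets exactly", {
  gen <- generate_cross_section(small_config(
    seed = 17, frac_vessels_embolized = 0.08, frac_fibers_airfilled = 0.04,
    noise_sd = 0))
  tr <- gen$truth
  geo <- xylemCT:::new_xylem_geometry(tr$pith_mask, tr$xylem_mask)
  air <- threshold_air(gen$section, method = "otsu")
  vs <- detect_vessels(air, geo, min_area_px = 50)
  emb <- tr$vessel_label_map > 0 &
    matrix(tr$vessel_label_map %in% tr$embolized_vessel_ids, 192, 192)
  expect_equal(nrow(vs$vessels), length(tr$embolized_vessel_ids))
  expect_identical(vs$label_map > 0, emb)
})

test_that("vessel detection is idempotent on its own output", {
  gen <- generate_cross_section(small_config(
    seed = 19, frac_vessels_embolized = 0.08, noise_sd = 0))
  tr <- gen$truth
  geo <- xylemCT:::new_xylem_geometry(tr$pith_mask, tr$xylem_mask)
  air <- threshold_air(gen$section, method = "otsu")
  vs <- detect_vessels(air, geo, min_area_px = 50)
  vs2 <- detect_vessels(vs$label_map > 0, geo, min_area_px = 50)
  expect_equal(vs2$vessels, vs$vessels)
  expect_identical(vs2$label_map, vs$label_map)
})

test_that("contour perimeter agrees with the analytic circle within 10%", {
  for (r in c(8, 12, 16, 20)) {
    n <- 2 * r + 11
    m <- disk_mask(n, r + 6, r + 6, r)
    geo <- xylemCT:::new_xylem_geometry(matrix(FALSE, n, n),
                                        matrix(TRUE, n, n))
    vs <- detect_vessels(m, geo, min_area_px = 1, min_circularity = 0,
                         max_circularity = 2)
    expect_lt(abs(vs$vessels$perimeter_px - 2 * pi * r) / (2 * pi * r), 0.10)
    expect_lt(abs(vs$vessels$circularity - 1), 0.15)
  }
})

test_that("manual edits: identity, exclusion, polygon inclusion and overlap", {
  n <- 96
  mask <- disk_mask(n, 30, 30, 8)
  geo <- xylemCT:::new_xylem_geometry(matrix(FALSE, n, n), matrix(TRUE, n, n))
  vs <- detect_vessels(mask, geo, min_area_px = 10)
  expect_equal(apply_manual_edits(vs, geometry = geo)$vessels, vs$vessels)
  vs0 <- apply_manual_edits(vs, exclude_ids = 1L, geometry = geo)
  expect_equal(nrow(vs0$vessels), 0)
  expect_equal(vs0$total_embolized_vessel_area_px, 0)
  # 5x5-pixel square polygon: area 25 by the pixel-centre rule, polygon
  # perimeter 20, circularity 4*pi*25/400
  sq <- cbind(c(59.5, 64.5, 64.5, 59.5), c(59.5, 59.5, 64.5, 64.5))
  vs1 <- apply_manual_edits(vs, include_polygons = list(sq), geometry = geo)
  new <- vs1$vessels[nrow(vs1$vessels), ]
  expect_equal(new$area_px, 25)
  expect_equal(new$perimeter_px, 20)
  expect_equal(new$circularity, 4 * pi * 25 / 400)
  # overlapping inclusion must fail
  over <- cbind(c(25.5, 33.5, 33.5, 25.5), c(25.5, 25.5, 33.5, 33.5))
  expect_error(apply_manual_edits(vs, include_polygons = list(over),
                                  geometry = geo), "overlaps")
  expect_error(apply_manual_edits(vs, exclude_ids = 99L, geometry = geo),
               "subset")
})

test_that("fiber mask is the air mask minus vessels, with optional speck removal", {
  n <- 96
  geo <- annulus_geometry(n, 10, 45)
  air <- disk_mask(n, 25, 48, 6) | disk_mask(n, 70, 48, 4)
  air[15, 48] <- TRUE  # lone speck inside the xylem
  air <- air & geo$xylem_mask
  vs <- detect_vessels(air, geo, min_area_px = 80)  # keeps only the r=6 disk
  fib <- derive_fiber_mask(air, vs, geo)
  expect_equal(fib$area_px, sum(air) - vs$total_embolized_vessel_area_px)
  expect_equal(sum(fib$mask & (vs$label_map > 0)), 0)
  # full subtraction leaves nothing
  fib0 <- derive_fiber_mask(vs$label_map > 0, vs, geo)
  expect_equal(fib0$area_px, 0)
  # speck filtering
  fib2 <- derive_fiber_mask(air, vs, geo, min_speck_px = 5)
  expect_equal(fib2$area_px, fib$area_px - 1)
})
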