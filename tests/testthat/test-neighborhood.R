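test_that("enlarge_region identity, disk growth and nesting", {
  m <- matrix(FALSE, 64, 64)
  m[32, 32] <- TRUE
  expect_identical(enlarge_region(m, 0), m)
  # single pixel, x = 2: all offsets with di^2 + dj^2 <= 4 -> 13 pixels
  e2 <- enlarge_region(m, 2)
  expect_equal(sum(e2), 13)
  expect_identical(e2, brute_edt_sq(m) <= 4)
  # metric monotonicity
  prev <- e2
  for (x in c(5, 10, 15)) {
    cur <- enlarge_region(m, x)
    expect_true(all(cur[prev]))
    prev <- cur
  }
  # empty region warns and returns empty
  expect_warning(e0 <- enlarge_region(matrix(FALSE, 8, 8), 3), "empty")
  expect_equal(sum(e0), 0)
})

test_that("enlargement equals brute-force distance computation on small fixtures", {
  set.seed(8)
  for (rep in 1:5) {
    m <- matrix(runif(96 * 96) < 0.01, 96, 96)
    if (!any(m)) m[50, 50] <- TRUE
    for (x in c(3, 10, 25)) {
      expect_identical(enlarge_region(m, x), brute_edt_sq(m) <= x^2)
    }
  }
})

test_that("fiber association classifies distances exactly and is monotone in x", {
  n <- 64
  geo <- xylemCT:::new_xylem_geometry(matrix(FALSE, n, n), matrix(TRUE, n, n))
  vmask <- disk_mask(n, 32, 32, 5)
  vs <- detect_vessels(vmask, geo, min_area_px = 10, min_circularity = 0,
                       max_circularity = 2)
  # fiber pixels at Euclidean distances 5 and 12 from the vessel boundary
  fib <- matrix(FALSE, n, n)
  fib[32, 32 + 5 + 5] <- TRUE   # 5 px beyond the lumen edge
  fib[32 + 5 + 12, 32] <- TRUE  # 12 px beyond
  fibers <- structure(list(mask = fib, area_px = sum(fib)),
                      class = "fiber_mask")
  fa <- fiber_association(vs, fibers, geo, x_list = c(10, 15, 20, 25))
  r10 <- fa$records[fa$records$enlargement_px == 10, ]
  expect_equal(r10$intersect_fiber_area_px, 1)  # only the distance-5 pixel
  expect_true(r10$has_fibers)
  # brute-force check of the x = 10 intersection
  d2 <- brute_edt_sq(vmask)
  expect_equal(sum(fib & (d2 <= 100) & !vmask), 1)
  # nondecreasing intersect over x
  per_x <- fa$records$intersect_fiber_area_px[order(fa$records$enlargement_px)]
  expect_true(all(diff(per_x) >= 0))
  # enlarged area excludes the vessel's own pixels, ratio in [0, 1]
  expect_true(all(fa$records$fiber_area_ratio >= 0 &
                    fa$records$fiber_area_ratio <= 1))
  expect_true(all(fa$records$intersect_fiber_area_px <=
                    fa$records$enlarged_area_px))
})

test_that("an empty fiber mask yields all-NO associations", {
  n <- 64
  geo <- xylemCT:::new_xylem_geometry(matrix(FALSE, n, n), matrix(TRUE, n, n))
  vs <- detect_vessels(disk_mask(n, 20, 20, 5) | disk_mask(n, 45, 45, 5),
                       geo, min_area_px = 10, min_circularity = 0,
                       max_circularity = 2)
  fibers <- structure(list(mask = matrix(FALSE, n, n), area_px = 0L),
                      class = "fiber_mask")
  fa <- fiber_association(vs, fibers, geo)
  expect_true(all(!fa$records$has_fibers))
  expect_true(all(fa$records$fiber_area_ratio == 0))
  expect_true(all(fa$summaries$pct_yes == 0))
  expect_equal(fa$summaries$n_yes + fa$summaries$n_no,
               rep(nrow(vs$vessels), 4))
})

test_that("removing fiber-free vessels raises the YES percentage of the rest", {
  n <- 96
  geo <- xylemCT:::new_xylem_geometry(matrix(FALSE, n, n), matrix(TRUE, n, n))
  vmask <- disk_mask(n, 25, 25, 5) | disk_mask(n, 70, 70, 5) |
    disk_mask(n, 25, 70, 5)
  vs <- detect_vessels(vmask, geo, min_area_px = 10, min_circularity = 0,
                       max_circularity = 2)
  fib <- matrix(FALSE, n, n)
  fib[25, 33] <- TRUE  # close to the first vessel only
  fibers <- structure(list(mask = fib, area_px = 1L), class = "fiber_mask")
  fa <- fiber_association(vs, fibers, geo, x_list = 10)
  before <- fa$summaries$pct_yes
  keep <- fa$records$vessel_id[fa$records$has_fibers]
  vs2 <- apply_manual_edits(
    vs, exclude_ids = setdiff(vs$vessels$vessel_id, keep), geometry = geo)
  fa2 <- fiber_association(vs2, fibers, geo, x_list = 10)
  expect_gt(fa2$summaries$pct_yes, before)
})

test_that("association on generator output is consistent across enlargements", {
  gen <- generate_cross_section(small_config(
    seed = 37, frac_vessels_embolized = 0.08, frac_fibers_airfilled = 0.05))
  res <- list(
    geo = xylemCT:::new_xylem_geometry(gen$truth$pith_mask,
                                       gen$truth$xylem_mask))
  air <- threshold_air(gen$section, method = "otsu")
  vs <- detect_vessels(air, res$geo, min_area_px = 50)
  fib <- derive_fiber_mask(air, vs, res$geo)
  fa <- fiber_association(vs, fib, res$geo, sample_id = "t")
  for (v in unique(fa$records$vessel_id)) {
    r <- fa$records[fa$records$vessel_id == v, ]
    r <- r[order(r$enlargement_px), ]
    expect_true(all(diff(r$intersect_fiber_area_px) >= 0))
    expect_true(all(diff(r$enlarged_area_px) >= 0))
  }
  expect_true(all(diff(fa$summaries$pct_yes[order(fa$summaries$enlargement_px)]) >= 0))
})
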