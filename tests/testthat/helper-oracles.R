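# Brute-force oracles and small fixtures shared across the suite.
# Oracles are deliberately naive (per-pixel loops) and independent of the
# package's distance-transform / labeling / rasterisation code paths.

# squared Euclidean distance to the nearest TRUE pixel, by exhaustive search
brute_edt_sq <- function(seed) {
  idx <- which(seed, arr.ind = TRUE)
  out <- matrix(Inf, nrow(seed), ncol(seed))
  if (nrow(idx) == 0) return(out)
  for (i in seq_len(nrow(seed))) {
    for (j in seq_len(ncol(seed))) {
      out[i, j] <- min((idx[, 1] - i)^2 + (idx[, 2] - j)^2)
    }
  }
  out
}

# component areas by naive stack-based flood fill (8-connectivity)
brute_flood_areas <- function(mask) {
  visited <- matrix(FALSE, nrow(mask), ncol(mask))
  areas <- integer(0)
  for (i0 in seq_len(nrow(mask))) {
    for (j0 in seq_len(ncol(mask))) {
      if (!mask[i0, j0] || visited[i0, j0]) next
      stack <- list(c(i0, j0))
      visited[i0, j0] <- TRUE
      a <- 0L
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        a <- a + 1L
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1] + di; jj <- p[2] + dj
          if (ii >= 1 && jj >= 1 && ii <= nrow(mask) && jj <= ncol(mask) &&
              mask[ii, jj] && !visited[ii, jj]) {
            visited[ii, jj] <- TRUE
            stack[[length(stack) + 1]] <- c(ii, jj)
          }
        }
      }
      areas <- c(areas, a)
    }
  }
  areas
}

# disk mask on an n x n grid, pixel-centre rule, 1-based centre coordinates
disk_mask <- function(n, cy, cx, r) {
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  m <- matrix(FALSE, n, n)
  m[cbind(g$i, g$j)] <- (g$i - cy)^2 + (g$j - cx)^2 <= r^2
  m
}

# annulus geometry fixture: pith disk of radius r_in, xylem up to r_out
annulus_geometry <- function(n, r_in, r_out) {
  ctr <- (n + 1) / 2
  pith <- disk_mask(n, ctr, ctr, r_in)
  stem <- disk_mask(n, ctr, ctr, r_out)
  xylemCT:::new_xylem_geometry(pith, stem & !pith)
}

# fast small-scale generator configuration for property sweeps
small_config <- function(seed = 1L, ...) {
  synth_config(
    image_size_px = 192L, pith_radius_px = 20, xylem_outer_radius_px = 85,
    vessel_count = 10L, vessel_radius_px_range = c(8, 13),
    fiber_cell_pitch_px = 6, fiber_lumen_radius_px = 2,
    ray_count = 8L, fiber_patch_size = 6L,
    seed = seed, ...
  )
}

# regular polygon approximating a circle, 0-based (row, col) vertices
circle_polygon <- function(cy, cx, r, nv = 72) {
  th <- seq(0, 2 * pi, length.out = nv + 1)[-(nv + 1)]
  cbind(cy + r * sin(th), cx + r * cos(th))
}
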