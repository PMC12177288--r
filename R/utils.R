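# small shared helpers: validation, hashing, mask utilities

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_xct <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

assert_that <- function(cond, stage, msg) {
  if (!isTRUE(cond)) stop_xct(stage, msg)
  invisible(TRUE)
}

as_mask <- function(x, stage = "mask") {
  if (is.logical(x) && is.matrix(x)) return(x)
  if (is.numeric(x) && is.matrix(x)) return(x != 0)
  stop_xct(stage, "expected a logical (or numeric 0/1) matrix")
}

mask_area <- function(m) sum(m)

#' Deterministic configuration hash
#'
#' FNV-1a hash of the canonical deparse of a configuration list, used to stamp
#' output files so that any result can be traced back to the exact parameter
#' set that produced it.
#'
#' @param x an R object (typically a config list).
#' @return an 8-character hexadecimal string.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(unlist(x, use.names = TRUE)), collapse = ";")
  bytes <- utf8ToInt(s)
  # simple 31-bit polynomial rolling hash, kept exact in double precision
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# pixel-centre point-in-polygon (even-odd rule), vectorised over points.
# polygon: matrix with columns (row, col), 0-based or 1-based consistently
# with the query points.
points_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    yi <- vr[i]; yj <- vr[j]
    xi <- vc[i]; xj <- vc[j]
    crosses <- ((yi > pr) != (yj > pr)) &
      (pc < (xj - xi) * (pr - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_perimeter <- function(vr, vc) {
  n <- length(vr)
  j <- c(n, seq_len(n - 1))
  sum(sqrt((vr - vr[j])^2 + (vc - vc[j])^2))
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_self_intersects <- function(vr, vc) {
  n <- length(vr)
  if (n < 4) return(FALSE)
  segs <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      # skip adjacent segments (share a vertex)
      if (abs(a - b) <= 1 || (a == 1 && b == n)) next
      if (segments_intersect(
        c(vr[segs[a, 1]], vc[segs[a, 1]]), c(vr[segs[a, 2]], vc[segs[a, 2]]),
        c(vr[segs[b, 1]], vc[segs[b, 1]]), c(vr[segs[b, 2]], vc[segs[b, 2]])
      )) return(TRUE)
    }
  }
  FALSE
}

# rasterise a polygon (vertices in 0-based (row, col) pixel coordinates) onto
# an nr x nc grid using the pixel-centre-in-polygon rule
rasterize_polygon <- function(poly, nr, nc) {
  vr <- poly[, 1]; vc <- poly[, 2]
  out <- matrix(FALSE, nr, nc)
  r0 <- max(1L, floor(min(vr)) + 1L); r1 <- min(nr, ceiling(max(vr)) + 1L)
  c0 <- max(1L, floor(min(vc)) + 1L); c1 <- min(nc, ceiling(max(vc)) + 1L)
  if (r0 > r1 || c0 > c1) return(out)
  grid <- expand.grid(r = r0:r1, c = c0:c1)
  # pixel (i, j) in 1-based matrix indexing has centre (i-1, j-1) in 0-based
  inside <- points_in_polygon(grid$r - 1, grid$c - 1, vr, vc)
  out[cbind(grid$r, grid$c)] <- inside
  out
}

# bounding box (1-based index ranges) of a mask, optionally padded
mask_bbox <- function(m, pad = 0L) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  list(
    r = c(max(1L, min(idx[, 1]) - pad), min(nrow(m), max(idx[, 1]) + pad)),
    c = c(max(1L, min(idx[, 2]) - pad), min(ncol(m), max(idx[, 2]) + pad))
  )
}
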