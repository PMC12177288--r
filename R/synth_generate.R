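# Synthetic cross-section generator: geometry, component placement, rendering.

# pixels of a disk with continuous centre (cy, cx) and radius r, clipped to
# an n x n grid; pixel-centre rule ((i - cy)^2 + (j - cx)^2 <= r^2)
disk_pixels <- function(cy, cx, r, n) {
  i0 <- max(1L, floor(cy - r)); i1 <- min(n, ceiling(cy + r))
  j0 <- max(1L, floor(cx - r)); j1 <- min(n, ceiling(cx + r))
  ii <- i0:i1; jj <- j0:j1
  g <- expand.grid(i = ii, j = jj)
  keep <- (g$i - cy)^2 + (g$j - cx)^2 <= r^2
  cbind(g$i[keep], g$j[keep])
}

# random greedy subset whose total area approaches `target` from candidate
# rows; returns integer row indices into `cand`
greedy_budget <- function(cand, target, reach = FALSE) {
  if (target <= 0 || nrow(cand) == 0) return(integer(0))
  ord <- sample.int(nrow(cand))
  tot <- 0
  sel <- integer(0)
  for (k in ord) {
    if (tot >= target) break
    new_tot <- tot + cand$area_px[k]
    # closeness rule: take the candidate only if it moves the total closer
    if (abs(new_tot - target) <= abs(tot - target)) {
      sel <- c(sel, k)
      tot <- new_tot
    } else break
  }
  while (reach && tot < target) {
    # the target must be met or exceeded: top up with the smallest
    # remaining lumen that covers the gap (overshoot below one lumen)
    rem <- setdiff(seq_len(nrow(cand)), sel)
    if (length(rem) == 0) break
    gap <- target - tot
    fits <- rem[cand$area_px[rem] >= gap]
    k <- if (length(fits) > 0) {
      fits[which.min(cand$area_px[fits])]
    } else {
      rem[which.max(cand$area_px[rem])]
    }
    sel <- c(sel, k)
    tot <- tot + cand$area_px[k]
  }
  sel
}

# deterministic best-fit subset: repeatedly add the candidate that brings
# the running total closest to the target, while it improves; used for the
# small outer share where whole-lumen quantisation dominates
greedy_bestfit <- function(cand, target) {
  sel <- integer(0)
  tot <- 0
  avail <- seq_len(nrow(cand))
  while (length(avail) > 0 && tot < target) {
    k <- avail[which.min(abs(tot + cand$area_px[avail] - target))]
    if (abs(tot + cand$area_px[k] - target) > abs(tot - target)) break
    sel <- c(sel, k)
    tot <- tot + cand$area_px[k]
    avail <- setdiff(avail, k)
  }
  sel
}

#' Radially targeted component placement
#'
#' Selects whole lumina (vessels or fiber cells) so that the placed
#' component's radial 95% cumulative-area threshold lands at a requested
#' percent of covered xylem area. With a numeric target `T`, 95% of the area
#' budget is drawn with uniform spatial density from candidates whose
#' covered-area coordinate is at most `T` and the remaining 5% from
#' candidates beyond `T`, so the cumulative area curve crosses 95% at `T`
#' (up to whole-lumen quantisation and the radial step width). With
#' `"uniform"`, candidates are drawn with homogeneous density everywhere.
#'
#' @param budget_px target component area, pixels.
#' @param radial_target `"uniform"` or percent of covered xylem area in
#'   `(0, 100]` at which the cumulative component area should reach 95%.
#' @param candidates data frame with columns `id`, `area_px` and
#'   `covered_pct` (the candidate's position expressed as percent of covered
#'   xylem area, pith outward).
#' @param inner_mass fraction of the budget placed inside the target
#'   coordinate (default 0.95, matching the 95% threshold definition).
#' @return data frame of selected candidate rows; attribute `achieved_px`
#'   holds the total selected area.
#' @export
place_component_radial <- function(budget_px, radial_target, candidates,
                                   inner_mass = 0.95) {
  st <- "place_component_radial"
  assert_that(all(c("id", "area_px", "covered_pct") %in% names(candidates)),
              st, "candidates must have columns id, area_px, covered_pct")
  avail <- sum(candidates$area_px)
  assert_that(budget_px <= avail, st, sprintf(
    "budget (%d px) exceeds available lumen area (%d px)",
    round(budget_px), round(avail)))
  if (budget_px <= 0) {
    out <- candidates[0, ]
    attr(out, "achieved_px") <- 0
    return(out)
  }
  if (identical(radial_target, "uniform")) {
    sel <- greedy_budget(candidates, budget_px)
  } else {
    assert_that(is.numeric(radial_target) && radial_target > 0 &&
                  radial_target <= 100, st,
                "radial_target must be 'uniform' or in (0, 100]")
    inner <- which(candidates$covered_pct <= radial_target)
    outer <- which(candidates$covered_pct > radial_target)
    need_in <- inner_mass * budget_px
    need_out <- budget_px - need_in
    # if there is not enough lumen area beyond the target, fold the
    # remainder inward (the threshold is still reached within the target)
    avail_out <- sum(candidates$area_px[outer])
    if (avail_out < need_out) {
      need_in <- budget_px - avail_out
      need_out <- avail_out
    }
    if (sum(candidates$area_px[inner]) < need_in) {
      stop_xct(st, sprintf(
        paste0("unreachable radial target: %.1f%% of covered xylem area ",
               "holds only %d px of candidate lumen area but %d px are ",
               "required inside the target"),
        radial_target, round(sum(candidates$area_px[inner])), round(need_in)))
    }
    # the inner share must REACH 95% of the budget, otherwise the cumulative
    # curve crosses 95% beyond the target; the outer share absorbs the rest
    sel_in <- inner[greedy_budget(candidates[inner, , drop = FALSE], need_in,
                                  reach = TRUE)]
    got_in <- sum(candidates$area_px[sel_in])
    sel_out <- outer[greedy_bestfit(candidates[outer, , drop = FALSE],
                                    max(0, budget_px - got_in))]
    sel <- c(sel_in, sel_out)
  }
  out <- candidates[sel, , drop = FALSE]
  attr(out, "achieved_px") <- sum(out$area_px)
  out
}

# contiguous-patch selection of fiber lumina honouring a radial law; patches
# grow among candidates on the same side of the radial target as their seed,
# so clustering does not blur the placed cumulative curve across the target
select_fiber_lumina <- function(cand, budget_px, radial_target, patch_size,
                                mode, inner_mass = 0.95) {
  if (budget_px <= 0 || nrow(cand) == 0) return(integer(0))
  if (mode == "random") {
    sel <- place_component_radial(budget_px, radial_target, cand, inner_mass)
    return(match(sel$id, cand$id))
  }
  uniform <- identical(radial_target, "uniform")
  if (!uniform) {
    inner_avail <- sum(cand$area_px[cand$covered_pct <= radial_target])
    if (inner_avail < inner_mass * budget_px) {
      stop_xct("place_component_radial", sprintf(
        "unreachable radial target %.1f%% for fiber patches", radial_target))
    }
  }
  remaining <- rep(TRUE, nrow(cand))
  sel <- integer(0)
  tot <- 0
  tot_in <- 0
  guard <- 0
  while (tot < budget_px && any(remaining) && guard < 1e5) {
    guard <- guard + 1
    if (uniform) {
      pool <- which(remaining)
    } else {
      want_inner <- tot_in < inner_mass * (tot + patch_size * mean(cand$area_px))
      pool <- if (want_inner) {
        which(remaining & cand$covered_pct <= radial_target)
      } else {
        which(remaining & cand$covered_pct > radial_target)
      }
      if (length(pool) == 0) pool <- which(remaining)
    }
    seed_k <- pool[sample.int(length(pool), 1L)]
    d2 <- (cand$cy[pool] - cand$cy[seed_k])^2 +
      (cand$cx[pool] - cand$cx[seed_k])^2
    patch <- pool[order(d2)][seq_len(min(patch_size, length(pool)))]
    added <- FALSE
    for (k in patch) {
      if (tot >= budget_px) break
      new_tot <- tot + cand$area_px[k]
      # stop when adding another lumen would move away from the budget
      if (abs(new_tot - budget_px) > abs(tot - budget_px)) break
      sel <- c(sel, k)
      tot <- new_tot
      added <- TRUE
      if (!uniform && cand$covered_pct[k] <= radial_target) {
        tot_in <- tot_in + cand$area_px[k]
      }
      remaining[k] <- FALSE
    }
    if (!added) break  # every remaining lumen would overshoot the budget
  }
  sel
}

#' Generate a synthetic stem cross-section with ground truth
#'
#' Renders a poplar-like diffuse-porous stem cross-section (pith, xylem
#' annulus, vessels, fiber lattice, parenchyma rays) at the configured gray
#' levels and noise, together with the complete ground truth: vessel label
#' map, embolized vessel ids, air-filled fiber mask, pith/xylem masks, the
#' true percent-embolized-area values and the true radial 95% thresholds.
#' Generation is bit-deterministic for a fixed configuration (seed included).
#'
#' @param config a [synth_config()].
#' @return list with elements `section` (a `cross_section`) and `truth`
#'   (a `ground_truth`).
#' @export
generate_cross_section <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  n <- config$image_size_px
  ctr <- (n + 1) / 2
  g <- config$gray_levels
  ring_px <- 3  # solid outer band (cambium side), keeps the outer contour crisp

  dr <- (seq_len(n) - ctr)
  rsq <- outer(dr^2, dr^2, "+")
  rdist <- sqrt(rsq)
  pith <- rsq <= config$pith_radius_px^2
  stem <- rsq <= config$xylem_outer_radius_px^2
  xylem <- stem & !pith
  xylem_area <- sum(xylem)

  # radial coordinate: percent of covered xylem area within distance d of the
  # pith; distances via the exact EDT seeded on the pith mask
  dmap <- sqrt(edt_sq(pith))
  dx_sorted <- sort(dmap[xylem])
  covered_pct <- function(d) {
    100 * findInterval(d, dx_sorted) / xylem_area
  }
  # The measured threshold is quantised to the radial step grid, so a
  # requested target is snapped to the closest achievable covered fraction:
  # the grid distance nearest the target's quantile distance. Candidates are
  # then classified by their outermost pixel so that the inner 95% of the
  # component area really lies within the snapped distance.
  step_px_default <- 10
  snap_target <- function(target) {
    if (identical(target, "uniform")) return("uniform")
    dT <- dx_sorted[max(1L, ceiling(target / 100 * length(dx_sorted)))]
    dstar <- max(step_px_default, round(dT / step_px_default) * step_px_default)
    100 * findInterval(dstar, dx_sorted) / xylem_area
  }

  # --- vessels: rejection-sampled non-overlapping disks, >= 2 px clearance
  rv_range <- config$vessel_radius_px_range
  vcy <- vcx <- vr <- numeric(0)
  fails <- 0L
  while (length(vr) < config$vessel_count) {
    r <- runif(1, rv_range[1], rv_range[2])
    dmin <- config$pith_radius_px + r + 3
    dmax <- config$xylem_outer_radius_px - ring_px - r - 1
    if (dmin >= dmax) {
      stop_xct("generate_cross_section",
               "infeasible packing: vessel radius does not fit in the annulus")
    }
    rad <- sqrt(runif(1, dmin^2, dmax^2))
    ang <- runif(1, 0, 2 * pi)
    cy <- ctr + rad * sin(ang)
    cx <- ctr + rad * cos(ang)
    ok <- TRUE
    if (length(vr) > 0) {
      ok <- all(sqrt((vcy - cy)^2 + (vcx - cx)^2) > vr + r + 2)
    }
    if (ok) {
      vcy <- c(vcy, cy); vcx <- c(vcx, cx); vr <- c(vr, r)
    } else {
      fails <- fails + 1L
      if (fails > 10000L) {
        stop_xct("generate_cross_section", sprintf(
          paste0("infeasible packing: could not place %d non-overlapping ",
                 "vessels with >= 2 px clearance after 10000 retries"),
          config$vessel_count))
      }
    }
  }

  vessel_label_map <- matrix(0L, n, n)
  vessel_area <- integer(length(vr))
  for (v in seq_along(vr)) {
    px <- disk_pixels(vcy[v], vcx[v], vr[v], n)
    vessel_label_map[px] <- v
    vessel_area[v] <- nrow(px)
  }

  # --- parenchyma rays: thin water-filled radial bands, no fiber lattice
  theta <- atan2(outer(dr, rep(1, n)), outer(rep(1, n), dr))
  ray_angles <- (seq_len(config$ray_count) - 1) * 2 * pi / config$ray_count +
    runif(1, 0, 2 * pi)
  ray_mask <- matrix(FALSE, n, n)
  half_w <- config$ray_width_px / 2
  for (a in ray_angles) {
    da <- theta - a
    perp <- abs(sin(da)) * rdist
    ray_mask <- ray_mask | (perp <= half_w & cos(da) > 0)
  }
  ray_mask <- ray_mask & xylem & (vessel_label_map == 0L)

  # --- fiber lattice: hexagonal grid of small lumina between the vessels
  pitch <- config$fiber_cell_pitch_px
  lr <- config$fiber_lumen_radius_px
  dy <- pitch * sqrt(3) / 2
  ys <- seq(ctr - config$xylem_outer_radius_px,
            ctr + config$xylem_outer_radius_px, by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(k) {
    x0 <- ctr - config$xylem_outer_radius_px + (k %% 2) * pitch / 2
    xs <- seq(x0, ctr + config$xylem_outer_radius_px, by = pitch)
    cbind(ys[k], xs)
  }))
  cdist <- sqrt((pts[, 1] - ctr)^2 + (pts[, 2] - ctr)^2)
  keep <- cdist >= config$pith_radius_px + lr + 2 &
    cdist <= config$xylem_outer_radius_px - ring_px - lr - 1
  pts <- pts[keep, , drop = FALSE]
  cdist <- cdist[keep]
  if (length(vr) > 0) {
    dv <- sqrt(outer(pts[, 1], vcy, "-")^2 + outer(pts[, 2], vcx, "-")^2)
    clear <- sweep(dv, 2, vr + lr + 2.5, ">")
    keep <- rowSums(clear) == length(vr)
    pts <- pts[keep, , drop = FALSE]
    cdist <- cdist[keep]
  }
  # keep lumina off the rays
  pa <- atan2(pts[, 1] - ctr, pts[, 2] - ctr)
  on_ray <- rep(FALSE, nrow(pts))
  for (a in ray_angles) {
    da <- pa - a
    on_ray <- on_ray | (abs(sin(da)) * cdist <= half_w + lr + 1 & cos(da) > 0)
  }
  pts <- pts[!on_ray, , drop = FALSE]
  cdist <- cdist[!on_ray]

  lumen_px <- vector("list", nrow(pts))
  lumen_area <- integer(nrow(pts))
  for (k in seq_len(nrow(pts))) {
    px <- disk_pixels(pts[k, 1], pts[k, 2], lr, n)
    lumen_px[[k]] <- px
    lumen_area[k] <- nrow(px)
  }

  # --- embolized vessel selection (whole lumina, radially targeted)
  # Vessels are classified by their centre coordinate: lumina span several
  # radial steps, and the outward spill of a centre-classified selection
  # means the measured crossing quantises up to the next step grid value.
  # Pulling the selection target back by half a step centres that upward
  # quantisation on the requested value.
  shift_half_step <- function(target) {
    if (identical(target, "uniform")) return("uniform")
    dT <- dx_sorted[max(1L, ceiling(target / 100 * length(dx_sorted)))]
    100 * findInterval(max(1, dT - step_px_default / 2), dx_sorted) / xylem_area
  }
  vessel_cand <- data.frame(
    id = seq_along(vr),
    area_px = vessel_area,
    covered_pct = covered_pct(pmax(0, sqrt((vcy - ctr)^2 + (vcx - ctr)^2) -
                                     config$pith_radius_px)),
    stringsAsFactors = FALSE
  )
  budget_v <- config$frac_vessels_embolized * xylem_area
  emb_sel <- place_component_radial(budget_v,
                                    shift_half_step(config$radial_target_vessels),
                                    vessel_cand)
  embolized_ids <- sort(emb_sel$id)

  # --- air-filled fiber selection
  fiber_cand <- data.frame(
    id = seq_len(nrow(pts)),
    area_px = lumen_area,
    covered_pct = covered_pct(pmax(0, cdist - config$pith_radius_px) + lr + 0.5),
    cy = pts[, 1], cx = pts[, 2],
    stringsAsFactors = FALSE
  )
  budget_f <- config$frac_fibers_airfilled * xylem_area
  target_f <- snap_target(config$radial_target_fibers)
  # patch clustering makes the placed mass lumpy; redraw (bounded) until the
  # lumen-level cumulative curve crosses 95% at the snapped step, keeping
  # the generator's own placement contract
  draw_fibers <- function() {
    select_fiber_lumina(fiber_cand, budget_f, target_f,
                        config$fiber_patch_size, config$fiber_fill_mode)
  }
  air_fibers <- draw_fibers()
  if (is.numeric(target_f) && length(air_fibers) > 0) {
    # exact pixel-level crossing of the candidate draw, using the same
    # distance map the radial profile will see
    crossing <- function(sel) {
      dd <- unlist(lapply(sel, function(k) dmap[lumen_px[[k]]]))
      step_k <- pmax(1, ceiling(dd / step_px_default))
      m <- tapply(rep(1L, length(step_k)), step_k, sum)
      ks <- as.integer(names(m))
      cum <- cumsum(as.numeric(m)) / length(dd)
      kc <- ks[which(cum >= 0.95)[1]]
      100 * findInterval(kc * step_px_default, dx_sorted) / xylem_area
    }
    for (try in seq_len(20)) {
      if (abs(crossing(air_fibers) - target_f) < 1e-6) break
      air_fibers <- draw_fibers()
    }
  }

  airfilled_fiber_mask <- matrix(FALSE, n, n)
  for (k in air_fibers) airfilled_fiber_mask[lumen_px[[k]]] <- TRUE

  # --- rendering
  img <- matrix(g$air, n, n)
  img[stem] <- g$wall
  img[pith] <- g$water
  img[ray_mask] <- g$water
  for (k in seq_len(nrow(pts))) {
    img[lumen_px[[k]]] <- if (k %in% air_fibers) g$air else g$water
  }
  img[vessel_label_map > 0L] <- g$water
  emb_mask <- vessel_label_map > 0L &
    matrix(vessel_label_map %in% embolized_ids, n, n)
  img[emb_mask] <- g$air
  if (config$noise_sd > 0) {
    img <- img + matrix(rnorm(n * n, 0, config$noise_sd), n, n)
  }
  if (config$edge_enhance) {
    blur <- EBImage::gblur(EBImage::Image(img), sigma = 2)
    img <- img + 0.4 * (img - as.matrix(blur))
  }
  img <- pmin(pmax(img, 0), 1)

  group <- attr(config, "group") %||% "unknown"
  preset <- attr(config, "preset") %||% "custom"
  section <- cross_section(img, pixel_size_um = config$pixel_size_um,
                           sample_id = sprintf("%s_seed%d", preset, config$seed),
                           group = group)

  geometry <- new_xylem_geometry(pith, xylem)
  emb_area <- sum(vessel_area[embolized_ids])
  fib_area <- sum(airfilled_fiber_mask)
  true_pa_v <- 100 * emb_area / xylem_area
  true_pa_f <- 100 * fib_area / xylem_area

  regions <- radial_increments(geometry, step_px = 10L)
  thr_v <- thr_f <- NA_real_
  if (emb_area > 0) {
    prof_v <- cumulative_profile(regions, emb_mask, geometry, "vessels")
    thr_v <- threshold95(prof_v)
  }
  if (fib_area > 0 && true_pa_f >= 0.5) {
    prof_f <- cumulative_profile(regions, airfilled_fiber_mask, geometry,
                                 "fibers")
    thr_f <- threshold95(prof_f)
  }

  truth <- structure(list(
    vessel_label_map = vessel_label_map,
    embolized_vessel_ids = embolized_ids,
    airfilled_fiber_mask = airfilled_fiber_mask,
    pith_mask = pith,
    xylem_mask = xylem,
    xylem_area_px = xylem_area,
    embolized_vessel_area_px = emb_area,
    airfilled_fiber_area_px = fib_area,
    true_pa_vess = true_pa_v,
    true_pa_fibers = true_pa_f,
    true_threshold95_vessels = thr_v,
    true_threshold95_fibers = thr_f,
    requested = list(pa_vess = 100 * config$frac_vessels_embolized,
                     pa_fibers = 100 * config$frac_fibers_airfilled),
    config = config
  ), class = "ground_truth")

  list(section = section, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", x$xylem_area_px, "xylem px;",
      length(x$embolized_vessel_ids), "embolized vessels\n")
  cat(sprintf("  true PA_vess = %.3f%%  true PA_fibers = %.3f%%\n",
              x$true_pa_vess, x$true_pa_fibers))
  cat(sprintf("  threshold95: vessels %s | fibers %s\n",
              format(x$true_threshold95_vessels),
              format(x$true_threshold95_fibers)))
  invisible(x)
}
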