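# Beam's-eye-view frame --------------------------------------------------
#
# Gantry angle g (degrees): at g = 0 the source is anterior and the beam
# travels posterior (-AP). The BEV u-axis (leaf travel) is
# e_u = (cos g, sin g, 0), the v-axis (leaf width) is SI, and the beam
# direction is e_b = (sin g, -cos g, 0). cospi/sinpi keep cardinal angles
# exact.
beam_frame <- function(gantry_deg) {
  cg <- cospi(gantry_deg / 180)
  sg <- sinpi(gantry_deg / 180)
  list(e_u = c(cg, sg, 0), e_v = c(0, 0, 1), e_b = c(sg, -cg, 0))
}

#' Project a patient displacement into the beam's-eye-view
#'
#' Orthographic projection (no divergence scaling): the component along the
#' beam axis is discarded, `u = d_LR cos(g) + d_AP sin(g)` lies along leaf
#' travel and `v = d_SI` along leaf width.
#'
#' @param d length-3 displacement (mm; LR, AP, SI).
#' @param gantry_deg gantry angle in degrees.
#' @return named numeric `c(u, v)` in mm.
#' @export
project_to_bev <- function(d, gantry_deg) {
  f <- beam_frame(gantry_deg)
  c(u = d[1] * f$e_u[1] + d[2] * f$e_u[2], v = d[3])
}

# Beamlet grid ------------------------------------------------------------

#' Beamlet grid for one beam
#'
#' Rectangular BEV fluence grid: u cells of width `u_res` (5, 2.5 or 1.25 mm)
#' along leaf travel, v cells fixed at the 5 mm leaf width and perfectly
#' aligned with the leaf rows (cell edges on multiples of the leaf width).
#' The extent covers the CTV projection plus `margin_mm` (default 25 mm).
#'
#' @param phantom a [build_phantom()] result.
#' @param gantry_deg gantry angle.
#' @param u_res beamlet width along leaf travel (mm).
#' @param margin_mm extent margin beyond the CTV projection.
#' @param leaf_width leaf (and beamlet row) width in mm.
#' @return object of class `beamlet_grid` with `u_edges`, `v_edges`,
#'   `nu`, `nv`; beamlet index `b = (iv - 1) * nu + iu`.
#' @export
beamlet_grid <- function(phantom, gantry_deg, u_res = 5, margin_mm = 25,
                         leaf_width = 5) {
  if (!u_res %in% c(5, 2.5, 1.25))
    stop("beamlet.u_res: supported resolutions are 5, 2.5, 1.25 mm")
  f <- beam_frame(gantry_deg)
  ctv <- voxel_centers(phantom$grid, voi_indices(phantom$vois$CTV))
  u <- ctv %*% f$e_u
  v <- ctv[, 3]
  u_lo <- floor((min(u) - margin_mm) / u_res) * u_res
  u_hi <- ceiling((max(u) + margin_mm) / u_res) * u_res
  v_lo <- floor((min(v) - margin_mm) / leaf_width) * leaf_width
  v_hi <- ceiling((max(v) + margin_mm) / leaf_width) * leaf_width
  u_edges <- seq(u_lo, u_hi, by = u_res)
  v_edges <- seq(v_lo, v_hi, by = leaf_width)
  structure(list(u_edges = u_edges, v_edges = v_edges,
                 nu = length(u_edges) - 1L, nv = length(v_edges) - 1L,
                 u_res = u_res, leaf_width = leaf_width,
                 gantry_deg = gantry_deg),
            class = "beamlet_grid")
}

beamlet_centers <- function(bg) {
  uc <- (bg$u_edges[-1] + bg$u_edges[-length(bg$u_edges)]) / 2
  vc <- (bg$v_edges[-1] + bg$v_edges[-length(bg$v_edges)]) / 2
  list(u = rep(uc, times = bg$nv), v = rep(vc, each = bg$nu))
}

# Aperture ----------------------------------------------------------------

#' MLC aperture
#'
#' Leaf tip positions per leaf row on the BEV u-axis at isocenter, plus the Y
#' collimator (jaw) positions on the v-axis. Rows are the leaf rows of the
#' beam's beamlet grid; a row with `left == right` is closed.
#'
#' @param tips `nv x 2` matrix of (left, right) tip positions (mm).
#' @param y_jaws length-2 `c(v_min, v_max)` jaw positions (mm).
#' @param v_edges leaf row edges (mm), length `nv + 1`.
#' @param leaf_width leaf width (mm), default 5.
#' @return object of class `aperture`.
#' @export
aperture <- function(tips, y_jaws, v_edges, leaf_width = 5) {
  tips <- rbind(tips)
  if (nrow(tips) != length(v_edges) - 1L)
    stop("aperture: one (left, right) pair per leaf row required")
  if (any(tips[, 1] > tips[, 2]))
    stop("aperture: left tip must not exceed right tip")
  if (y_jaws[1] > y_jaws[2]) stop("aperture: v_min must not exceed v_max")
  structure(list(tips = tips, y_jaws = as.numeric(y_jaws),
                 v_edges = as.numeric(v_edges), leaf_width = leaf_width),
            class = "aperture")
}

aperture_area_mm2 <- function(ap) {
  vlo <- pmax(ap$v_edges[-length(ap$v_edges)], ap$y_jaws[1])
  vhi <- pmin(ap$v_edges[-1], ap$y_jaws[2])
  sum(pmax(ap$tips[, 2] - ap$tips[, 1], 0) * pmax(vhi - vlo, 0))
}

#' Shift an aperture to follow a BEV target displacement
#'
#' Translational (centroid) tracking: the planned open region is translated
#' by `(u, v)`. Each output leaf row takes the planned open interval found at
#' its row center minus `v`, shifted by `+u`; rows mapping outside the
#' planned row range close. Jaws shift by `v`. Tips and jaws are clamped to
#' the travel limit, setting the `clamped` flag.
#'
#' @param ap planned [aperture()].
#' @param shift length-2 BEV shift `c(u, v)` in mm.
#' @param travel_limit leaf/jaw travel limit (mm, symmetric).
#' @return shifted [aperture()] with attribute `clamped`.
#' @export
track_aperture <- function(ap, shift, travel_limit = 200) {
  u <- shift[1]; v <- shift[2]
  nv <- nrow(ap$tips)
  centers <- (ap$v_edges[-1] + ap$v_edges[-length(ap$v_edges)]) / 2
  src_pos <- centers - v
  j <- findInterval(src_pos, ap$v_edges, left.open = FALSE)
  tips <- matrix(0, nv, 2)
  open <- j >= 1L & j <= nv
  open[open] <- ap$tips[j[open], 2] > ap$tips[j[open], 1]
  tips[open, 1] <- ap$tips[j[open], 1] + u
  tips[open, 2] <- ap$tips[j[open], 2] + u
  jaws <- ap$y_jaws + v
  clamped <- any(abs(tips[open, ]) > travel_limit) ||
    any(abs(jaws) > travel_limit)
  tips[open, ] <- pmin(pmax(tips[open, ], -travel_limit), travel_limit)
  jaws <- pmin(pmax(jaws, -travel_limit), travel_limit)
  out <- aperture(tips, jaws, ap$v_edges, ap$leaf_width)
  attr(out, "clamped") <- clamped
  out
}

#' Beamlet aperture weights
#'
#' Geometric overlap of each beamlet with the open part of the MLC aperture:
#' weight = (open fraction of the beamlet's u-interval within the row's
#' [left, right] leaf gap) x (open fraction of its v-interval within the
#' jaws). Fully open beamlets get 1, fully covered ones 0; partially covered
#' beamlets interpolate linearly between the two.
#'
#' @param ap an [aperture()] on the same row set as `bg`.
#' @param bg the beam's [beamlet_grid()].
#' @return numeric weight vector over beamlets, in `[0, 1]`.
#' @export
beamlet_weights <- function(ap, bg) {
  if (nrow(ap$tips) != bg$nv ||
      abs(ap$v_edges[1] - bg$v_edges[1]) > 1e-9)
    stop("aperture rows are not aligned with the beamlet grid rows")
  ue_lo <- bg$u_edges[-length(bg$u_edges)]
  ue_hi <- bg$u_edges[-1]
  ve_lo <- bg$v_edges[-length(bg$v_edges)]
  ve_hi <- bg$v_edges[-1]
  fv <- pmax(pmin(ve_hi, ap$y_jaws[2]) - pmax(ve_lo, ap$y_jaws[1]), 0) /
    bg$leaf_width
  w <- numeric(bg$nu * bg$nv)
  for (iv in seq_len(bg$nv)) {
    if (fv[iv] == 0) next
    L <- ap$tips[iv, 1]; R <- ap$tips[iv, 2]
    if (R <= L) next
    fu <- pmax(pmin(ue_hi, R) - pmax(ue_lo, L), 0) / bg$u_res
    w[(iv - 1L) * bg$nu + seq_len(bg$nu)] <- fu * fv[iv]
  }
  w
}

# Plan generation ----------------------------------------------------------

#' Generate a step-and-shoot IMRT plan
#'
#' Heuristic conformal-segment generator (not inverse optimization): beams at
#' evenly spaced gantry angles; per beam, segment 1 is conformal to the PTV
#' projection in the beam's-eye-view and further segments are seeded
#' shrunken/offset sub-apertures. Every segment respects a minimum open area;
#' monitor units are split across segments with a decaying pattern
#' (~60/25/15% for three segments) and sum to `total_mu`.
#'
#' @param phantom a [build_phantom()] result.
#' @param ptv the planning target [voi()] (e.g. from [expand_margin()]).
#' @param n_beams number of beams (7 or 9 are typical).
#' @param segments_per_beam segments per beam.
#' @param total_mu total monitor units over the whole plan.
#' @param u_res beamlet resolution along leaf travel (5, 2.5 or 1.25 mm).
#' @param min_area_cm2 minimum open segment area.
#' @param seed integer seed for the sub-aperture generator.
#' @param gantry_start gantry angle of the first beam (degrees).
#' @return object of class `treatment_plan`: `beams` (each with
#'   `gantry_deg`, `bgrid`, `segments` of `aperture` + `planned_mu`),
#'   `iso`, `total_mu`.
#' @export
generate_plan <- function(phantom, ptv = NULL, n_beams = 7,
                          segments_per_beam = 3, total_mu = 1000,
                          u_res = 5, min_area_cm2 = 4, seed = 1,
                          gantry_start = 0) {
  if (n_beams < 1) stop("plan.n_beams must be >= 1")
  if (total_mu <= 0) stop("plan.total_mu must be > 0")
  if (is.null(ptv)) ptv <- phantom$vois$PTV
  if (is.null(ptv)) stop("plan: a PTV voi is required")
  min_area <- min_area_cm2 * 100 # mm^2
  ctv_idx <- voi_indices(phantom$vois$CTV)
  iso <- colMeans(voxel_centers(phantom$grid, ctv_idx))
  gantries <- (gantry_start + (seq_len(n_beams) - 1L) * 360 / n_beams) %% 360
  ptv_pts <- voxel_centers(phantom$grid, voi_indices(ptv))
  seg_w <- 2.4^-(seq_len(segments_per_beam) - 1)
  seg_w <- seg_w / sum(seg_w)
  beam_mu <- rep(total_mu / n_beams, n_beams)

  beams <- vector("list", n_beams)
  for (b in seq_len(n_beams)) {
    g <- gantries[b]
    bg <- beamlet_grid(phantom, g, u_res = u_res)
    f <- beam_frame(g)
    u <- as.numeric(ptv_pts %*% f$e_u)
    v <- ptv_pts[, 3]
    # conformal interval per leaf row, padded by the projected voxel footprint
    pad_u <- (abs(f$e_u[1]) * phantom$grid$spacing[1] +
              abs(f$e_u[2]) * phantom$grid$spacing[2]) / 2
    row_of <- findInterval(v, bg$v_edges)
    tips <- matrix(0, bg$nv, 2)
    for (iv in seq_len(bg$nv)) {
      ui <- u[row_of == iv]
      if (length(ui))
        tips[iv, ] <- c(min(ui) - pad_u, max(ui) + pad_u)
    }
    open_rows <- which(tips[, 2] > tips[, 1])
    jaw <- c(bg$v_edges[min(open_rows)], bg$v_edges[max(open_rows) + 1L])
    conformal <- aperture(tips, jaw, bg$v_edges, bg$leaf_width)
    if (aperture_area_mm2(conformal) < min_area)
      stop("plan: minimum segment area unsatisfiable for the conformal field")
    segs <- vector("list", segments_per_beam)
    segs[[1]] <- list(aperture = conformal,
                      planned_mu = beam_mu[b] * seg_w[1])
    if (segments_per_beam > 1) {
      for (s in 2:segments_per_beam) {
        sub <- with_seed(derive_seed(seed, 300L * b + s), {
          ok <- FALSE
          for (try in 1:25) {
            shrink <- stats::runif(1, 0.45, 0.8)
            off <- stats::runif(1, -0.2, 0.2)
            drop_edge <- sample(0:1, 1)
            t2 <- matrix(0, bg$nv, 2)
            rows <- open_rows
            if (drop_edge && length(rows) > 2)
              rows <- rows[-c(1, length(rows))]
            for (iv in rows) {
              ctr <- mean(tips[iv, ]) + off * diff(tips[iv, ])
              half <- shrink * diff(tips[iv, ]) / 2
              t2[iv, ] <- c(ctr - half, ctr + half)
            }
            capr <- aperture(t2, jaw, bg$v_edges, bg$leaf_width)
            if (aperture_area_mm2(capr) >= min_area) { ok <- TRUE; break }
          }
          if (!ok) stop("plan: minimum segment area unsatisfiable")
          capr
        })
        segs[[s]] <- list(aperture = sub, planned_mu = beam_mu[b] * seg_w[s])
      }
    }
    beams[[b]] <- list(gantry_deg = g, bgrid = bg, segments = segs)
  }
  structure(list(beams = beams, iso = iso, total_mu = total_mu,
                 u_res = u_res, ptv_name = ptv$name, seed = seed),
            class = "treatment_plan")
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat(sprintf("treatment_plan: %d beams, %d segments, %.1f MU total\n",
              length(x$beams), sum(lengths(lapply(x$beams, `[[`, "segments"))),
              x$total_mu))
  invisible(x)
}

plan_segment_mu <- function(plan) {
  unlist(lapply(plan$beams, function(b)
    vapply(b$segments, `[[`, numeric(1), "planned_mu")))
}

#' Scale plan monitor units to a prescription
#'
#' Linearly rescales every segment's MU so that the static dose of the plan
#' meets `Dx(target) = prescription_cgy` (D95 of the PTV by default). Dose is
#' linear in MU, so the scaling is exact.
#'
#' @param plan a [generate_plan()] result.
#' @param dij dose influence store from [compute_dij_store()].
#' @param phantom the phantom. @param target_voi VOI name to prescribe to.
#' @param dx Dx percentage. @param prescription_cgy prescription in cGy.
#' @return the rescaled plan.
#' @export
normalize_plan_mu <- function(plan, dij, phantom, target_voi = "PTV",
                              dx = 95, prescription_cgy = 725) {
  dose <- planned_dose(plan, dij)
  tv <- phantom$vois[[target_voi]]
  if (is.null(tv)) stop("normalize_plan_mu: unknown VOI ", target_voi)
  dvh <- cumulative_dvh(dose[voi_indices(tv)], tv, phantom$grid)
  cur <- dose_at_volume(dvh, dx)
  if (cur <= 0) stop("normalize_plan_mu: zero target dose")
  scale <- prescription_cgy / cur
  for (b in seq_along(plan$beams))
    for (s in seq_along(plan$beams[[b]]$segments))
      plan$beams[[b]]$segments[[s]]$planned_mu <-
        plan$beams[[b]]$segments[[s]]$planned_mu * scale
  plan$total_mu <- plan$total_mu * scale
  plan
}
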