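#' Dose increment of one aperture
#'
#' Steps (iv)-(v) of the per-aperture loop: the sparse dose increment
#' `incremental_mu * sum_b weight_b * D_b` over the dose-calculation region.
#' A zero-MU aperture yields a zero increment but the computation path is
#' exercised all the same (beam-off apertures are processed like any other).
#'
#' @param weights beamlet weight vector (from [beamlet_weights()]).
#' @param dij_beam one beam's dose influence set (from
#'   [compute_dose_influence()]).
#' @param inc_mu incremental monitor units since the previous report.
#' @return numeric dose increment (cGy) over the region voxels.
#' @export
aperture_dose_increment <- function(weights, dij_beam, inc_mu) {
  if (length(weights) != ncol(dij_beam$D))
    stop("weights and dose influence matrix refer to different beamlet grids")
  inc_mu * as.numeric(dij_beam$D %*% weights)
}

# empty accumulator over a grid
dose_accumulator <- function(grid, target_idx) {
  list(static_dose = numeric(n_voxels(grid)),
       target_dose = numeric(length(target_idx)),
       target_idx = target_idx, mu_processed = 0, n_out_of_region = 0L)
}

#' Accumulate one dose increment
#'
#' Step (vi): the increment is added to the static-anatomy dose grid
#' everywhere. Under the `mlc_voi` method the target dose vector additionally
#' samples the increment at the displaced (and optionally rotated) target
#' voxel positions, mapping dose back into the target as defined at planning.
#' Under `mlc_only` the target is static and reads its own grid positions.
#' Samples falling outside the dose-calculation region contribute 0 and are
#' counted in `n_out_of_region`.
#'
#' @param acc accumulator (internal; create via `reconstruct`).
#' @param inc_region increment over region voxels (cGy).
#' @param grid the [grid_spec()].
#' @param region_idx linear indices of the region voxels.
#' @param region_mask logical mask of the region over the grid.
#' @param displacement length-3 target displacement (mm) for this aperture.
#' @param rotation optional [rotation_spec()].
#' @param method `"mlc_voi"` or `"mlc_only"`.
#' @param target_pts target voxel centers (`n x 3`).
#' @param target_ijk0 0-based integer voxel coords of the target voxels.
#' @param interp `"trilinear"` or `"nearest"`.
#' @return the updated accumulator.
#' @keywords internal
accumulate_increment <- function(acc, inc_region, grid, region_idx,
                                 region_mask, displacement, rotation, method,
                                 target_pts, target_ijk0,
                                 interp = "trilinear") {
  acc$static_dose[region_idx] <- acc$static_dose[region_idx] + inc_region
  if (method == "mlc_only") {
    inc_grid <- numeric(n_voxels(grid))
    inc_grid[region_idx] <- inc_region
    acc$target_dose <- acc$target_dose + inc_grid[acc$target_idx]
    return(acc)
  }
  inc_grid <- numeric(n_voxels(grid))
  inc_grid[region_idx] <- inc_region
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  if (is.null(rotation) || (rotation$pitch_deg == 0 &&
                            rotation$roll_deg == 0)) {
    # rigid constant shift: identical fractional weights for all voxels
    s <- displacement / grid$spacing
    if (interp == "nearest") {
      sh <- as.integer(round(s))
      i <- target_ijk0[, 1] + sh[1]
      j <- target_ijk0[, 2] + sh[2]
      k <- target_ijk0[, 3] + sh[3]
      ok <- i >= 0L & i < nx & j >= 0L & j < ny & k >= 0L & k < nz
      val <- numeric(nrow(target_ijk0))
      lin <- k[ok] * (nx * ny) + j[ok] * nx + i[ok] + 1L
      val[ok] <- inc_grid[lin]
      esc <- !ok
      esc[ok] <- !region_mask[lin]
    } else {
      s0 <- floor(s)
      fr <- s - s0
      s0 <- as.integer(s0)
      i0 <- target_ijk0[, 1] + s0[1]
      j0 <- target_ijk0[, 2] + s0[2]
      k0 <- target_ijk0[, 3] + s0[3]
      val <- numeric(nrow(target_ijk0))
      for (ci in 0:1) for (cj in 0:1) for (ck in 0:1) {
        wgt <- (if (ci) fr[1] else 1 - fr[1]) *
               (if (cj) fr[2] else 1 - fr[2]) *
               (if (ck) fr[3] else 1 - fr[3])
        if (wgt == 0) next
        i <- i0 + ci; j <- j0 + cj; k <- k0 + ck
        ok <- i >= 0L & i < nx & j >= 0L & j < ny & k >= 0L & k < nz
        lin <- k[ok] * (nx * ny) + j[ok] * nx + i[ok] + 1L
        add <- numeric(length(val))
        add[ok] <- inc_grid[lin] * wgt
        val <- val + add
      }
      # escaped = nearest voxel of the sampled position outside the region
      rn <- as.integer(round(s))
      i <- target_ijk0[, 1] + rn[1]
      j <- target_ijk0[, 2] + rn[2]
      k <- target_ijk0[, 3] + rn[3]
      ok <- i >= 0L & i < nx & j >= 0L & j < ny & k >= 0L & k < nz
      esc <- !ok
      esc[ok] <- !region_mask[k[ok] * (nx * ny) + j[ok] * nx + i[ok] + 1L]
    }
  } else {
    pts <- displace_and_rotate(target_pts, rotation, displacement)
    val <- if (interp == "nearest") {
      ijk <- nearest_ijk(grid, pts)
      ok <- ijk_in_grid(grid, ijk)
      v <- numeric(nrow(pts))
      v[ok] <- inc_grid[ijk_to_linear(grid, ijk[ok, , drop = FALSE])]
      v
    } else interp_trilinear(inc_grid, grid, pts)
    ijk <- nearest_ijk(grid, pts)
    ok <- ijk_in_grid(grid, ijk)
    esc <- !ok
    esc[ok] <- !region_mask[ijk_to_linear(grid, ijk[ok, , drop = FALSE])]
  }
  acc$target_dose <- acc$target_dose + val
  acc$n_out_of_region <- acc$n_out_of_region + sum(esc)
  acc
}

#' Reconstruct the actually delivered dose of a recorded delivery
#'
#' The per-aperture reconstruction loop: processes the aperture reports of a
#' delivery record in time order and, for each report, (i) finds the target
#' position closest in time, (ii) selects the beam's pre-calculated beamlets,
#' (iii) assigns geometric overlap weights, (iv)-(v) computes the dose
#' increment scaled by the incremental MU since the previous report, and
#' (vi) maps the increment onto the planning grid, with the target VOI mapped
#' at its displaced (and optionally rotated) position.
#'
#' Methods: `"mlc_voi"` moves the target VOI through the dose grid while the
#' reported aperture is used as delivered; `"mlc_only"` keeps the anatomy
#' static and instead applies the residual shift (MLC tracking motion minus
#' target motion, in the BEV) to the planned aperture.
#'
#' @param record a [simulate_delivery()] record (any mode; `mlc_only`
#'   requires a record of a known plan).
#' @param traj the [trajectory()] the anatomy actually followed.
#' @param phantom,plan,dij phantom, plan and [compute_dij_store()] store.
#' @param method `"mlc_voi"` (default) or `"mlc_only"`.
#' @param target_voi name of the moving target VOI (default `"PTV"`; the CTV
#'   is contained in it and is mapped with it).
#' @param offset constant interfractional offset vector (mm) added to the
#'   intrafractional motion during reconstruction.
#' @param rotation optional [rotation_spec()] applied to the whole fraction
#'   in the target mapping (tracking itself stays translational).
#' @param interp `"trilinear"` (default) or `"nearest"` target sampling.
#' @return object of class `recon_result`: `static_dose` (cGy, full grid),
#'   `target_dose` (cGy over target VOI voxels), `voi_doses` (named list;
#'   target-derived VOIs from the moving target vector, OARs from the static
#'   grid), `mu_processed`, `n_out_of_region`, provenance fields.
#' @export
reconstruct <- function(record, traj = NULL, phantom, plan, dij,
                        method = c("mlc_voi", "mlc_only"),
                        target_voi = "PTV", offset = c(0, 0, 0),
                        rotation = NULL, interp = c("trilinear", "nearest")) {
  method <- match.arg(method)
  interp <- match.arg(interp)
  if (is.null(record$apertures) || !length(record$apertures))
    stop("empty aperture stream")
  if (is.null(record$apertures[[1]]$inc_mu))
    record <- associate_machine_state(record)
  grid <- phantom$grid
  region_idx <- dij$region_idx
  region_mask <- logical(n_voxels(grid))
  region_mask[region_idx] <- TRUE
  tv <- phantom$vois[[target_voi]]
  if (is.null(tv)) stop("unknown target VOI: ", target_voi)
  target_idx <- voi_indices(tv)
  target_pts <- voxel_centers(grid, target_idx)
  target_ijk0 <- arrayInd(target_idx, grid$dims) - 1L
  storage.mode(target_ijk0) <- "integer"
  acc <- dose_accumulator(grid, target_idx)
  gantry_of_beam <- vapply(dij$beams, `[[`, numeric(1), "gantry_deg")
  static_region <- numeric(length(region_idx))
  t_prev <- -Inf
  for (rp in record$apertures) {
    if (rp$t_s < t_prev) stop("aperture reports out of order")
    t_prev <- rp$t_s
    b <- rp$beam
    if (b > length(dij$beams) ||
        abs(gantry_of_beam[b] - plan$beams[[b]]$gantry_deg) > 1e-9)
      stop("no dose influence data for gantry angle of beam ", b)
    dj <- dij$beams[[b]]
    d_t <- if (!is.null(traj)) nearest_target_sample(rp$t_s, traj)$d
           else c(0, 0, 0)
    d_t <- d_t + offset
    if (method == "mlc_only") {
      resid <- rp$shift - project_to_bev(d_t, plan$beams[[b]]$gantry_deg)
      ap <- track_aperture(plan$beams[[b]]$segments[[rp$segment]]$aperture,
                           resid)
    } else {
      ap <- rp$aperture
    }
    w <- beamlet_weights(ap, dj$bgrid)
    inc <- aperture_dose_increment(w, dj, rp$inc_mu)
    acc <- accumulate_increment(acc, inc, grid, region_idx, region_mask,
                                displacement = d_t, rotation = rotation,
                                method = method, target_pts = target_pts,
                                target_ijk0 = target_ijk0, interp = interp)
    acc$mu_processed <- acc$mu_processed + rp$inc_mu
  }
  # target-derived VOIs (the target VOI and anything nested inside it, e.g.
  # the CTV inside the PTV) move with the target; OARs stay static
  voi_doses <- list()
  for (v in phantom$vois) {
    idx_v <- which(v$mask)
    nested <- !anyNA(match(idx_v, target_idx))
    if (method == "mlc_voi" && nested && v$name %in% c(target_voi, "CTV")) {
      voi_doses[[v$name]] <- acc$target_dose[match(idx_v, target_idx)]
    } else {
      voi_doses[[v$name]] <- acc$static_dose[idx_v]
    }
  }
  structure(list(static_dose = acc$static_dose,
                 target_dose = acc$target_dose, target_idx = target_idx,
                 target_voi = target_voi, voi_doses = voi_doses,
                 mu_processed = acc$mu_processed,
                 n_out_of_region = acc$n_out_of_region,
                 method = method, mode = record$mode,
                 offset = offset,
                 rotation = if (!is.null(rotation))
                   c(pitch_deg = rotation$pitch_deg,
                     roll_deg = rotation$roll_deg) else c(0, 0),
                 grid = grid),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf(
    "recon_result: mode=%s method=%s, %.1f MU processed, %d escaped samples\n",
    x$mode, x$method, x$mu_processed, x$n_out_of_region))
  invisible(x)
}

#' Sweep interfractional offsets
#'
#' One reconstruction of a conventional delivery per constant offset vector,
#' each compared both to the zero-offset static reference and to the
#' offset-shifted static reference (the static delivery reconstructed with
#' the same constant offset), isolating intrafractional from interfractional
#' effects.
#'
#' @param record a conventional-mode [simulate_delivery()] record.
#' @param static_record the matching static-mode record.
#' @param traj the intrafractional [trajectory()].
#' @param phantom,plan,dij see [reconstruct()].
#' @param offsets `n x 3` matrix of offset vectors (see [offset_grid()]).
#' @param prescription_cgy prescription for Dx metrics.
#' @return data.frame: one row per offset with CTV D98, PTV D95, rectum D2,
#'   bladder D2 (cGy) and deltas vs the offset-shifted static reference.
#' @export
sweep_offsets <- function(record, static_record, traj, phantom, plan, dij,
                          offsets = offset_grid(), prescription_cgy = 725) {
  if (record$mode != "conventional")
    stop("offset sweeps are defined for conventional deliveries")
  record <- associate_machine_state(record)
  static_record <- associate_machine_state(static_record)
  rows <- vector("list", nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    off <- as.numeric(offsets[i, ])
    res <- reconstruct(record, traj, phantom, plan, dij, offset = off)
    ref <- reconstruct(static_record, NULL, phantom, plan, dij, offset = off)
    m <- voi_metrics(res, phantom, prescription_cgy)
    mr <- voi_metrics(ref, phantom, prescription_cgy)
    rows[[i]] <- data.frame(
      d_lr_mm = off[1], d_ap_mm = off[2], d_si_mm = off[3],
      ctv_d98_cgy = m$ctv_d98_cgy, ptv_d95_cgy = m$ptv_d95_cgy,
      rectum_d2_cgy = m$rectum_d2_cgy, bladder_d2_cgy = m$bladder_d2_cgy,
      delta_ctv_d98_cgy = m$ctv_d98_cgy - mr$ctv_d98_cgy,
      delta_ptv_d95_cgy = m$ptv_d95_cgy - mr$ptv_d95_cgy)
  }
  do.call(rbind, rows)
}

#' Sweep target rotations
#'
#' One reconstruction of a tracked delivery per pitch/roll rotation, the
#' rotation held constant over the whole fraction and applied only in the
#' target-dose mapping: MLC tracking keeps following translations only.
#'
#' @param record a tracked-mode [simulate_delivery()] record.
#' @param traj the intrafractional [trajectory()].
#' @param phantom,plan,dij see [reconstruct()].
#' @param rotations data.frame from [rotation_grid()].
#' @param pivot rotation pivot (mm); defaults to the plan isocenter (target
#'   centre of volume).
#' @param prescription_cgy prescription for Dx metrics.
#' @return data.frame: one row per rotation with target/OAR Dx metrics.
#' @export
sweep_rotations <- function(record, traj, phantom, plan, dij,
                            rotations = rotation_grid(seq(-20, 20, 4),
                                                      seq(-20, 20, 4)),
                            pivot = plan$iso, prescription_cgy = 725) {
  if (record$mode != "tracked")
    stop("rotation sweeps are defined for tracked deliveries")
  record <- associate_machine_state(record)
  rows <- vector("list", nrow(rotations))
  for (i in seq_len(nrow(rotations))) {
    rot <- rotation_spec(rotations$pitch_deg[i], rotations$roll_deg[i],
                         pivot = pivot)
    res <- reconstruct(record, traj, phantom, plan, dij, rotation = rot)
    m <- voi_metrics(res, phantom, prescription_cgy)
    rows[[i]] <- data.frame(
      pitch_deg = rotations$pitch_deg[i], roll_deg = rotations$roll_deg[i],
      ctv_d98_cgy = m$ctv_d98_cgy, ptv_d95_cgy = m$ptv_d95_cgy,
      rectum_d2_cgy = m$rectum_d2_cgy, bladder_d2_cgy = m$bladder_d2_cgy)
  }
  do.call(rbind, rows)
}
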