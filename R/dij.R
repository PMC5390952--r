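#' Synthetic dose deposition kernel
#'
#' Documented stand-in for a treatment-planning-system pencil beam: each
#' beamlet deposits
#' `D(voxel) = C * exp(-mu * radiological_depth) * F_u(du) * F_v(dv)` where
#' `F` is the lateral profile of a beamlet-wide top-hat convolved with a
#' Gaussian of width `sigma_mm`, and `du, dv` are BEV offsets from the
#' beamlet center. The calibration constant C is fixed so that a single
#' beamlet at unit weight and 1 MU deposits `cal_cgy_per_mu` cGy on its
#' central axis at `cal_depth_mm` water-equivalent depth. The homogeneous,
#' water-equivalent pelvis makes this simple shift-invariant kernel adequate
#' and keeps tracking-equivalence oracles exact.
#'
#' @param mu_mm linear attenuation coefficient (1/mm).
#' @param sigma_mm lateral Gaussian sigma (mm).
#' @param cal_cgy_per_mu calibration dose (cGy per MU).
#' @param cal_depth_mm calibration depth (mm).
#' @param step_mm ray-march step for radiological depth (mm).
#' @param cutoff_mm lateral truncation radius beyond the beamlet edge (mm).
#' @return object of class `dose_kernel`.
#' @export
dose_kernel <- function(mu_mm = 0.005, sigma_mm = 3, cal_cgy_per_mu = 0.25,
                        cal_depth_mm = 100, step_mm = 1,
                        cutoff_mm = 3.5 * sigma_mm) {
  if (mu_mm <= 0 || sigma_mm <= 0 || cal_cgy_per_mu <= 0 || step_mm <= 0)
    stop("kernel parameters must be > 0")
  structure(list(mu_mm = mu_mm, sigma_mm = sigma_mm,
                 cal_cgy_per_mu = cal_cgy_per_mu,
                 cal_depth_mm = cal_depth_mm, step_mm = step_mm,
                 cutoff_mm = cutoff_mm),
            class = "dose_kernel")
}

# lateral profile: top-hat of width w convolved with Gaussian(sigma)
lateral_profile <- function(delta, width, sigma) {
  stats::pnorm((delta + width / 2) / sigma) -
    stats::pnorm((delta - width / 2) / sigma)
}

kernel_calibration <- function(kernel, bg) {
  f0 <- lateral_profile(0, bg$u_res, kernel$sigma_mm) *
    lateral_profile(0, bg$leaf_width, kernel$sigma_mm)
  kernel$cal_cgy_per_mu / (exp(-kernel$mu_mm * kernel$cal_depth_mm) * f0)
}

# radiological depth (mm water-equivalent) of each point along -e_b back to
# the grid entry, by fixed-step nearest-neighbour density sampling
radiological_depth <- function(phantom, pts, e_b, step_mm) {
  grid <- phantom$grid
  n <- nrow(pts)
  extent <- sqrt(sum((grid$dims * grid$spacing)^2))
  ks <- seq(0.5, extent / step_mm + 0.5, by = 1)
  depth <- numeric(n)
  for (k in ks) {
    sx <- pts[, 1] - e_b[1] * k * step_mm
    sy <- pts[, 2] - e_b[2] * k * step_mm
    sz <- pts[, 3] - e_b[3] * k * step_mm
    ix <- as.integer(round((sx - grid$origin[1]) / grid$spacing[1]))
    iy <- as.integer(round((sy - grid$origin[2]) / grid$spacing[2]))
    iz <- as.integer(round((sz - grid$origin[3]) / grid$spacing[3]))
    ok <- ix >= 0L & ix < grid$dims[1] & iy >= 0L & iy < grid$dims[2] &
      iz >= 0L & iz < grid$dims[3]
    if (!any(ok)) break
    lin <- iz[ok] * (grid$dims[1] * grid$dims[2]) + iy[ok] * grid$dims[1] +
      ix[ok] + 1L
    depth[ok] <- depth[ok] + phantom$density[lin] * step_mm
  }
  depth
}

#' Compute the dose influence matrix for one beam
#'
#' Pre-calculates, for every beamlet of the beam, the sparse dose-per-MU
#' column over the voxels of the dose-calculation region (the CTV plus an
#' isotropic expansion). Deterministic; a beamlet whose ray misses the region
#' simply yields an empty column.
#'
#' @param phantom a [build_phantom()] result.
#' @param beam one beam of a [generate_plan()] plan (needs `gantry_deg` and
#'   `bgrid`).
#' @param kernel a [dose_kernel()].
#' @param region the dose-calculation [voi()] (see [dose_region()]).
#' @return list with `D` (`Matrix::dgCMatrix`, region voxels x beamlets,
#'   cGy/MU at unit weight), `region_idx` (global linear voxel indices),
#'   `bgrid`, `gantry_deg`.
#' @export
compute_dose_influence <- function(phantom, beam, kernel = dose_kernel(),
                                   region = dose_region(phantom)) {
  grid <- phantom$grid
  region_idx <- voi_indices(region)
  cm <- crop_mask(grid)
  if (!is.null(cm)) region_idx <- region_idx[cm[region_idx]]
  pts <- voxel_centers(grid, region_idx)
  f <- beam_frame(beam$gantry_deg)
  bg <- beam$bgrid
  depth <- radiological_depth(phantom, pts, f$e_b, kernel$step_mm)
  axial <- kernel_calibration(kernel, bg) * exp(-kernel$mu_mm * depth)
  u <- as.numeric(pts %*% f$e_u)
  v <- pts[, 3]
  bc <- beamlet_centers(bg)
  cut_u <- bg$u_res / 2 + kernel$cutoff_mm
  cut_v <- bg$leaf_width / 2 + kernel$cutoff_mm
  ord_u <- order(u)
  nb <- bg$nu * bg$nv
  is <- vector("list", nb); xs <- vector("list", nb); js <- vector("list", nb)
  # per v-row candidate voxels, then window in u per beamlet
  for (iv in seq_len(bg$nv)) {
    vc <- (bg$v_edges[iv] + bg$v_edges[iv + 1]) / 2
    row_sel <- which(abs(v - vc) <= cut_v)
    if (!length(row_sel)) next
    fv <- lateral_profile(v[row_sel] - vc, bg$leaf_width, kernel$sigma_mm)
    for (iu in seq_len(bg$nu)) {
      uc <- (bg$u_edges[iu] + bg$u_edges[iu + 1]) / 2
      sel <- row_sel[abs(u[row_sel] - uc) <= cut_u]
      if (!length(sel)) next
      fu <- lateral_profile(u[sel] - uc, bg$u_res, kernel$sigma_mm)
      val <- axial[sel] * fu * fv[match(sel, row_sel)]
      keep <- val > 0
      if (!any(keep)) next
      b <- (iv - 1L) * bg$nu + iu
      is[[b]] <- sel[keep]
      xs[[b]] <- val[keep]
      js[[b]] <- rep.int(b, sum(keep))
    }
  }
  D <- Matrix::sparseMatrix(i = unlist(is), j = unlist(js), x = unlist(xs),
                            dims = c(length(region_idx), nb))
  list(D = D, region_idx = region_idx, bgrid = bg,
       gantry_deg = beam$gantry_deg)
}

#' Compute dose influence matrices for a whole plan
#'
#' @param phantom,plan,kernel see [compute_dose_influence()].
#' @param region_margin_mm isotropic margin of the dose-calculation region.
#' @return object of class `dij_store`: `region_idx`, per-beam list `beams`.
#' @export
compute_dij_store <- function(phantom, plan, kernel = dose_kernel(),
                              region_margin_mm = 25) {
  region <- dose_region(phantom, region_margin_mm)
  beams <- lapply(plan$beams, function(b)
    compute_dose_influence(phantom, b, kernel, region))
  structure(list(region_idx = beams[[1]]$region_idx, beams = beams,
                 kernel = kernel, region_margin_mm = region_margin_mm,
                 n_voxels = n_voxels(phantom$grid), grid = phantom$grid),
            class = "dij_store")
}

#' Planned (static) dose of a plan
#'
#' The reference dose grid `sum_segments MU * sum_beamlets w_b D_b`, i.e. the
#' dose a motion-free delivery deposits.
#'
#' @param plan a [generate_plan()] result.
#' @param dij a [compute_dij_store()] result.
#' @return dense dose vector (cGy) over the full grid.
#' @export
planned_dose <- function(plan, dij) {
  acc_region <- numeric(length(dij$region_idx))
  for (b in seq_along(plan$beams)) {
    beam <- plan$beams[[b]]
    dj <- dij$beams[[b]]
    for (seg in beam$segments) {
      w <- beamlet_weights(seg$aperture, dj$bgrid)
      acc_region <- acc_region + seg$planned_mu *
        as.numeric(dj$D %*% w)
    }
  }
  dose <- numeric(prod_dims_from(dij))
  dose[dij$region_idx] <- acc_region
  dose
}

# full-grid length is recoverable from the stored grid when available;
# fall back to max index
prod_dims_from <- function(dij) {
  if (!is.null(dij$n_voxels)) dij$n_voxels else max(dij$region_idx)
}
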