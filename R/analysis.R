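#' Cumulative dose-volume histogram
#'
#' Exact empirical cumulative DVH from per-voxel doses: no binning, each VOI
#' voxel counted fully (VOIs are non-exclusive, so voxels shared between
#' overlapping structures appear in every curve they belong to). The curve is
#' non-increasing in dose and equals 1 at dose 0.
#'
#' @param dose numeric dose vector (cGy) over the VOI voxels, or over the full
#'   grid (it is then restricted to the VOI).
#' @param v the [voi()].
#' @param grid the [grid_spec()].
#' @return object of class `dvh`: sorted doses, voxel volume, VOI name.
#' @export
cumulative_dvh <- function(dose, v, grid) {
  nv <- sum(v$mask)
  if (nv == 0) stop("empty VOI: ", v$name)
  if (length(dose) == n_voxels(grid)) dose <- dose[v$mask]
  if (length(dose) != nv)
    stop("dose vector does not cover VOI ", v$name)
  structure(list(voi = v$name, doses = sort(dose),
                 voxel_cm3 = voxel_volume_cm3(grid), n = nv),
            class = "dvh")
}

#' Evaluate the cumulative DVH curve
#'
#' Volume fraction of the VOI receiving at least each queried dose.
#'
#' @param dvh a [cumulative_dvh()].
#' @param dose_cgy dose levels to evaluate at.
#' @return volume fractions in `[0, 1]`.
#' @export
dvh_volume_fraction <- function(dvh, dose_cgy) {
  vapply(dose_cgy, function(d) sum(dvh$doses >= d) / dvh$n, numeric(1))
}

#' Dose at volume (Dx)
#'
#' The minimum dose received by the hottest x% of the VOI volume, computed on
#' the sorted per-voxel doses with linear interpolation between ranks (no
#' histogram binning). `D100` is the minimum voxel dose, `x -> 0` approaches
#' the maximum.
#'
#' @param dvh a [cumulative_dvh()].
#' @param x volume percentage in `(0, 100]`.
#' @return dose in cGy.
#' @export
dose_at_volume <- function(dvh, x) {
  if (x <= 0 || x > 100) stop("Dx: x must be in (0, 100]")
  n <- dvh$n
  desc <- rev(dvh$doses) # hottest first
  r <- x / 100 * n       # fractional rank
  if (r <= 1) return(desc[1])
  if (r >= n) return(desc[n])
  lo <- floor(r)
  desc[lo] + (r - lo) * (desc[lo + 1] - desc[lo])
}

#' Volume at dose (absolute)
#'
#' VOI volume receiving at least the threshold dose, in cm^3.
#'
#' @param dvh a [cumulative_dvh()].
#' @param threshold_cgy dose threshold (cGy).
#' @return volume in cm^3.
#' @export
volume_at_dose <- function(dvh, threshold_cgy) {
  sum(dvh$doses >= threshold_cgy) * dvh$voxel_cm3
}

#' V95% overlap with an organ at risk
#'
#' Volume of OAR voxels receiving at least 95% of the prescribed dose
#' (voxel count times voxel volume), used as a proxy for target-to-OAR
#' distance.
#'
#' @param dose dose vector over the full grid (cGy).
#' @param oar the OAR [voi()]. @param grid the [grid_spec()].
#' @param prescription_cgy prescription dose (cGy), default 725 for a single
#'   fraction.
#' @return overlap volume in cm^3.
#' @export
v95_overlap <- function(dose, oar, grid, prescription_cgy = 725) {
  if (prescription_cgy <= 0) stop("prescription must be > 0")
  sum(dose[oar$mask] >= 0.95 * prescription_cgy) * voxel_volume_cm3(grid)
}

#' Non-tumour integral dose
#'
#' Integral dose `I = rho * (V / N) * sum_i D_i` over a VOI with constant
#' mass density, in litre-Gy (volume in litres, doses converted from cGy to
#' Gy). The non-tumour "organ" is conventionally the body minus the CTV.
#'
#' @param dose dose vector (cGy) over the full grid or over the VOI voxels.
#' @param v the [voi()] (e.g. from [non_tumour_voi()]).
#' @param grid the [grid_spec()].
#' @param density_g_cm3 constant mass density of the organ.
#' @return integral dose in litre-Gy.
#' @export
ntid <- function(dose, v, grid, density_g_cm3 = 1) {
  if (density_g_cm3 <= 0) stop("density must be > 0")
  n <- sum(v$mask)
  if (n == 0) stop("empty VOI: ", v$name)
  if (length(dose) == n_voxels(grid)) dose <- dose[v$mask]
  if (length(dose) != n) stop("dose vector does not cover VOI ", v$name)
  v_litre <- n * voxel_volume_cm3(grid) / 1000
  density_g_cm3 * (v_litre / n) * sum(dose / 100)
}

#' Body-minus-CTV VOI
#'
#' @param phantom a [build_phantom()] result.
#' @return [voi()] named "non_tumour".
#' @export
non_tumour_voi <- function(phantom) {
  voi("non_tumour", phantom$vois$body$mask & !phantom$vois$CTV$mask,
      phantom$grid)
}

#' Standard per-VOI metrics of a reconstruction
#'
#' CTV D98, PTV D95, rectum D2 and bladder D2 (cGy), V95% overlap volumes of
#' the OARs and the non-tumour integral dose, for a single fraction.
#'
#' @param result a [reconstruct()] result.
#' @param phantom the phantom (must contain CTV, PTV, rectum, bladder, body).
#' @param prescription_cgy single-fraction prescription (cGy).
#' @return one-row data.frame of metrics.
#' @export
voi_metrics <- function(result, phantom, prescription_cgy = 725) {
  grid <- phantom$grid
  dvh_of <- function(name) {
    cumulative_dvh(result$voi_doses[[name]], phantom$vois[[name]], grid)
  }
  ctv <- dvh_of("CTV")
  ptv <- if (!is.null(phantom$vois$PTV)) dvh_of("PTV") else NULL
  rect <- dvh_of("rectum")
  blad <- dvh_of("bladder")
  nt <- non_tumour_voi(phantom)
  data.frame(
    ctv_d98_cgy = dose_at_volume(ctv, 98),
    ptv_d95_cgy = if (!is.null(ptv)) dose_at_volume(ptv, 95) else NA_real_,
    rectum_d2_cgy = dose_at_volume(rect, 2),
    bladder_d2_cgy = dose_at_volume(blad, 2),
    rectum_v95_cm3 = v95_overlap(result$static_dose, phantom$vois$rectum,
                                 grid, prescription_cgy),
    bladder_v95_cm3 = v95_overlap(result$static_dose, phantom$vois$bladder,
                                  grid, prescription_cgy),
    ntid_litre_gy = ntid(result$static_dose, nt, grid),
    mu_processed = result$mu_processed)
}

#' Metric deltas relative to a static reference
#'
#' All dosimetric results are reported relative to the static delivery of the
#' same plan (the motion-free gold standard):
#' `delta = metric(result) - metric(static_ref)` for every metric column.
#' Deltas negate when the arguments are swapped.
#'
#' @param result,static_ref [reconstruct()] results on the same phantom/plan.
#' @param phantom the phantom.
#' @param prescription_cgy prescription (cGy).
#' @return one-row data.frame of metric deltas (same column names, prefixed
#'   `delta_`).
#' @export
compare_to_static <- function(result, static_ref, phantom,
                              prescription_cgy = 725) {
  if (!identical(dim(result$grid$dims), dim(static_ref$grid$dims)) ||
      any(result$grid$dims != static_ref$grid$dims) ||
      any(abs(result$grid$spacing - static_ref$grid$spacing) > 1e-12))
    stop("compare_to_static: mismatched geometry")
  m <- voi_metrics(result, phantom, prescription_cgy)
  r <- voi_metrics(static_ref, phantom, prescription_cgy)
  d <- m - r
  names(d) <- paste0("delta_", names(m))
  d
}

#' Export a DVH curve as a data.frame
#'
#' @param dvh a [cumulative_dvh()].
#' @param n_points number of dose levels (0 to max dose).
#' @return data.frame `dose_cgy, volume_fraction`.
#' @export
dvh_curve <- function(dvh, n_points = 201) {
  d <- seq(0, max(dvh$doses), length.out = n_points)
  data.frame(dose_cgy = d, volume_fraction = dvh_volume_fraction(dvh, d))
}
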