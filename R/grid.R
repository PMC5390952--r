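#' Voxel grid specification
#'
#' Defines the regular voxel grid that every phantom, volume of interest and
#' dose vector in this package lives on. Axes follow one fixed patient
#' convention: LR = +x (patient left), AP = +y (anterior), SI = +z (superior).
#' `origin` is the position (mm) of the *center* of voxel (1,1,1); voxel
#' coordinates are voxel-center positions.
#'
#' @param dims integer vector of length 3, voxel counts per axis (LR, AP, SI).
#' @param spacing numeric vector of length 3, voxel pitch in mm per axis.
#' @param origin numeric vector of length 3, mm position of the first voxel
#'   center. Defaults to a grid centered on the coordinate origin.
#' @param axial_crop optional inclusive slice range `c(lo, hi)` along SI used
#'   to restrict dose accumulation (off by default).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(dims, spacing, origin = NULL, axial_crop = NULL) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  if (length(dims) != 3L || any(dims < 1L))
    stop("grid.dims: need 3 voxel counts >= 1")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("grid.spacing: need 3 positive spacings (mm)")
  if (is.null(origin)) origin <- -(dims - 1L) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("grid.origin: need 3 components (mm)")
  if (!is.null(axial_crop)) {
    axial_crop <- as.integer(axial_crop)
    if (length(axial_crop) != 2L || axial_crop[1] < 1L ||
        axial_crop[2] > dims[3] || axial_crop[1] > axial_crop[2])
      stop("grid.axial_crop: slice range must lie within dims[3]")
  }
  structure(list(dims = dims, spacing = spacing, origin = origin,
                 axial_crop = axial_crop),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$dims)

#' Voxel center positions
#'
#' @param grid a [grid_spec()].
#' @param idx optional linear voxel indices (1-based, x fastest); default all.
#' @return numeric matrix `n x 3` of mm positions (LR, AP, SI).
#' @export
voxel_centers <- function(grid, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(n_voxels(grid))
  ijk <- arrayInd(idx, grid$dims)
  cbind(grid$origin[1] + (ijk[, 1] - 1) * grid$spacing[1],
        grid$origin[2] + (ijk[, 2] - 1) * grid$spacing[2],
        grid$origin[3] + (ijk[, 3] - 1) * grid$spacing[3])
}

# mm position -> nearest 1-based ijk (no bounds check)
nearest_ijk <- function(grid, pts) {
  pts <- rbind(pts)
  cbind(as.integer(round((pts[, 1] - grid$origin[1]) / grid$spacing[1])) + 1L,
        as.integer(round((pts[, 2] - grid$origin[2]) / grid$spacing[2])) + 1L,
        as.integer(round((pts[, 3] - grid$origin[3]) / grid$spacing[3])) + 1L)
}

ijk_in_grid <- function(grid, ijk) {
  ijk[, 1] >= 1L & ijk[, 1] <= grid$dims[1] &
  ijk[, 2] >= 1L & ijk[, 2] <= grid$dims[2] &
  ijk[, 3] >= 1L & ijk[, 3] <= grid$dims[3]
}

ijk_to_linear <- function(grid, ijk) {
  (ijk[, 3] - 1L) * (grid$dims[1] * grid$dims[2]) +
    (ijk[, 2] - 1L) * grid$dims[1] + ijk[, 1]
}

#' Voxel volume in cm^3
#' @param grid a [grid_spec()].
#' @export
voxel_volume_cm3 <- function(grid) prod(grid$spacing) / 1000

# linear indices restricted by the optional axial crop
crop_mask <- function(grid) {
  if (is.null(grid$axial_crop)) return(NULL)
  iz <- arrayInd(seq_len(n_voxels(grid)), grid$dims)[, 3]
  iz >= grid$axial_crop[1] & iz <= grid$axial_crop[2]
}

#' Trilinear interpolation of a gridded field
#'
#' Samples a dense per-voxel field at arbitrary mm positions. Positions whose
#' enclosing cell extends beyond the grid contribute the value 0.
#'
#' @param values numeric vector of length `prod(grid$dims)` (x fastest).
#' @param grid a [grid_spec()].
#' @param pts `n x 3` matrix of mm positions.
#' @return numeric vector of interpolated values.
#' @export
interp_trilinear <- function(values, grid, pts) {
  pts <- rbind(pts)
  fx <- (pts[, 1] - grid$origin[1]) / grid$spacing[1]
  fy <- (pts[, 2] - grid$origin[2]) / grid$spacing[2]
  fz <- (pts[, 3] - grid$origin[3]) / grid$spacing[3]
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  out <- numeric(nrow(pts))
  gather <- function(i, j, k) {
    ok <- i >= 0L & i <= nx - 1L & j >= 0L & j <= ny - 1L & k >= 0L & k <= nz - 1L
    v <- numeric(length(i))
    lin <- k[ok] * (nx * ny) + j[ok] * nx + i[ok] + 1
    v[ok] <- values[lin]
    v
  }
  i0 <- as.integer(i0); j0 <- as.integer(j0); k0 <- as.integer(k0)
  out <- gather(i0,      j0,      k0)      * (1 - tx) * (1 - ty) * (1 - tz) +
         gather(i0 + 1L, j0,      k0)      * tx       * (1 - ty) * (1 - tz) +
         gather(i0,      j0 + 1L, k0)      * (1 - tx) * ty       * (1 - tz) +
         gather(i0 + 1L, j0 + 1L, k0)      * tx       * ty       * (1 - tz) +
         gather(i0,      j0,      k0 + 1L) * (1 - tx) * (1 - ty) * tz +
         gather(i0 + 1L, j0,      k0 + 1L) * tx       * (1 - ty) * tz +
         gather(i0,      j0 + 1L, k0 + 1L) * (1 - tx) * ty       * tz +
         gather(i0 + 1L, j0 + 1L, k0 + 1L) * tx       * ty       * tz
  out
}

# deterministic sub-stream seeds; product stays < 2^53 so arithmetic is exact,
# result stays < 2^31 for set.seed()
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed %% 2147483647L) * 48271 + as.numeric(salt)) %%
               2147483647)
}

# evaluate expr under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
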