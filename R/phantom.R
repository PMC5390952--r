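#' Volume of interest
#'
#' A named boolean voxel mask on a grid. VOIs are non-exclusive: a voxel may
#' belong to several VOIs (e.g. CTV and PTV) and is then counted fully in each
#' one during DVH analysis.
#'
#' @param name character name (e.g. "CTV").
#' @param mask logical vector/array with one entry per grid voxel.
#' @param grid the [grid_spec()] the mask lives on.
#' @return object of class `voi`.
#' @export
voi <- function(name, mask, grid) {
  mask <- as.logical(mask)
  if (length(mask) != n_voxels(grid))
    stop(sprintf("voi '%s': mask length %d does not match grid (%d voxels)",
                 name, length(mask), n_voxels(grid)))
  structure(list(name = name, mask = mask), class = "voi")
}

voi_indices <- function(v) which(v$mask)

#' VOI volume in cm^3
#' @param v a [voi()]. @param grid its [grid_spec()].
#' @export
voi_volume_cm3 <- function(v, grid) sum(v$mask) * voxel_volume_cm3(grid)

# analytic solids used by the phantom builder -------------------------------

solid_mask <- function(grid, solid) {
  p <- voxel_centers(grid)
  switch(solid$type,
    ellipsoid = {
      d <- sweep(sweep(p, 2, solid$center), 2, solid$radii, "/")
      rowSums(d^2) <= 1
    },
    cylinder_si = { # elliptical cross-section in LR/AP, finite SI extent
      d1 <- (p[, 1] - solid$center[1]) / solid$radii[1]
      d2 <- (p[, 2] - solid$center[2]) / solid$radii[2]
      d1^2 + d2^2 <= 1 & abs(p[, 3] - solid$center[3]) <= solid$half_length
    },
    box = {
      abs(p[, 1] - solid$center[1]) <= solid$half_size[1] &
      abs(p[, 2] - solid$center[2]) <= solid$half_size[2] &
      abs(p[, 3] - solid$center[3]) <= solid$half_size[3]
    },
    full = rep(TRUE, n_voxels(grid)),
    stop("unknown solid type: ", solid$type))
}

solid_extent <- function(solid) {
  switch(solid$type,
    ellipsoid   = rbind(solid$center - solid$radii, solid$center + solid$radii),
    cylinder_si = rbind(solid$center - c(solid$radii, solid$half_length),
                        solid$center + c(solid$radii, solid$half_length)),
    box         = rbind(solid$center - solid$half_size,
                        solid$center + solid$half_size),
    full        = NULL)
}

#' Default phantom configuration
#'
#' The stated world of the digital pelvic phantom: a water-equivalent body with
#' an ellipsoidal prostate CTV (~44 cm^3, matching typical prostate volumes),
#' a rectum posterior of the CTV (3 mm anterior gap) and a bladder
#' anterior/superior of it. Organ sizes and adjacencies mimic a typical
#' prostate case; densities are 1.0 g/cm^3 inside the body and 0 outside.
#'
#' @param dims,spacing,origin grid parameters, see [grid_spec()].
#' @param body,ctv,rectum,bladder analytic solid descriptions (lists with a
#'   `type` of "ellipsoid", "cylinder_si", "box" or "full" plus geometry
#'   fields in mm).
#' @return a config list for [build_phantom()].
#' @export
phantom_config <- function(dims = c(50, 50, 50), spacing = c(3, 3, 3),
                           origin = NULL,
                           body = list(type = "ellipsoid", center = c(0, 0, 0),
                                       radii = c(70, 68, 72)),
                           ctv = list(type = "ellipsoid", center = c(0, 0, 0),
                                      radii = c(24, 22, 20)),
                           rectum = list(type = "cylinder_si",
                                         center = c(0, -38, 0),
                                         radii = c(14, 13), half_length = 45),
                           bladder = list(type = "ellipsoid",
                                          center = c(0, 42, 34),
                                          radii = c(20, 16, 16))) {
  list(grid = grid_spec(dims, spacing, origin),
       body = body, ctv = ctv, rectum = rectum, bladder = bladder)
}

#' Build the digital pelvic phantom
#'
#' Voxelizes the configured analytic solids into body, CTV, rectum and bladder
#' VOIs and a mass-density grid (1.0 g/cm^3 inside the body, 0 outside),
#' standing in for the planning CT of a prostate case.
#'
#' @param config a [phantom_config()].
#' @return object of class `phantom`: fields `grid`, `density`, `vois`
#'   (named list of [voi()]), `config`.
#' @export
build_phantom <- function(config = phantom_config()) {
  grid <- config$grid
  for (organ in c("ctv", "rectum", "bladder")) {
    s <- config[[organ]]
    ext <- solid_extent(s)
    if (!is.null(ext)) {
      if (any(!is.finite(unlist(ext))) ||
          any(ext[2, ] - ext[1, ] <= 0))
        stop(sprintf("phantom.%s: degenerate (zero-size) solid", organ))
      gmin <- grid$origin - grid$spacing / 2
      gmax <- grid$origin + (grid$dims - 0.5) * grid$spacing
      if (any(ext[1, ] < gmin) || any(ext[2, ] > gmax))
        stop(sprintf("phantom.%s: organ extends beyond the grid", organ))
    }
  }
  body    <- voi("body",    solid_mask(grid, config$body), grid)
  ctv     <- voi("CTV",     solid_mask(grid, config$ctv), grid)
  rectum  <- voi("rectum",  solid_mask(grid, config$rectum), grid)
  bladder <- voi("bladder", solid_mask(grid, config$bladder), grid)
  for (v in list(body, ctv, rectum, bladder))
    if (!any(v$mask)) stop(sprintf("phantom.%s: empty mask", v$name))
  density <- numeric(n_voxels(grid))
  density[body$mask] <- 1.0
  structure(list(grid = grid, density = density,
                 vois = list(body = body, CTV = ctv, rectum = rectum,
                             bladder = bladder),
                 config = config),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("phantom on "); print(x$grid)
  for (v in x$vois)
    cat(sprintf("  %-8s %8.1f cm^3\n", v$name, voi_volume_cm3(v, x$grid)))
  invisible(x)
}

#' Margin specification
#'
#' Per-direction margins in mm, ordered (left, right, anterior, posterior,
#' superior, inferior). A scalar gives an isotropic margin; `posterior` etc.
#' override single directions, as in the clinical "5 mm reduced to 3 mm
#' posteriorly" margin.
#'
#' @param isotropic scalar mm applied to all six directions.
#' @param left,right,anterior,posterior,superior,inferior optional overrides.
#' @return named numeric vector of length 6.
#' @export
margin_spec <- function(isotropic = 5, left = NULL, right = NULL,
                        anterior = NULL, posterior = NULL,
                        superior = NULL, inferior = NULL) {
  m <- rep(as.numeric(isotropic), 6)
  names(m) <- c("left", "right", "anterior", "posterior", "superior",
                "inferior")
  for (d in names(m)) {
    v <- get(d)
    if (!is.null(v)) m[d] <- as.numeric(v)
  }
  if (any(m < 0)) stop("margins must be >= 0")
  m
}

#' Expand a VOI by an anisotropic margin
#'
#' Returns the set of voxels whose center lies within the margin expansion of
#' the base VOI: voxel p is included when some base voxel q satisfies the
#' per-octant ellipsoid condition sum_i (delta_i / m_i(sign delta_i))^2 <= 1,
#' where m_i picks the margin for the direction of the displacement component.
#' With an isotropic margin this is the usual spherical expansion. The base is
#' always a subset of the result.
#'
#' @param base a [voi()] (e.g. the CTV).
#' @param margins a [margin_spec()] (or scalar mm).
#' @param grid the [grid_spec()].
#' @param name name for the new VOI.
#' @return a [voi()].
#' @export
expand_margin <- function(base, margins, grid, name = "PTV") {
  if (length(margins) == 1) margins <- margin_spec(margins)
  if (!any(base$mask)) stop("expand_margin: empty base VOI")
  if (length(margins) != 6) stop("margins: use margin_spec() (6 directions)")
  m <- pmax(margins, 0)
  names(m) <- c("left", "right", "anterior", "posterior", "superior",
                "inferior")
  if (all(m == 0)) return(voi(name, base$mask, grid))
  base_idx <- which(base$mask)
  # surface voxels of the base suffice as expansion seeds
  arr <- array(base$mask, grid$dims)
  inner <- array(FALSE, grid$dims)
  if (all(grid$dims > 2)) {
    core <- arr[2:(grid$dims[1] - 1), 2:(grid$dims[2] - 1),
                2:(grid$dims[3] - 1)] &
      arr[1:(grid$dims[1] - 2), 2:(grid$dims[2] - 1), 2:(grid$dims[3] - 1)] &
      arr[3:grid$dims[1],       2:(grid$dims[2] - 1), 2:(grid$dims[3] - 1)] &
      arr[2:(grid$dims[1] - 1), 1:(grid$dims[2] - 2), 2:(grid$dims[3] - 1)] &
      arr[2:(grid$dims[1] - 1), 3:grid$dims[2],       2:(grid$dims[3] - 1)] &
      arr[2:(grid$dims[1] - 1), 2:(grid$dims[2] - 1), 1:(grid$dims[3] - 2)] &
      arr[2:(grid$dims[1] - 1), 2:(grid$dims[2] - 1), 3:grid$dims[3]]
    inner[2:(grid$dims[1] - 1), 2:(grid$dims[2] - 1),
          2:(grid$dims[3] - 1)] <- core
  }
  seed_idx <- which(arr & !inner)
  seeds <- voxel_centers(grid, seed_idx)
  # candidates: bounding box of the base dilated by the largest margins
  bctr <- voxel_centers(grid, base_idx)
  lo <- apply(bctr, 2, min) - c(m["right"], m["posterior"], m["inferior"])
  hi <- apply(bctr, 2, max) + c(m["left"], m["anterior"], m["superior"])
  allc <- voxel_centers(grid)
  cand <- which(allc[, 1] >= lo[1] & allc[, 1] <= hi[1] &
                allc[, 2] >= lo[2] & allc[, 2] <= hi[2] &
                allc[, 3] >= lo[3] & allc[, 3] <= hi[3] & !base$mask)
  out <- base$mask
  if (length(cand)) {
    mdir <- function(delta, pos, neg) ifelse(delta >= 0, m[pos], m[neg])
    scaled <- function(delta, pos, neg) {
      md <- mdir(delta, pos, neg)
      r <- ifelse(md > 0, delta / pmax(md, .Machine$double.eps),
                  ifelse(delta == 0, 0, Inf))
      r
    }
    hit <- logical(length(cand))
    cpos <- allc[cand, , drop = FALSE]
    # chunk over seeds to bound memory
    step <- max(1L, floor(2e6 / length(cand)))
    for (s0 in seq(1L, nrow(seeds), by = step)) {
      s1 <- min(nrow(seeds), s0 + step - 1L)
      for (s in s0:s1) {
        dx <- cpos[, 1] - seeds[s, 1]
        dy <- cpos[, 2] - seeds[s, 2]
        dz <- cpos[, 3] - seeds[s, 3]
        q <- scaled(dx, "left", "right")^2 +
             scaled(dy, "anterior", "posterior")^2 +
             scaled(dz, "superior", "inferior")^2
        hit <- hit | q <= 1
      }
      if (all(hit)) break
    }
    out[cand[hit]] <- TRUE
  }
  # the expansion must stay inside the grid: voxels on the outermost layer
  # indicate the true expansion exits the grid
  ijk <- arrayInd(which(out), grid$dims)
  if (any(apply(ijk, 2, min) == 1L) || any(apply(ijk, 2, max) == grid$dims))
    stop("expand_margin: expansion exits the grid")
  voi(name, out, grid)
}

#' Add a VOI to a phantom
#'
#' @param phantom a [build_phantom()] result.
#' @param v a [voi()] on the same grid.
#' @return the phantom with `v` added under its name.
#' @export
add_voi <- function(phantom, v) {
  stopifnot(inherits(v, "voi"))
  phantom$vois[[v$name]] <- v
  phantom
}

#' Dose-calculation region
#'
#' The CTV expanded by an isotropic margin (default 25 mm); dose influence
#' matrices are only computed for voxels inside this region, covering the
#' anticipated range of target motion.
#'
#' @param phantom a [build_phantom()] result.
#' @param margin_mm isotropic expansion in mm.
#' @return a [voi()] named "dose_region".
#' @export
dose_region <- function(phantom, margin_mm = 25) {
  expand_margin(phantom$vois$CTV, margin_spec(margin_mm), phantom$grid,
                name = "dose_region")
}
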