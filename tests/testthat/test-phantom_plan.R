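test_that("grid_spec validates and measures voxels", {
  g <- grid_spec(c(10, 10, 10), c(2, 2, 2))
  expect_equal(voxel_volume_cm3(g), 0.008)
  expect_equal(g$origin, c(-9, -9, -9))
  expect_error(grid_spec(c(0, 10, 10), c(2, 2, 2)), "dims")
  expect_error(grid_spec(c(10, 10, 10), c(2, -1, 2)), "spacing")
  expect_error(grid_spec(c(10, 10, 10), c(2, 2, 2), axial_crop = c(5, 12)),
               "axial_crop")
})

test_that("build_phantom voxelizes the configured organs", {
  ph <- build_phantom()
  ctv <- ph$config$ctv
  analytic <- 4 / 3 * pi * prod(ctv$radii) / 1000
  expect_lt(abs(voi_volume_cm3(ph$vois$CTV, ph$grid) - analytic) / analytic,
            0.1)
  # OARs non-empty and disjoint from the CTV
  expect_gt(sum(ph$vois$rectum$mask), 0)
  expect_gt(sum(ph$vois$bladder$mask), 0)
  expect_equal(sum(ph$vois$rectum$mask & ph$vois$CTV$mask), 0)
  expect_equal(sum(ph$vois$bladder$mask & ph$vois$CTV$mask), 0)
  # density: water inside body, zero outside
  expect_true(all(ph$density[ph$vois$body$mask] == 1))
  expect_true(all(ph$density[!ph$vois$body$mask] == 0))
})

test_that("degenerate or out-of-grid organs are rejected", {
  cfg <- phantom_config()
  cfg$ctv$radii <- c(0, 0, 0)
  expect_error(build_phantom(cfg), "degenerate")
  cfg <- phantom_config()
  cfg$bladder$center <- c(0, 120, 0)
  expect_error(build_phantom(cfg), "beyond the grid")
})

test_that("expand_margin: identity, sphere volume, anisotropy, nesting", {
  # fine 1 mm grid so sub-voxel margins are resolvable
  g <- grid_spec(c(45, 45, 45), c(1, 1, 1))
  p <- voxel_centers(g)
  sph <- voi("CTV", rowSums(p^2) <= 12^2, g)

  expect_equal(expand_margin(sph, margin_spec(0), g)$mask, sph$mask)

  p5 <- expand_margin(sph, margin_spec(5), g)
  analytic <- 4 / 3 * pi * 17^3 / 1000
  # center-based voxelized expansion: within the half-voxel surface band
  lo <- 4 / 3 * pi * 16.5^3 / 1000
  hi <- 4 / 3 * pi * 17.5^3 / 1000
  expect_gt(voi_volume_cm3(p5, g), lo)
  expect_lt(voi_volume_cm3(p5, g), hi)
  expect_true(all(p5$mask[sph$mask])) # superset of base

  p53 <- expand_margin(sph, margin_spec(5, posterior = 3), g)
  post_extent <- function(v) min(voxel_centers(g, voi_indices(v))[, 2])
  expect_equal(post_extent(p53) - post_extent(p5), 2)

  # monotone nesting over margins
  p1 <- expand_margin(sph, margin_spec(1), g)
  p3 <- expand_margin(sph, margin_spec(3), g)
  expect_true(all(p3$mask[p1$mask]))
  expect_true(all(p5$mask[p3$mask]))

  expect_error(expand_margin(sph, margin_spec(15), g), "exits the grid")
  expect_error(expand_margin(voi("E", rep(FALSE, prod(g$dims)), g),
                             margin_spec(5), g), "empty")
})

test_that("generate_plan spaces beams evenly and conserves MU", {
  w <- tiny_world()
  plan7 <- generate_plan(w$phantom, ptv = w$phantom$vois$PTV, n_beams = 7,
                         segments_per_beam = 1, total_mu = 100,
                         min_area_cm2 = 1, seed = 1)
  expect_equal(vapply(plan7$beams, `[[`, numeric(1), "gantry_deg"),
               (0:6) * 360 / 7)
  for (seed in 1:3) {
    p <- generate_plan(w$phantom, ptv = w$phantom$vois$PTV, n_beams = 3,
                       segments_per_beam = 3, total_mu = 250,
                       min_area_cm2 = 1, seed = seed)
    expect_equal(sum(trackdose:::plan_segment_mu(p)), 250)
  }
  expect_error(generate_plan(w$phantom, ptv = w$phantom$vois$PTV,
                             n_beams = 0), "n_beams")
  expect_error(generate_plan(w$phantom, ptv = w$phantom$vois$PTV,
                             total_mu = 0), "total_mu")
})

test_that("conformal segment opens every PTV-interior beamlet fully", {
  w <- tiny_world()
  for (b in seq_along(w$plan$beams)) {
    beam <- w$plan$beams[[b]]
    bg <- beam$bgrid
    wgt <- beamlet_weights(beam$segments[[1]]$aperture, bg)
    f <- trackdose:::beam_frame(beam$gantry_deg)
    pts <- voxel_centers(w$phantom$grid, voi_indices(w$phantom$vois$PTV))
    u <- as.numeric(pts %*% f$e_u)
    v <- pts[, 3]
    bc <- trackdose:::beamlet_centers(bg)
    # beamlets whose full extent lies inside the projected PTV point span of
    # their row must be fully open
    for (iv in seq_len(bg$nv)) {
      vin <- v >= bg$v_edges[iv] & v < bg$v_edges[iv + 1]
      if (!any(vin)) next
      idx <- (iv - 1L) * bg$nu + seq_len(bg$nu)
      interior <- bc$u[idx] - bg$u_res / 2 >= min(u[vin]) &
                  bc$u[idx] + bg$u_res / 2 <= max(u[vin])
      if (any(interior))
        expect_true(all(wgt[idx][interior] == 1))
    }
  }
})

test_that("dose influence follows the kernel closed form on the axis", {
  # box body: depth is a pure function of AP position, exact under the
  # 1 mm sampling because it divides the 3 mm AP spacing
  cfg <- phantom_config(
    dims = c(41, 60, 41), spacing = c(2.5, 3, 2.5),
    body = list(type = "full"),
    ctv = list(type = "ellipsoid", center = c(0, 0, 0), radii = c(15, 15, 15)),
    rectum = list(type = "cylinder_si", center = c(0, -25, 0),
                  radii = c(6, 6), half_length = 20),
    bladder = list(type = "ellipsoid", center = c(0, 26, 20),
                   radii = c(8, 8, 8)))
  ph <- build_phantom(cfg)
  kern <- dose_kernel()
  beam <- list(gantry_deg = 0, bgrid = beamlet_grid(ph, 0))
  di <- compute_dose_influence(ph, beam, kern)
  expect_true(all(di$D@x >= 0))
  # pick the beamlet centered at u = 2.5, v = 2.5 (a voxel-center column)
  bc <- trackdose:::beamlet_centers(di$bgrid)
  b <- which(bc$u == 2.5 & bc$v == 2.5)
  col <- as.numeric(di$D[, b])
  pts <- voxel_centers(ph$grid, di$region_idx)
  on_axis <- which(pts[, 1] == 2.5 & pts[, 3] == 2.5)
  on_axis <- on_axis[order(pts[on_axis, 2], decreasing = TRUE)]
  d_axis <- col[on_axis]
  expect_true(all(d_axis > 0))
  # successive voxels (3 mm deeper) decay by exactly exp(-mu * 3)
  expect_equal(d_axis[-1] / d_axis[-length(d_axis)],
               rep(exp(-kern$mu_mm * 3), length(d_axis) - 1),
               tolerance = 1e-12)
  # calibration: dose at the voxel nearest 100 mm depth matches the
  # configured cGy/MU within the depth-sampling quantization (0.5 mm)
  y_top <- ph$grid$origin[2] + (ph$grid$dims[2] - 0.5) * ph$grid$spacing[2]
  depth <- y_top - pts[on_axis, 2]
  k100 <- which.min(abs(depth - 100))
  expected <- kern$cal_cgy_per_mu * exp(-kern$mu_mm * (depth[k100] - 100))
  expect_lt(abs(d_axis[k100] - expected) / expected, 0.006)
})

test_that("dose influence columns are shift-invariant on the box phantom", {
  w <- box_world()
  di <- w$dij$beams[[1]] # gantry 0: u = +x, one beamlet pitch = 2 voxels
  grid <- w$phantom$grid
  bg <- di$bgrid
  dense <- function(b) {
    v <- numeric(prod(grid$dims))
    v[di$region_idx] <- as.numeric(di$D[, b])
    array(v, grid$dims)
  }
  reg <- array(FALSE, grid$dims); reg[di$region_idx] <- TRUE
  b <- which(trackdose:::beamlet_centers(bg)$u == 2.5 &
             trackdose:::beamlet_centers(bg)$v == 2.5)
  a0 <- dense(b); a1 <- dense(b + 1L) # neighbour in u
  # a1 shifted back by one beamlet pitch (2 voxels in x) must equal a0
  nx <- grid$dims[1]
  src <- 3:nx; dst <- 1:(nx - 2)
  both <- reg[dst, , ] & reg[src, , ]
  expect_true(sum(both) > 1000)
  expect_identical(a1[src, , ][both], a0[dst, , ][both])
})

test_that("planned dose is zero outside the calculation region", {
  w <- tiny_world()
  pd <- planned_dose(w$plan, w$dij)
  outside <- setdiff(seq_along(pd), w$dij$region_idx)
  expect_true(all(pd[outside] == 0))
  expect_true(all(pd >= 0))
  expect_gt(max(pd), 0)
})
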