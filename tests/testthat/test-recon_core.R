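test_that("beamlet weights: open, covered, bisected and row alignment", {
  v_edges <- seq(-10, 10, by = 5)
  bg <- structure(list(u_edges = seq(-10, 10, by = 5), v_edges = v_edges,
                       nu = 4L, nv = 4L, u_res = 5, leaf_width = 5,
                       gantry_deg = 0),
                  class = "beamlet_grid")
  tips <- rbind(c(-10, 10), c(-10, 10), c(-2.5, 10), c(0, 0))
  ap <- aperture(tips, c(-10, 10), v_edges)
  w <- beamlet_weights(ap, bg)
  m <- matrix(w, nrow = bg$nu) # [iu, iv]
  expect_true(all(m[, 1] == 1))         # fully open row
  expect_true(all(m[, 4] == 0))         # closed row
  expect_equal(m[1, 3], 0)              # behind the left tip
  expect_equal(m[2, 3], 0.5)            # tip bisects the beamlet: exactly 0.5
  # jaw bisecting a row halves its weights
  ap2 <- aperture(tips, c(-10, 2.5), v_edges)
  w2 <- beamlet_weights(ap2, bg)
  expect_equal(matrix(w2, nrow = bg$nu)[, 3],
               0.5 * matrix(w, nrow = bg$nu)[, 3])
  expect_error(beamlet_weights(aperture(tips[1:3, ], c(-10, 10),
                                        v_edges[1:4]), bg), "aligned")
})

test_that("beamlet weights agree with the area sub-sampling oracle", {
  v_edges <- seq(-20, 20, by = 5)
  bg <- structure(list(u_edges = seq(-20, 20, by = 5), v_edges = v_edges,
                       nu = 8L, nv = 8L, u_res = 5, leaf_width = 5,
                       gantry_deg = 0),
                  class = "beamlet_grid")
  for (seed in 1:25) {
    ap <- random_lattice_aperture(bg, seed)
    expect_lt(max(abs(beamlet_weights(ap, bg) -
                        oracle_weights_subsample(ap, bg))), 1e-3)
  }
})

test_that("aperture_dose_increment matches a dense matrix-vector oracle", {
  w <- tiny_world()
  dj <- w$dij$beams[[1]]
  dense <- as.matrix(dj$D)
  with_seed(13, {
    for (i in 1:5) {
      wt <- stats::runif(ncol(dense))
      mu <- stats::runif(1, 0, 50)
      expect_equal(aperture_dose_increment(wt, dj, mu),
                   as.numeric(dense %*% wt) * mu, tolerance = 1e-10)
    }
  })
  wt <- numeric(ncol(dense)); wt[7] <- 1
  expect_equal(aperture_dose_increment(wt, dj, 1), dense[, 7])
  expect_equal(aperture_dose_increment(wt, dj, 0), numeric(nrow(dense)))
  expect_error(aperture_dose_increment(numeric(3), dj, 1), "beamlet")
})

test_that("static reconstruction reproduces the planned dose", {
  w <- tiny_world()
  rec <- simulate_delivery(w$plan, "static", timing = w$timing)
  res <- reconstruct(rec, NULL, w$phantom, w$plan, w$dij)
  pd <- planned_dose(w$plan, w$dij)
  expect_lt(max(abs(res$static_dose - pd)) / max(pd), 1e-9)
  expect_equal(res$mu_processed, w$plan$total_mu, tolerance = 1e-9)
  # zero displacement: target vector equals static dose on the target
  expect_equal(res$target_dose, res$static_dose[res$target_idx])
})

test_that("conventional mode with zero trajectory equals static bitwise", {
  w <- tiny_world()
  rec_s <- simulate_delivery(w$plan, "static", timing = w$timing)
  zero <- constant_trajectory(c(0, 0, 0), rec_s)
  rec_c <- simulate_delivery(w$plan, "conventional", zero, timing = w$timing)
  res_s <- reconstruct(rec_s, NULL, w$phantom, w$plan, w$dij)
  res_c <- reconstruct(rec_c, zero, w$phantom, w$plan, w$dij)
  expect_identical(res_c$static_dose, res_s$static_dose)
  expect_identical(res_c$target_dose, res_s$target_dose)
})

test_that("integer-voxel displacement samples the shifted grid exactly", {
  w <- tiny_world()
  grid <- w$phantom$grid
  rec <- simulate_delivery(w$plan, "static", timing = w$timing)
  d <- c(grid$spacing[1], 0, -grid$spacing[3]) # exactly one voxel pitch
  tr <- constant_trajectory(d, rec)
  rec_c <- simulate_delivery(w$plan, "conventional", tr, timing = w$timing)
  res <- reconstruct(rec_c, tr, w$phantom, w$plan, w$dij)
  shifted_idx <- trackdose:::ijk_to_linear(
    grid, sweep(arrayInd(res$target_idx, grid$dims), 2, c(1L, 0L, -1L), "+"))
  expect_identical(res$target_dose, res$static_dose[shifted_idx])
})

test_that("out-of-region samples contribute zero and are counted", {
  w <- tiny_world()
  rec <- simulate_delivery(w$plan, "static", timing = w$timing)
  big <- constant_trajectory(c(60, 0, 0), rec) # way outside the region
  rec_c <- simulate_delivery(w$plan, "conventional", big, timing = w$timing)
  res <- reconstruct(rec_c, big, w$phantom, w$plan, w$dij)
  expect_gt(res$n_out_of_region, 0)
  expect_true(all(res$target_dose == 0))
})

test_that("rotating a symmetric dose about its centre leaves the DVH alone", {
  # synthetic spherically symmetric increment field, spherical target
  g <- grid_spec(c(31, 31, 31), c(2, 2, 2))
  p <- voxel_centers(g)
  r2 <- rowSums(p^2)
  field <- exp(-r2 / 800)
  target <- r2 <= 14^2
  region_idx <- which(r2 <= 28^2)
  region_mask <- logical(prod(g$dims)); region_mask[region_idx] <- TRUE
  t_idx <- which(target)
  t_ijk0 <- arrayInd(t_idx, g$dims) - 1L
  storage.mode(t_ijk0) <- "integer"
  base <- list(static_dose = numeric(prod(g$dims)),
               target_dose = numeric(length(t_idx)), target_idx = t_idx,
               mu_processed = 0, n_out_of_region = 0L)
  no_rot <- trackdose:::accumulate_increment(
    base, field[region_idx], g, region_idx, region_mask, c(0, 0, 0), NULL,
    "mlc_voi", p[t_idx, ], t_ijk0)
  rot <- trackdose:::accumulate_increment(
    base, field[region_idx], g, region_idx, region_mask, c(0, 0, 0),
    rotation_spec(17, -9, pivot = c(0, 0, 0)), "mlc_voi", p[t_idx, ], t_ijk0)
  dvh0 <- cumulative_dvh(no_rot$target_dose, voi("T", target, g), g)
  dvh1 <- cumulative_dvh(rot$target_dose, voi("T", target, g), g)
  expect_lt(abs(dose_at_volume(dvh1, 98) - dose_at_volume(dvh0, 98)) /
              dose_at_volume(dvh0, 98), 0.01)
})

test_that("CTV D98 degrades monotonically with posterior offset", {
  w <- tiny_world()
  # lateral beam (gantry 90): posterior displacement runs along leaf travel,
  # so an uncompensated offset drags the target across the field edge
  plan <- generate_plan(w$phantom, ptv = w$phantom$vois$PTV, n_beams = 1,
                        segments_per_beam = 1, total_mu = 30,
                        min_area_cm2 = 1, seed = 1, gantry_start = 90)
  dij <- compute_dij_store(w$phantom, plan, region_margin_mm = 20)
  rec_s <- simulate_delivery(plan, "static", timing = w$timing)
  d98 <- vapply(c(0, 2, 4, 6, 8), function(off) {
    res <- reconstruct(rec_s, NULL, w$phantom, plan, dij,
                       offset = c(0, -off, 0))
    m <- voi_metrics(res, w$phantom)
    m$ctv_d98_cgy
  }, numeric(1))
  expect_true(all(diff(d98) <= 1e-9))
  expect_lt(d98[5], d98[1]) # strictly lower well beyond the margin
})

test_that("per-aperture cost does not grow with processed history", {
  w <- tiny_world()
  timing <- timing_config(aperture_interval_s = 0.1, hold_s = 1,
                          dose_rate_mu_min = 300)
  rec <- associate_machine_state(
    simulate_delivery(w$plan, "static", timing = timing))
  half <- rec
  half$apertures <- rec$apertures[seq_len(length(rec$apertures) %/% 2)]
  run <- function(r) {
    t0 <- proc.time()[["elapsed"]]
    reconstruct(r, NULL, w$phantom, w$plan, w$dij)
    (proc.time()[["elapsed"]] - t0)
  }
  run(half) # warm-up
  t_half <- run(half) / length(half$apertures)
  t_full <- run(rec) / length(rec$apertures)
  expect_lt(t_full / max(t_half, 1e-6), 3)
})

test_that("sweeps enumerate their grids and agree at the neutral element", {
  w <- tiny_world()
  tr <- generate_trajectory("continuous_drift", 8, 25, seed = 5)
  rec_c <- simulate_delivery(w$plan, "conventional", tr, timing = w$timing)
  rec_s <- simulate_delivery(w$plan, "static", timing = w$timing)
  offs <- offset_grid(1, 1) # 27 offsets: the full grid is an acceptance case
  tab <- sweep_offsets(rec_c, rec_s, tr, w$phantom, w$plan, w$dij, offs)
  expect_equal(nrow(tab), 27)
  base <- reconstruct(associate_machine_state(rec_c), tr, w$phantom, w$plan,
                      w$dij)
  m0 <- voi_metrics(base, w$phantom)
  zero_row <- tab[tab$d_lr_mm == 0 & tab$d_ap_mm == 0 & tab$d_si_mm == 0, ]
  expect_equal(zero_row$ctv_d98_cgy, m0$ctv_d98_cgy, tolerance = 1e-12)
  expect_error(sweep_offsets(rec_s, rec_s, tr, w$phantom, w$plan, w$dij,
                             offs), "conventional")

  rec_t <- simulate_delivery(w$plan, "tracked", tr,
                             latency_model(0, 0, seed = 1), w$timing)
  rots <- rotation_grid(c(-8, 0, 8), c(-8, 0, 8))
  rtab <- sweep_rotations(rec_t, tr, w$phantom, w$plan, w$dij, rots)
  expect_equal(nrow(rtab), 9)
  base_t <- reconstruct(associate_machine_state(rec_t), tr, w$phantom,
                        w$plan, w$dij)
  mt <- voi_metrics(base_t, w$phantom)
  zr <- rtab[rtab$pitch_deg == 0 & rtab$roll_deg == 0, ]
  expect_equal(zr$ctv_d98_cgy, mt$ctv_d98_cgy, tolerance = 1e-12)
  expect_error(sweep_rotations(rec_c, tr, w$phantom, w$plan, w$dij, rots),
               "tracked")
})
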