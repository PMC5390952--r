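# Shared fixtures, built once per test session and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Tiny pelvic phantom (24^3 @ 4 mm) with a 2-beam single-segment plan:
# fast enough for per-operation tests and sweeps.
tiny_world <- function() fixture("tiny", function() {
  cfg <- phantom_config(
    dims = c(24, 24, 24), spacing = c(4, 4, 4),
    body = list(type = "full"),
    ctv = list(type = "ellipsoid", center = c(0, 0, 0), radii = c(12, 11, 10)),
    rectum = list(type = "cylinder_si", center = c(0, -22, 0),
                  radii = c(7, 6), half_length = 24),
    bladder = list(type = "ellipsoid", center = c(0, 22, 16),
                   radii = c(9, 8, 8)))
  ph <- build_phantom(cfg)
  ph <- add_voi(ph, expand_margin(ph$vois$CTV, margin_spec(1), ph$grid,
                                  "PTV"))
  plan <- generate_plan(ph, n_beams = 2, segments_per_beam = 1,
                        total_mu = 30, min_area_cm2 = 1, seed = 4)
  dij <- compute_dij_store(ph, plan, region_margin_mm = 20)
  timing <- timing_config(aperture_interval_s = 0.5, hold_s = 1,
                          dose_rate_mu_min = 600)
  list(phantom = ph, plan = plan, dij = dij, timing = timing)
})

# Box-body phantom on a 2.5 mm grid with opposed beams (gantry 0/180):
# grid-commensurate shifts make tracking equivalences exact.
box_world <- function() fixture("box", function() {
  cfg <- phantom_config(
    dims = c(40, 40, 40), spacing = c(2.5, 2.5, 2.5),
    body = list(type = "full"),
    ctv = list(type = "ellipsoid", center = c(0, 0, 0), radii = c(15, 15, 12)),
    rectum = list(type = "cylinder_si", center = c(0, -25, 0),
                  radii = c(8, 7), half_length = 30),
    bladder = list(type = "ellipsoid", center = c(0, 27, 22),
                   radii = c(10, 9, 9)))
  ph <- build_phantom(cfg)
  ph <- add_voi(ph, voi("PTV", ph$vois$CTV$mask, ph$grid))
  plan <- generate_plan(ph, n_beams = 2, segments_per_beam = 1,
                        total_mu = 60, seed = 3)
  dij <- compute_dij_store(ph, plan)
  timing <- timing_config(dose_rate_mu_min = 600, hold_s = 1)
  list(phantom = ph, plan = plan, dij = dij, timing = timing)
})

# Default-scale world (50^3 @ 3 mm, 7 beams x 3 segments, 1 mm margin,
# prescription-normalized): the acceptance-criteria workload.
default_world <- function() fixture("default", function() {
  ph <- build_phantom()
  ph <- add_voi(ph, expand_margin(ph$vois$CTV, margin_spec(1), ph$grid,
                                  "PTV"))
  plan <- generate_plan(ph, n_beams = 7, segments_per_beam = 3,
                        total_mu = 1000, seed = 2)
  dij <- compute_dij_store(ph, plan)
  plan <- normalize_plan_mu(plan, dij, ph, "PTV", 95, 725)
  list(phantom = ph, plan = plan, dij = dij, timing = timing_config())
})

# constant-displacement trajectory covering a delivery record
constant_trajectory <- function(d, record, rate_hz = 25) {
  t_end <- record$states$t_s[nrow(record$states)] + 1
  ts <- seq(0, t_end, by = 1 / rate_hz)
  trajectory(ts, matrix(rep(d, each = length(ts)), ncol = 3))
}

# random apertures with tips/jaws on a 0.01 mm lattice (the reporting
# precision of the delivery log, and the lattice of the area oracle)
random_lattice_aperture <- function(bg, seed) {
  with_seed(seed, {
    nv <- bg$nv
    u_lo <- bg$u_edges[1]
    u_hi <- bg$u_edges[length(bg$u_edges)]
    tips <- matrix(0, nv, 2)
    for (iv in seq_len(nv)) {
      if (stats::runif(1) < 0.2) next # closed row
      a <- round(stats::runif(2, u_lo, u_hi), 2)
      tips[iv, ] <- sort(a)
    }
    v_lo <- bg$v_edges[1]
    v_hi <- bg$v_edges[length(bg$v_edges)]
    jaws <- sort(round(stats::runif(2, v_lo, v_hi), 2))
    aperture(tips, jaws, bg$v_edges, bg$leaf_width)
  })
}

# independent area oracle: midpoint sub-sampling on the 0.01 mm lattice
oracle_weights_subsample <- function(ap, bg, h = 0.01) {
  um <- lapply(seq_len(bg$nu), function(iu)
    seq(bg$u_edges[iu] + h / 2, bg$u_edges[iu + 1] - h / 2, by = h))
  vm <- lapply(seq_len(bg$nv), function(iv)
    seq(bg$v_edges[iv] + h / 2, bg$v_edges[iv + 1] - h / 2, by = h))
  w <- numeric(bg$nu * bg$nv)
  for (iv in seq_len(bg$nv)) {
    fv <- mean(vm[[iv]] > ap$y_jaws[1] & vm[[iv]] < ap$y_jaws[2])
    L <- ap$tips[iv, 1]; R <- ap$tips[iv, 2]
    if (fv == 0 || R <= L) next
    for (iu in seq_len(bg$nu)) {
      fu <- mean(um[[iu]] > L & um[[iu]] < R)
      w[(iv - 1L) * bg$nu + iu] <- fu * fv
    }
  }
  w
}

# strip aperture streams down to comparable numeric form
stream_signature <- function(record) {
  lapply(record$apertures, function(r)
    list(t = r$t_s, tips = r$aperture$tips, jaws = r$aperture$y_jaws))
}
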