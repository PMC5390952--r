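# One CSV dialect everywhere: comma separator, "." decimal, header row,
# numbers written with 17 significant digits so write -> read -> write is
# byte-stable and numerically exact.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

read_csv_strict <- function(path, expected_header) {
  lines <- readLines(path)
  if (!length(lines)) stop(sprintf("%s: empty file", basename(path)))
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!is.null(expected_header) &&
      !identical(header[seq_along(expected_header)], expected_header))
    stop(sprintf("%s: unexpected header '%s'", basename(path), lines[1]))
  n_fields <- length(header)
  rows <- vector("list", length(lines) - 1L)
  for (i in seq_along(rows)) {
    f <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    if (length(f) != n_fields)
      stop(sprintf("%s: malformed row at line %d", basename(path), i + 1L))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v) & f != ""))
      stop(sprintf("%s: non-numeric field at line %d", basename(path),
                   i + 1L))
    rows[[i]] <- v
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(numeric(0), 0, n_fields)
  colnames(m) <- header
  m
}

#' Write a trajectory to CSV
#'
#' Header `t_s,d_lr_mm,d_ap_mm,d_si_mm`, one row per sample.
#'
#' @param traj a [trajectory()]. @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  lines <- c("t_s,d_lr_mm,d_ap_mm,d_si_mm",
             paste(fmt_num(traj$t_s), fmt_num(traj$d_lr_mm),
                   fmt_num(traj$d_ap_mm), fmt_num(traj$d_si_mm), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' Validates the header, field counts (reporting the first bad line) and the
#' uniform sample spacing.
#'
#' @param path CSV file written by [write_trajectory_csv()].
#' @return a [trajectory()].
#' @export
read_trajectory_csv <- function(path) {
  m <- read_csv_strict(path, c("t_s", "d_lr_mm", "d_ap_mm", "d_si_mm"))
  trajectory(m[, 1], m[, 2:4, drop = FALSE])
}

#' Write a delivery record to a directory container
#'
#' Plain-text container: `meta.json` (mode, timing, per-beam leaf row edges),
#' `apertures.csv`
#' (`t_s,beam,segment,shift_u_mm,shift_v_mm,clamped,vmin_mm,vmax_mm,`
#' `rowNN_left_mm,rowNN_right_mm,...`, rows padded to the widest beam) and
#' `states.csv` (`t_s,cum_mu,dose_rate,gantry_deg,beam_on`).
#'
#' @param record a [simulate_delivery()] record. @param dir output directory.
#' @export
write_delivery_record <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  beams <- unique(vapply(record$apertures, `[[`, numeric(1), "beam"))
  v_edges <- lapply(sort(beams), function(b) {
    rp <- record$apertures[[which(vapply(record$apertures, `[[`, numeric(1),
                                         "beam") == b)[1]]]
    rp$aperture$v_edges
  })
  meta <- list(mode = record$mode, total_mu = record$total_mu,
               timing = unclass(record$timing),
               beam_v_edges = v_edges,
               traj_meta = record$traj_meta,
               latency = if (!is.null(record$latency))
                 unclass(record$latency) else NULL)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  max_nv <- max(vapply(record$apertures,
                       function(r) nrow(r$aperture$tips), integer(1)))
  hdr <- c("t_s", "beam", "segment", "shift_u_mm", "shift_v_mm", "clamped",
           "vmin_mm", "vmax_mm",
           as.vector(rbind(sprintf("row%02d_left_mm", seq_len(max_nv)),
                           sprintf("row%02d_right_mm", seq_len(max_nv)))))
  lines <- vapply(record$apertures, function(r) {
    tips <- r$aperture$tips
    pad <- max_nv - nrow(tips)
    if (pad > 0) tips <- rbind(tips, matrix(NA_real_, pad, 2))
    paste(c(fmt_num(r$t_s), fmt_num(r$beam), fmt_num(r$segment),
            fmt_num(r$shift[1]), fmt_num(r$shift[2]),
            fmt_num(as.numeric(r$clamped)),
            fmt_num(r$aperture$y_jaws[1]), fmt_num(r$aperture$y_jaws[2]),
            fmt_num(as.vector(t(tips)))), collapse = ",")
  }, character(1))
  writeLines(c(paste(hdr, collapse = ","), lines),
             file.path(dir, "apertures.csv"))
  st <- record$states
  writeLines(c("t_s,cum_mu,dose_rate,gantry_deg,beam_on",
               paste(fmt_num(st$t_s), fmt_num(st$cum_mu),
                     fmt_num(st$dose_rate), fmt_num(st$gantry_deg),
                     fmt_num(as.numeric(st$beam_on)), sep = ",")),
             file.path(dir, "states.csv"))
  invisible(dir)
}

#' Read a delivery record container
#'
#' @param dir directory written by [write_delivery_record()].
#' @return a `delivery_record`.
#' @export
read_delivery_record <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ap <- read_csv_strict(file.path(dir, "apertures.csv"), NULL)
  st <- read_csv_strict(file.path(dir, "states.csv"),
                        c("t_s", "cum_mu", "dose_rate", "gantry_deg",
                          "beam_on"))
  v_edges <- meta$beam_v_edges
  if (is.matrix(v_edges)) # jsonlite simplifies equal-length lists
    v_edges <- lapply(seq_len(nrow(v_edges)), function(i) v_edges[i, ])
  reports <- vector("list", nrow(ap))
  for (i in seq_len(nrow(ap))) {
    b <- as.integer(ap[i, "beam"])
    ve <- as.numeric(v_edges[[b]])
    nv <- length(ve) - 1L
    tips <- matrix(ap[i, 8L + seq_len(2L * nv)], ncol = 2, byrow = TRUE)
    reports[[i]] <- list(
      t_s = ap[i, "t_s"], beam = b, segment = as.integer(ap[i, "segment"]),
      aperture = aperture(tips, c(ap[i, "vmin_mm"], ap[i, "vmax_mm"]), ve),
      shift = c(ap[i, "shift_u_mm"], ap[i, "shift_v_mm"]),
      clamped = ap[i, "clamped"] != 0)
  }
  timing <- do.call(timing_config, meta$timing)
  structure(list(mode = meta$mode, apertures = reports,
                 states = data.frame(t_s = st[, 1], cum_mu = st[, 2],
                                     dose_rate = st[, 3],
                                     gantry_deg = st[, 4],
                                     beam_on = st[, 5] != 0),
                 timing = timing, total_mu = meta$total_mu,
                 traj_meta = meta$traj_meta,
                 latency = if (!is.null(meta$latency))
                   do.call(latency_model, meta$latency) else NULL),
            class = "delivery_record")
}

#' Write a reconstruction result container
#'
#' Plain-text container: `meta.json` plus `static_dose.csv` (non-zero voxels)
#' and `target_dose.csv` (dose over the moving target VOI voxels).
#'
#' @param result a [reconstruct()] result. @param dir output directory.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(mode = result$mode, method = result$method,
               target_voi = result$target_voi,
               mu_processed = result$mu_processed,
               n_out_of_region = result$n_out_of_region,
               offset = result$offset, rotation = as.list(result$rotation),
               grid = list(dims = result$grid$dims,
                           spacing = result$grid$spacing,
                           origin = result$grid$origin))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  nz <- which(result$static_dose != 0)
  writeLines(c("voxel_index,dose_cgy",
               paste(fmt_num(nz), fmt_num(result$static_dose[nz]),
                     sep = ",")),
             file.path(dir, "static_dose.csv"))
  writeLines(c("voxel_index,dose_cgy",
               paste(fmt_num(result$target_idx),
                     fmt_num(result$target_dose), sep = ",")),
             file.path(dir, "target_dose.csv"))
  invisible(dir)
}

#' Read a reconstruction result container
#'
#' @param dir directory written by [write_result()].
#' @return a partial `recon_result` (dose vectors + metadata; per-VOI
#'   vectors are re-derivable given the phantom).
#' @export
read_result <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  grid <- grid_spec(meta$grid$dims, meta$grid$spacing, meta$grid$origin)
  sd <- read_csv_strict(file.path(dir, "static_dose.csv"),
                        c("voxel_index", "dose_cgy"))
  td <- read_csv_strict(file.path(dir, "target_dose.csv"),
                        c("voxel_index", "dose_cgy"))
  static_dose <- numeric(n_voxels(grid))
  static_dose[as.integer(sd[, 1])] <- sd[, 2]
  structure(list(static_dose = static_dose, target_dose = td[, 2],
                 target_idx = as.integer(td[, 1]),
                 target_voi = meta$target_voi,
                 mu_processed = meta$mu_processed,
                 n_out_of_region = meta$n_out_of_region,
                 method = meta$method, mode = meta$mode,
                 offset = as.numeric(meta$offset),
                 rotation = unlist(meta$rotation), grid = grid),
            class = "recon_result")
}

#' Write the phantom/plan/dose-influence bundle
#'
#' Plain-text stand-in for a binary container: `meta.json` (grid, kernel,
#' plan geometry), `voi_<name>.csv` mask index lists, and one MatrixMarket
#' `dij_beam<k>.mtx` per beam plus `region_idx.csv`.
#'
#' @param phantom,plan,dij the objects to persist (dij may be NULL).
#' @param dir output directory.
#' @export
write_bundle <- function(phantom, plan, dij = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plan_meta <- list(
    iso = plan$iso, total_mu = plan$total_mu, u_res = plan$u_res,
    ptv_name = plan$ptv_name, seed = plan$seed,
    beams = lapply(plan$beams, function(b) list(
      gantry_deg = b$gantry_deg,
      u_edges = b$bgrid$u_edges, v_edges = b$bgrid$v_edges,
      segments = lapply(b$segments, function(s) list(
        planned_mu = s$planned_mu, y_jaws = s$aperture$y_jaws,
        tips = s$aperture$tips)))))
  meta <- list(grid = list(dims = phantom$grid$dims,
                           spacing = phantom$grid$spacing,
                           origin = phantom$grid$origin),
               phantom_config = phantom$config[names(phantom$config) !=
                                                 "grid"],
               plan = plan_meta,
               kernel = if (!is.null(dij)) unclass(dij$kernel) else NULL,
               region_margin_mm = if (!is.null(dij)) dij$region_margin_mm
                                  else NULL)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  for (v in phantom$vois)
    writeLines(c("voxel_index",
                 fmt_num(which(v$mask))),
               file.path(dir, sprintf("voi_%s.csv", v$name)))
  if (!is.null(dij)) {
    writeLines(c("voxel_index", fmt_num(dij$region_idx)),
               file.path(dir, "region_idx.csv"))
    for (k in seq_along(dij$beams))
      Matrix::writeMM(dij$beams[[k]]$D,
                      file.path(dir, sprintf("dij_beam%02d.mtx", k)))
  }
  invisible(dir)
}

# Run configuration ---------------------------------------------------------

#' Default run configuration
#'
#' The configuration schema of the command-line front-end: phantom geometry,
#' plan parameters, beamlet resolution, trajectory spec, latency, timing,
#' mode/method and a single global seed that determines every artifact.
#' Demo-scale by default (a reduced phantom so the full triptych runs in
#' about a minute).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    phantom = list(dims = c(40, 40, 40), spacing = c(3, 3, 3),
                   body = list(type = "ellipsoid", center = c(0, 0, 0),
                               radii = c(56, 54, 57)),
                   ctv = list(type = "ellipsoid", center = c(0, 0, 0),
                              radii = c(18, 16, 15)),
                   rectum = list(type = "cylinder_si", center = c(0, -30, 0),
                                 radii = c(10, 9), half_length = 35),
                   bladder = list(type = "ellipsoid", center = c(0, 33, 27),
                                  radii = c(13, 11, 11))),
    margin = list(isotropic_mm = 3, posterior_mm = NULL),
    plan = list(n_beams = 7, segments_per_beam = 2, total_mu = 400,
                min_area_cm2 = 4),
    beamlet = list(u_res = 5),
    kernel = list(mu_mm = 0.005, sigma_mm = 3, cal_cgy_per_mu = 0.25,
                  cal_depth_mm = 100, step_mm = 1),
    trajectory = list(archetype = "continuous_drift", duration_s = 120,
                      rate_hz = 25),
    latency = list(mean_ms = 100, sd_ms = 15),
    timing = list(aperture_interval_s = 0.04, state_interval_s = 0.02,
                  hold_s = 2, dose_rate_mu_min = 600),
    mode = "tracked", method = "mlc_voi",
    prescription_cgy = 725,
    sweep = list(offset_half_range_mm = 3, offset_step_mm = 1,
                 rotation_range_deg = 20, rotation_step_deg = 4))
}

#' Validate a run configuration
#'
#' Checks types and supported values; errors name the offending key
#' (e.g. `beamlet.u_res`).
#'
#' @param config nested configuration list (missing entries take defaults).
#' @return the completed configuration, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  base <- default_config()
  config <- utils::modifyList(base, config, keep.null = TRUE)
  if (!config$beamlet$u_res %in% c(5, 2.5, 1.25))
    stop("config error at key 'beamlet.u_res': must be one of 5, 2.5, 1.25")
  if (!config$mode %in% c("static", "conventional", "tracked"))
    stop("config error at key 'mode': must be static, conventional or tracked")
  if (!config$method %in% c("mlc_voi", "mlc_only"))
    stop("config error at key 'method': must be mlc_voi or mlc_only")
  if (!config$trajectory$archetype %in%
        c("continuous_drift", "erratic", "high_frequency", "stable"))
    stop("config error at key 'trajectory.archetype': unknown archetype")
  if (config$latency$mean_ms < 0 || config$latency$sd_ms < 0)
    stop("config error at key 'latency': parameters must be >= 0")
  if (config$plan$total_mu <= 0)
    stop("config error at key 'plan.total_mu': must be > 0")
  if (config$timing$dose_rate_mu_min <= 0)
    stop("config error at key 'timing.dose_rate_mu_min': must be > 0")
  if (!is.numeric(config$seed) || length(config$seed) != 1)
    stop("config error at key 'seed': a single integer seed is required")
  config
}

#' Read and validate a JSON run configuration
#'
#' @param path JSON file; missing entries take [default_config()] values.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}
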