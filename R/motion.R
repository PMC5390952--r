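#' Generate an intrafraction prostate motion trajectory
#'
#' Produces a seeded, uniformly sampled 3D displacement trajectory (mm,
#' relative to the planning position) emulating one of four qualitative
#' archetypes of recorded prostate motion:
#' \describe{
#'   \item{continuous_drift}{monotone posterior + inferior baseline drift
#'     plus small correlated noise}
#'   \item{erratic}{the same drift plus sparse sudden transients, mostly
#'     anterior}
#'   \item{high_frequency}{slow anterior + superior drift plus frequent short
#'     transients anteriorly/superiorly}
#'   \item{stable}{small zero-mean noise, bounded by `stable_amp_mm`}
#' }
#' Axes: LR = +x (left), AP = +y (anterior), SI = +z (superior).
#'
#' @param archetype one of `"continuous_drift"`, `"erratic"`,
#'   `"high_frequency"`, `"stable"`.
#' @param duration_s trajectory length in seconds.
#' @param rate_hz sampling rate (default 25 Hz).
#' @param seed integer seed; the trajectory is bit-reproducible per
#'   (archetype, seed, duration, rate).
#' @param params optional overrides of the archetype parameters, see
#'   [trajectory_params()].
#' @return object of class `trajectory`: data.frame with columns
#'   `t_s, d_lr_mm, d_ap_mm, d_si_mm` plus attributes.
#' @export
generate_trajectory <- function(archetype, duration_s, rate_hz = 25, seed = 1,
                                params = list()) {
  archetypes <- c("continuous_drift", "erratic", "high_frequency", "stable")
  if (!archetype %in% archetypes)
    stop("unknown trajectory archetype: ", archetype)
  if (duration_s <= 0 || rate_hz <= 0)
    stop("duration and rate must be > 0")
  p <- utils::modifyList(trajectory_params(archetype), params)
  n <- floor(duration_s * rate_hz) + 1L
  t <- (seq_len(n) - 1L) / rate_hz
  dt <- 1 / rate_hz

  with_seed(derive_seed(seed, 101L), {
    ar_noise <- function(sd_mm, phi = 0.98) {
      e <- stats::rnorm(n, 0, sd_mm * sqrt(1 - phi^2))
      as.numeric(stats::filter(e, phi, method = "recursive"))
    }
    transients <- function(rate_per_min, amp_lo, amp_hi, tau_s) {
      x <- numeric(n)
      n_ev <- stats::rpois(1, rate_per_min * duration_s / 60)
      if (n_ev > 0) {
        t_ev <- sort(stats::runif(n_ev, 0, duration_s))
        amp <- stats::runif(n_ev, amp_lo, amp_hi)
        for (e in seq_len(n_ev)) {
          after <- t >= t_ev[e]
          x[after] <- x[after] + amp[e] * exp(-(t[after] - t_ev[e]) / tau_s)
        }
      }
      x
    }
    d <- switch(archetype,
      continuous_drift = cbind(
        ar_noise(p$noise_sd_mm),
        p$drift_ap_mm_min * t / 60 + ar_noise(p$noise_sd_mm),
        p$drift_si_mm_min * t / 60 + ar_noise(p$noise_sd_mm)),
      erratic = cbind(
        ar_noise(p$noise_sd_mm),
        p$drift_ap_mm_min * t / 60 + ar_noise(p$noise_sd_mm) +
          transients(p$transient_per_min, p$transient_amp_mm[1],
                     p$transient_amp_mm[2], p$transient_tau_s),
        p$drift_si_mm_min * t / 60 + ar_noise(p$noise_sd_mm) +
          0.3 * transients(p$transient_per_min, p$transient_amp_mm[1],
                           p$transient_amp_mm[2], p$transient_tau_s)),
      high_frequency = cbind(
        ar_noise(p$noise_sd_mm),
        p$drift_ap_mm_min * t / 60 + ar_noise(p$noise_sd_mm) +
          transients(p$transient_per_min, p$transient_amp_mm[1],
                     p$transient_amp_mm[2], p$transient_tau_s),
        p$drift_si_mm_min * t / 60 + ar_noise(p$noise_sd_mm) +
          transients(p$transient_per_min, p$transient_amp_mm[1],
                     p$transient_amp_mm[2], p$transient_tau_s)),
      stable = {
        x <- cbind(ar_noise(p$noise_sd_mm), ar_noise(p$noise_sd_mm),
                   ar_noise(p$noise_sd_mm))
        pmin(pmax(x, -p$stable_amp_mm), p$stable_amp_mm)
      })
    trajectory(t, d, archetype = archetype, rate_hz = rate_hz, seed = seed)
  })
}

#' Default archetype parameters
#'
#' Drift velocities, transient rates/amplitudes and noise levels per motion
#' archetype. Values are this package's stated emulation of typical recorded
#' prostate motion: slow drifts of a few mm over several minutes, transients
#' of a few mm lasting seconds, sub-mm noise.
#'
#' @param archetype archetype name.
#' @return list of parameters (units in the names).
#' @export
trajectory_params <- function(archetype) {
  switch(archetype,
    continuous_drift = list(drift_ap_mm_min = -0.6, drift_si_mm_min = -0.4,
                            noise_sd_mm = 0.15),
    erratic = list(drift_ap_mm_min = -0.6, drift_si_mm_min = -0.4,
                   noise_sd_mm = 0.15, transient_per_min = 1.5,
                   transient_amp_mm = c(2, 5), transient_tau_s = 10),
    high_frequency = list(drift_ap_mm_min = 0.3, drift_si_mm_min = 0.3,
                          noise_sd_mm = 0.15, transient_per_min = 6,
                          transient_amp_mm = c(1, 3), transient_tau_s = 2.5),
    stable = list(noise_sd_mm = 0.25, stable_amp_mm = 1),
    stop("unknown trajectory archetype: ", archetype))
}

#' Construct a trajectory from samples
#'
#' @param t_s strictly increasing, uniformly spaced times in seconds.
#' @param d `n x 3` displacement matrix in mm (LR, AP, SI).
#' @param archetype,rate_hz,seed provenance attributes.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(t_s, d, archetype = "custom", rate_hz = NULL,
                       seed = NA) {
  d <- rbind(d)
  if (length(t_s) != nrow(d)) stop("trajectory: times and samples differ")
  if (length(t_s) > 1) {
    dt <- diff(t_s)
    if (any(dt <= 0)) stop("trajectory: timestamps must strictly increase")
    if (max(dt) - min(dt) > 1e-9)
      stop("trajectory: sampling must be uniform")
    if (is.null(rate_hz)) rate_hz <- 1 / dt[1]
  }
  if (any(!is.finite(d))) stop("trajectory: non-finite displacement")
  out <- data.frame(t_s = t_s, d_lr_mm = d[, 1], d_ap_mm = d[, 2],
                    d_si_mm = d[, 3])
  attr(out, "archetype") <- archetype
  attr(out, "rate_hz") <- rate_hz
  attr(out, "seed") <- seed
  class(out) <- c("trajectory", "data.frame")
  out
}

traj_matrix <- function(traj) {
  cbind(traj$d_lr_mm, traj$d_ap_mm, traj$d_si_mm)
}

# nearest sample index, ties toward the earlier sample
nearest_time_index <- function(times, t) {
  n <- length(times)
  k <- findInterval(t, times)
  k[k < 1L] <- 1L
  k_hi <- pmin(k + 1L, n)
  lo_d <- t - times[k]
  hi_d <- times[k_hi] - t
  ifelse(hi_d < lo_d, k_hi, k)
}

#' Nearest-in-time target sample
#'
#' Returns the trajectory sample closest in time to `t` (ties break toward the
#' earlier sample; queries beyond the ends clamp).
#'
#' @param t query time in seconds.
#' @param traj a [trajectory()].
#' @return list with `t_s` and `d` (length-3 displacement, mm).
#' @export
nearest_target_sample <- function(t, traj) {
  if (nrow(traj) == 0) stop("empty trajectory")
  k <- nearest_time_index(traj$t_s, t)
  list(t_s = traj$t_s[k],
       d = c(traj$d_lr_mm[k], traj$d_ap_mm[k], traj$d_si_mm[k]),
       index = k)
}

#' Localisation latency model
#'
#' Gaussian latency applied to target positions to emulate the localisation
#' delay of an electromagnetic tracking system; default 100 +/- 15 ms. Draws
#' are clipped at 0 and seeded per query index so that "online" runs are
#' reproducible.
#'
#' @param mean_ms mean latency (ms). @param sd_ms standard deviation (ms).
#' @param seed integer seed.
#' @return object of class `latency_model`.
#' @export
latency_model <- function(mean_ms = 100, sd_ms = 15, seed = 1) {
  if (mean_ms < 0 || sd_ms < 0) stop("latency parameters must be >= 0")
  structure(list(mean_ms = mean_ms, sd_ms = sd_ms, seed = seed),
            class = "latency_model")
}

#' Draw latency values
#'
#' One draw per query index; draw k is fully determined by (model seed, k).
#'
#' @param lat a [latency_model()].
#' @param n number of draws, for query indices `1:n`.
#' @param query_index alternative explicit indices.
#' @return latency values in ms, clipped at 0.
#' @export
latency_draws <- function(lat, n = NULL, query_index = NULL) {
  if (is.null(query_index)) query_index <- seq_len(n)
  vapply(query_index, function(k) {
    with_seed(derive_seed(lat$seed, 7000L + k),
              max(0, stats::rnorm(1, lat$mean_ms, lat$sd_ms)))
  }, numeric(1))
}

#' Latency-delayed view of a trajectory
#'
#' What the tracking system sees at time `query_t`: the trajectory sample
#' nearest in time to `query_t - L`, with L drawn once per query from the
#' latency model. Queries before the first available delayed sample return
#' zero displacement (the tracker starts at the planning position).
#'
#' @param traj a [trajectory()]. @param lat a [latency_model()].
#' @param query_t query time (s). @param query_index integer index of this
#'   query, seeding the latency draw.
#' @return length-3 displacement (mm).
#' @export
delayed_view <- function(traj, lat, query_t, query_index = 1L) {
  L <- latency_draws(lat, query_index = query_index) / 1000
  td <- query_t - L
  if (td < traj$t_s[1]) return(c(0, 0, 0))
  nearest_target_sample(td, traj)$d
}

#' Interfractional offset grid
#'
#' Full Cartesian grid of constant offset vectors over the three axes, from
#' -half_range to +half_range in steps of `step` (default 3 mm / 1 mm, i.e.
#' 343 vectors).
#'
#' @param half_range_mm half range per axis (mm).
#' @param step_mm step (mm); must divide `half_range_mm`.
#' @return matrix `n x 3` of offsets (LR, AP, SI) in mm.
#' @export
offset_grid <- function(half_range_mm = 3, step_mm = 1) {
  if (step_mm <= 0) stop("offset step must be > 0")
  if (abs(half_range_mm / step_mm - round(half_range_mm / step_mm)) > 1e-9)
    stop("half_range must be a multiple of step")
  v <- seq(-half_range_mm, half_range_mm, by = step_mm)
  g <- as.matrix(expand.grid(d_lr_mm = v, d_ap_mm = v, d_si_mm = v))
  rownames(g) <- NULL
  g
}

#' Pitch/roll rotation grid
#'
#' Cartesian product of pitch angles (about the LR axis) and roll angles
#' (about the SI axis), applied in the fixed order pitch first, then roll.
#' A pitch-only grid is obtained with `roll = 0`.
#'
#' @param pitch_deg,roll_deg numeric vectors of angles in degrees.
#' @return data.frame with columns `pitch_deg`, `roll_deg`.
#' @export
rotation_grid <- function(pitch_deg, roll_deg = 0) {
  if (length(pitch_deg) == 0 || length(roll_deg) == 0)
    stop("rotation_grid: empty angle range")
  g <- expand.grid(pitch_deg = pitch_deg, roll_deg = roll_deg)
  g[order(g$pitch_deg, g$roll_deg), , drop = FALSE] -> g
  rownames(g) <- NULL
  g
}

#' Rotation specification
#'
#' Pitch about the +LR axis followed by roll about the +SI axis (right-handed
#' about both axes), pivoting on the target centre of volume.
#'
#' @param pitch_deg,roll_deg angles in degrees.
#' @param pivot length-3 pivot position (mm), typically the CTV centroid.
#' @return object of class `rotation_spec` with the composed 3x3 matrix.
#' @export
rotation_spec <- function(pitch_deg = 0, roll_deg = 0, pivot = c(0, 0, 0)) {
  cp <- cospi(pitch_deg / 180); sp <- sinpi(pitch_deg / 180)
  cr <- cospi(roll_deg / 180);  sr <- sinpi(roll_deg / 180)
  r_pitch <- matrix(c(1, 0, 0,
                      0, cp, sp,
                      0, -sp, cp), 3, 3) # right-handed about +x (LR)
  r_roll <- matrix(c(cr, sr, 0,
                     -sr, cr, 0,
                     0, 0, 1), 3, 3)     # right-handed about +z (SI)
  structure(list(pitch_deg = pitch_deg, roll_deg = roll_deg, pivot = pivot,
                 R = r_roll %*% r_pitch),
            class = "rotation_spec")
}

#' Rotate about a pivot, then shift
#'
#' Applies `R_roll %*% R_pitch %*% (p - pivot) + pivot + shift` to one or more
#' points. Distances to the pivot are preserved when `shift = 0`.
#'
#' @param points `n x 3` matrix (or length-3 vector) of mm positions.
#' @param rot a [rotation_spec()] (or NULL for identity).
#' @param shift length-3 displacement (mm).
#' @return `n x 3` matrix of transformed positions.
#' @export
displace_and_rotate <- function(points, rot = NULL, shift = c(0, 0, 0)) {
  pts <- rbind(points)
  dimnames(pts) <- NULL
  if (!is.null(rot) && (rot$pitch_deg != 0 || rot$roll_deg != 0)) {
    ctr <- sweep(pts, 2, rot$pivot)
    pts <- sweep(ctr %*% t(rot$R), 2, rot$pivot, "+")
  }
  sweep(pts, 2, shift, "+")
}
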