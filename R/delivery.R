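#' Delivery timing configuration
#'
#' Stream cadences (40 ms aperture reports, 20 ms machine states), the
#' beam-off hold between segments during which the leaves move to the next
#' shape, and the dose rate. Cadences follow the linac reporting intervals;
#' hold and dose rate are declared simulator configuration, not measured
#' facts.
#'
#' @param aperture_interval_s aperture report interval (default 0.04 s).
#' @param state_interval_s machine state interval (default 0.02 s).
#' @param hold_s beam-off hold before each segment (s).
#' @param dose_rate_mu_min dose rate while beam-on (MU/min).
#' @return object of class `timing_config`.
#' @export
timing_config <- function(aperture_interval_s = 0.04, state_interval_s = 0.02,
                          hold_s = 2, dose_rate_mu_min = 600) {
  if (aperture_interval_s <= 0 || state_interval_s <= 0)
    stop("timing: intervals must be > 0")
  if (hold_s < 0) stop("timing: hold must be >= 0")
  structure(list(aperture_interval_s = aperture_interval_s,
                 state_interval_s = state_interval_s, hold_s = hold_s,
                 dose_rate_mu_min = dose_rate_mu_min),
            class = "timing_config")
}

# sample times for one phase: start + k*dt inside [start, end], plus the exact
# phase end (events at phase boundaries pin segment MU to segment apertures)
phase_times <- function(start, end, dt) {
  if (end <= start) return(numeric(0))
  k <- floor((end - start) / dt + 1e-12)
  ts <- start + (0:k) * dt
  if (ts[length(ts)] < end - 1e-12) ts <- c(ts, end)
  ts[length(ts)] <- end
  unique(ts)
}

#' Simulate a step-and-shoot delivery
#'
#' Generates the asynchronous aperture and machine-state streams of a full
#' delivery in one of three modes:
#' \describe{
#'   \item{static}{no motion, no tracking: every report shows the planned
#'     segment aperture}
#'   \item{conventional}{the anatomy moves but the MLC does not react}
#'   \item{tracked}{each aperture report is the planned shape shifted in the
#'     BEV by the latency-delayed target displacement (translational MLC
#'     tracking, idealized infinite leaf speed)}
#' }
#' Beams are delivered sequentially; each segment is preceded by a beam-off
#' hold (apertures keep streaming with zero incremental MU), then beam-on for
#' `planned_mu / dose_rate`. Cumulative MU is integrated at the dose rate
#' while beam-on and is exactly the planned total at the end.
#'
#' @param plan a [generate_plan()] result.
#' @param mode `"static"`, `"conventional"` or `"tracked"`.
#' @param traj a [trajectory()] (required for conventional/tracked); held at
#'   its last sample if shorter than the delivery.
#' @param lat a [latency_model()] (tracked mode).
#' @param timing a [timing_config()].
#' @return object of class `delivery_record`: `apertures` (list of reports
#'   with `t_s`, `beam`, `segment`, `aperture`, `shift`, `clamped`),
#'   `states` (data.frame `t_s, cum_mu, dose_rate, gantry_deg, beam_on`),
#'   `mode`, `timing`, `total_mu`.
#' @export
simulate_delivery <- function(plan, mode = c("static", "conventional",
                                             "tracked"),
                              traj = NULL, lat = latency_model(),
                              timing = timing_config()) {
  mode <- match.arg(mode)
  if (timing$dose_rate_mu_min <= 0) stop("timing.dose_rate must be > 0")
  if (mode != "static" && is.null(traj))
    stop("mode '", mode, "' requires a trajectory")
  rate_s <- timing$dose_rate_mu_min / 60
  reports <- list()
  st_t <- numeric(0); st_mu <- numeric(0); st_on <- logical(0)
  st_g <- numeric(0)
  t_now <- 0; cum_mu <- 0; q_index <- 0L

  emit_states <- function(ts, mu_at, on, gantry) {
    st_t <<- c(st_t, ts); st_mu <<- c(st_mu, mu_at)
    st_on <<- c(st_on, rep(on, length(ts)))
    st_g <<- c(st_g, rep(gantry, length(ts)))
  }
  emit_reports <- function(ts, beam_i, seg_i, planned_ap, gantry) {
    for (t in ts) {
      q_index <<- q_index + 1L
      if (mode == "tracked") {
        d <- delayed_view(traj, lat, t, q_index)
        sh <- project_to_bev(d, gantry)
        ap <- track_aperture(planned_ap, sh)
        reports[[length(reports) + 1L]] <<- list(
          t_s = t, beam = beam_i, segment = seg_i, aperture = ap,
          shift = unname(sh), clamped = isTRUE(attr(ap, "clamped")))
      } else {
        reports[[length(reports) + 1L]] <<- list(
          t_s = t, beam = beam_i, segment = seg_i, aperture = planned_ap,
          shift = c(0, 0), clamped = FALSE)
      }
    }
  }

  for (b in seq_along(plan$beams)) {
    beam <- plan$beams[[b]]
    for (s in seq_along(beam$segments)) {
      seg <- beam$segments[[s]]
      # beam-off hold: leaves move to this segment's shape
      if (timing$hold_s > 0) {
        ts <- phase_times(t_now, t_now + timing$hold_s,
                          timing$state_interval_s)
        emit_states(ts, rep(cum_mu, length(ts)), FALSE, beam$gantry_deg)
        ta <- phase_times(t_now, t_now + timing$hold_s,
                          timing$aperture_interval_s)
        emit_reports(ta, b, s, seg$aperture, beam$gantry_deg)
        t_now <- t_now + timing$hold_s
      }
      # beam-on
      dur <- seg$planned_mu / rate_s
      if (dur > 0) {
        ts <- phase_times(t_now, t_now + dur, timing$state_interval_s)
        mu_at <- cum_mu + (ts - t_now) * rate_s
        mu_at[length(mu_at)] <- cum_mu + seg$planned_mu # exact at segment end
        emit_states(ts, mu_at, TRUE, beam$gantry_deg)
        ta <- phase_times(t_now, t_now + dur, timing$aperture_interval_s)
        emit_reports(ta, b, s, seg$aperture, beam$gantry_deg)
        t_now <- t_now + dur
        cum_mu <- cum_mu + seg$planned_mu
      }
    }
  }
  states <- data.frame(t_s = st_t, cum_mu = st_mu,
                       dose_rate = ifelse(st_on, timing$dose_rate_mu_min, 0),
                       gantry_deg = st_g, beam_on = st_on)
  # collapse duplicate timestamps at phase boundaries, keeping the earlier
  # event: MU accrued up to a segment boundary stays attributed to the
  # aperture that delivered it
  keep <- !duplicated(states$t_s)
  states <- states[keep, , drop = FALSE]
  rownames(states) <- NULL
  rep_t <- vapply(reports, `[[`, numeric(1), "t_s")
  reports <- reports[!duplicated(rep_t)]
  structure(list(mode = mode, apertures = reports, states = states,
                 timing = timing, total_mu = cum_mu,
                 traj_meta = if (!is.null(traj))
                   list(archetype = attr(traj, "archetype"),
                        seed = attr(traj, "seed")) else NULL,
                 latency = if (mode == "tracked") lat else NULL),
            class = "delivery_record")
}

#' @export
print.delivery_record <- function(x, ...) {
  cat(sprintf(
    "delivery_record: mode=%s, %d aperture reports, %d states, %.1f MU\n",
    x$mode, length(x$apertures), nrow(x$states), x$total_mu))
  invisible(x)
}

#' Associate machine states and incremental MU with aperture reports
#'
#' Each aperture report is matched to the machine state nearest in time (ties
#' toward the earlier state); the incremental MU of a report is its
#' associated cumulative MU minus the previous report's (0 baseline for the
#' first). A decreasing cumulative MU indicates stream corruption and is an
#' error.
#'
#' @param record a [simulate_delivery()] record.
#' @return the record with `inc_mu` and `state_row` added to every report.
#' @export
associate_machine_state <- function(record) {
  st <- record$states
  if (nrow(st) == 0) stop("empty machine stream")
  if (is.unsorted(st$t_s)) stop("machine stream not time-sorted")
  if (any(diff(st$cum_mu) < -1e-12))
    stop("cumulative MU decreases: corrupt machine stream")
  rep_t <- vapply(record$apertures, `[[`, numeric(1), "t_s")
  if (is.unsorted(rep_t)) stop("aperture reports out of order")
  k <- nearest_time_index(st$t_s, rep_t)
  mu_assoc <- st$cum_mu[k]
  inc <- diff(c(0, mu_assoc))
  if (any(inc < -1e-9)) stop("negative incremental MU")
  inc[inc < 0] <- 0
  for (i in seq_along(record$apertures)) {
    record$apertures[[i]]$state_row <- k[i]
    record$apertures[[i]]$inc_mu <- inc[i]
  }
  record$mu_processed_total <- mu_assoc[length(mu_assoc)]
  record
}
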