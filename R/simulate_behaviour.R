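#' Gaze/pupil generator parameters
#'
#' Defaults describe a calm low-workload driving block: ~3.5 mm pupil,
#' moderate fixation scatter, 0.2 blinks/s and 0.5 abrupt pupil
#' discontinuities per second.  The `hw_*` entries are the multiplicative /
#' additive modifiers applied under high visuo-spatial workload: larger
#' pupil (dilation), tighter fixation scatter (visual tunnelling) and
#' fewer blinks.
#'
#' @param duration_s block duration (s).
#' @param fs pupil/gaze sampling rate (Hz).
#' @param pupil_mean mean pupil diameter (mm).
#' @param dilation_offset additive pupil offset (mm).
#' @param pupil_noise_sd white measurement noise SD (mm).
#' @param drift_amp slow-drift amplitude (mm).
#' @param discontinuity_rate rate of injected step discontinuities (1/s).
#' @param step_mm absolute step size of a discontinuity (mm).
#' @param step_tau_s decay time constant of a discontinuity (s); steps
#'   are sharp-onset transients, not permanent level shifts.
#' @param blink_rate blink rate (1/s).
#' @param blink_dur_s mean blink duration (s).
#' @param fixation_dur_s mean fixation duration (s).
#' @param saccade_gap_s inter-fixation gap (s).
#' @param centre gaze centroid (screen units).
#' @param spread SD of fixation positions around the centroid.
#' @param hw_dilation,hw_spread_factor,hw_blink_factor,hw_ipa_factor
#'   high-workload modifiers of pupil offset, fixation spread, blink rate
#'   and discontinuity rate.
#' @return parameter list.
#' @export
gaze_params <- function(duration_s = 300, fs = 250, pupil_mean = 3.5,
                        dilation_offset = 0, pupil_noise_sd = 0.02,
                        drift_amp = 0.15, discontinuity_rate = 0.5,
                        step_mm = 0.1, step_tau_s = 0.5,
                        blink_rate = 0.2, blink_dur_s = 0.15,
                        fixation_dur_s = 0.35, saccade_gap_s = 0.04,
                        centre = c(0.5, 0.5), spread = 0.15,
                        hw_dilation = 0.3, hw_spread_factor = 0.6,
                        hw_blink_factor = 0.7, hw_ipa_factor = 1.5) {
  as.list(environment())
}

condition_gaze_params <- function(p, workload) {
  if (workload == "HW") {
    p$dilation_offset <- p$dilation_offset + p$hw_dilation
    p$spread <- p$spread * p$hw_spread_factor
    p$blink_rate <- p$blink_rate * p$hw_blink_factor
    p$discontinuity_rate <- p$discontinuity_rate * p$hw_ipa_factor
  }
  p
}

#' Generate a synthetic gaze/pupil block
#'
#' Pupil diameter = mean + offset + slow sinusoidal drift + Gaussian noise
#' + step discontinuities at Poisson event times; samples inside blink gaps
#' are NaN with the validity mask cleared.  Fixation and blink event tables
#' are consistent with the signals.
#'
#' @param params a [gaze_params()] list.
#' @param seed integer seed.
#' @return object of class `gaze_block` with `time`, `x`, `y`, `pupil_mm`,
#'   `valid`, `fs`, `duration_s`, `fixations` and `blinks` data frames,
#'   and the true injected discontinuity count `n_steps`.
#' @export
generate_gaze_block <- function(params, seed = 1) {
  p <- params
  n <- round(p$duration_s * p$fs)
  with_seed(seed, {
    t <- (seq_len(n) - 1) / p$fs
    drift <- p$drift_amp * (sin(2 * pi * 0.02 * t + runif(1, 0, 2 * pi)) +
                              0.5 * sin(2 * pi * 0.05 * t + runif(1, 0, 2 * pi)))
    pupil <- p$pupil_mean + p$dilation_offset + drift +
      rnorm(n, sd = p$pupil_noise_sd)
    n_steps <- rpois(1, p$discontinuity_rate * p$duration_s)
    if (n_steps > 0) {
      at <- sort(runif(n_steps, 0.02, 0.98)) * p$duration_s
      for (a in at) {
        idx <- which(t >= a & t < a + 8 * p$step_tau_s)
        pupil[idx] <- pupil[idx] + sample(c(-1, 1), 1) * p$step_mm *
          exp(-(t[idx] - a) / p$step_tau_s)
      }
    } else at <- numeric(0)

    # fixations tile the block with small saccade gaps
    fix_on <- fix_off <- fx <- fy <- numeric(0)
    cur <- 0
    while (cur < p$duration_s - p$fixation_dur_s / 4) {
      d <- rexp(1, 1 / p$fixation_dur_s)
      d <- min(max(d, 0.05), p$duration_s - cur)
      fix_on <- c(fix_on, cur); fix_off <- c(fix_off, cur + d)
      fx <- c(fx, rnorm(1, p$centre[1], p$spread))
      fy <- c(fy, rnorm(1, p$centre[2], p$spread))
      cur <- cur + d + p$saccade_gap_s
    }
    x <- y <- rep(NA_real_, n)
    fi <- findInterval(t, fix_on)
    in_fix <- fi >= 1 & t < fix_off[pmax(fi, 1L)]
    x[in_fix] <- fx[fi[in_fix]]; y[in_fix] <- fy[fi[in_fix]]
    jitter_sd <- p$spread / 50
    x <- x + rnorm(n, sd = jitter_sd); y <- y + rnorm(n, sd = jitter_sd)

    n_blinks <- rpois(1, p$blink_rate * p$duration_s)
    b_on <- sort(runif(n_blinks, 0, p$duration_s - 2 * p$blink_dur_s))
    b_off <- b_on + pmax(0.05, rnorm(n_blinks, p$blink_dur_s, 0.03))
    valid <- rep(TRUE, n)
    if (length(b_on)) {
      bi <- findInterval(t, b_on)
      valid[bi >= 1 & t <= b_off[pmax(bi, 1L)]] <- FALSE
    }
    pupil[!valid] <- NaN
  })
  structure(list(
    time = t, x = x, y = y, pupil_mm = pupil, valid = valid,
    fs = p$fs, duration_s = p$duration_s,
    fixations = data.frame(onset_s = fix_on, offset_s = fix_off,
                           x = fx, y = fy, duration_s = fix_off - fix_on),
    blinks = data.frame(onset_s = b_on, offset_s = b_off),
    n_steps = n_steps, step_times = at, params = p),
    class = "gaze_block")
}

#' Telemetry generator parameters
#'
#' Acceleration and steering rate follow mean-reverting (Ornstein--
#' Uhlenbeck-type) processes whose innovation SD ("volatility") drives the
#' downstream RMSSD; lane position is a mean-reverting deviation from the
#' lane centre.  `hw_*` modifiers implement the degraded high-workload
#' driving profile.
#'
#' @param duration_s block duration (s).
#' @param fs telemetry sampling rate (Hz).
#' @param accel_vol,steer_vol innovation SDs of acceleration (m/s^2) and
#'   steering rate (rad/s).
#' @param brake_base,brake_noise mean and noise SD of brake position.
#' @param lane_sd stationary SD of lane deviation (m).
#' @param n_lane_changes number of lane-change events.
#' @param violation_rate rate of traffic violations (1/s).
#' @param hw_vol_factor,hw_lane_factor,hw_brake_add,hw_violation_factor
#'   high-workload modifiers.
#' @return parameter list.
#' @export
telemetry_params <- function(duration_s = 300, fs = 10, accel_vol = 0.3,
                             steer_vol = 0.05, brake_base = 0.1,
                             brake_noise = 0.05, lane_sd = 0.3,
                             n_lane_changes = 4, violation_rate = 1 / 150,
                             hw_vol_factor = 1.6, hw_lane_factor = 1.6,
                             hw_brake_add = 0.08, hw_violation_factor = 2.5) {
  as.list(environment())
}

condition_telemetry_params <- function(p, workload) {
  if (workload == "HW") {
    p$accel_vol <- p$accel_vol * p$hw_vol_factor
    p$steer_vol <- p$steer_vol * p$hw_vol_factor
    p$lane_sd <- p$lane_sd * p$hw_lane_factor
    p$brake_base <- p$brake_base + p$hw_brake_add
    p$violation_rate <- p$violation_rate * p$hw_violation_factor
  }
  p
}

# mean-reverting AR(1) with stationary SD `sd_stat`
ou_series <- function(n, sd_stat, phi = 0.98) {
  if (sd_stat == 0) return(rep(0, n))
  innov_sd <- sd_stat * sqrt(1 - phi^2)
  as.numeric(stats::filter(rnorm(n, sd = innov_sd), phi,
                           method = "recursive"))
}

#' Generate a synthetic driving telemetry block
#'
#' @param params a [telemetry_params()] list.
#' @param seed integer seed.
#' @return object of class `telemetry_block` with uniformly sampled
#'   `time`, `accel`, `steer`, `brake`, `lane_pos` plus `lane_changes`
#'   (event times) and a typed `violations` data frame.
#' @export
generate_telemetry_block <- function(params, seed = 1) {
  p <- params
  n <- round(p$duration_s * p$fs)
  with_seed(seed, {
    t <- (seq_len(n) - 1) / p$fs
    accel <- ou_series(n, p$accel_vol)
    steer <- ou_series(n, p$steer_vol)
    brake <- pmin(1, pmax(0, p$brake_base + ou_series(n, p$brake_noise)))
    lane <- ou_series(n, p$lane_sd, phi = 0.995)
    lc <- sort(runif(p$n_lane_changes, 5, max(5, p$duration_s - 5)))
    # a lane change adds a transient excursion around its time
    for (a in lc) {
      idx <- which(abs(t - a) < 1.5)
      lane[idx] <- lane[idx] + 3.5 * exp(-((t[idx] - a) / 0.6)^2)
    }
    n_viol <- rpois(1, p$violation_rate * p$duration_s)
    viol <- data.frame(
      time_s = sort(runif(n_viol, 0, p$duration_s)),
      type = if (n_viol) sample(c("radar", "collision"), n_viol,
                                replace = TRUE, prob = c(0.8, 0.2))
             else character(0),
      stringsAsFactors = FALSE)
  })
  structure(list(time = t, accel = accel, steer = steer, brake = brake,
                 lane_pos = lane, lane_changes = lc, violations = viol,
                 fs = p$fs, duration_s = p$duration_s, params = p),
            class = "telemetry_block")
}
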