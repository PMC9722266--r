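#' Simulate the kinematics of one reaching trial
#'
#' Generates one trial of 200 Hz hand kinematics.  The forward component is a
#' minimal-jerk reach of the requested amplitude and duration; the lateral
#' component is a point mass driven by the curl-field force (`f_x = B v_y`),
#' the learner's feedforward compensation (`-compensation * v_y`), optional
#' lateral PD feedback, and Gaussian execution-force noise, integrated with
#' RK4 at a 1 ms substep.  On channel trials the field is replaced by a stiff
#' spring--damper along the straight path and `force_x` records the channel
#' wall force applied to the hand; on field trials `force_x`/`force_y` record
#' the curl-field force.
#'
#' @param B Environment viscosity (N/(m/s)); signed, CW positive.  Ignored
#'   when `is_channel = TRUE` (the channel replaces the field).
#' @param is_channel Logical; channel trial?
#' @param compensation Learner's feedforward viscosity estimate (same units
#'   as `B`); the feedforward force is `-compensation * v_y`.
#' @param params A [participant_params()] object.
#' @param amplitude_m Reach amplitude (m).
#' @param channel List with `stiffness` (N/m) and `damping` (N/(m/s)).
#' @param wait_s Recorded pre-cue duration (s); the go cue is at this time.
#' @param rt_s Reaction time: movement starts at `wait_s + rt_s`.
#' @param mt_s Minimal-jerk movement duration (s).
#' @param post_s Recorded duration after movement end (s).
#' @param noise Logical; include execution noise?
#' @param feedback Logical; apply the lateral PD feedback?  Feedback acts on
#'   the perceived lateral error, which the channel clamps below perceptual
#'   threshold, so it is inactive on channel trials regardless of this flag
#'   (otherwise a position servo would fight the channel wall and shade the
#'   measured compensation by `stiffness / (stiffness + Kp)`).
#' @return A tibble with `t`, `hand_x`, `hand_y`, `vel_x`, `vel_y`,
#'   `force_x`, `force_y` and an `events` attribute (list with `go_cue`,
#'   `movement_onset`, `movement_offset`, from the 3.5 cm/s online
#'   threshold).
#' @export
simulate_reach <- function(B, is_channel = FALSE, compensation = 0,
                           params = participant_params(),
                           amplitude_m = 0.12,
                           channel = list(stiffness = 7000, damping = 30),
                           wait_s = 1.5, rt_s = 0.3, mt_s = 0.6,
                           post_s = 1.0, noise = TRUE, feedback = TRUE) {
  stopifnot(is.finite(B), is.finite(compensation), mt_s > 0)
  dt <- 1 / SAMPLE_RATE
  nsub <- 5L
  t_move <- wait_s + rt_s
  n <- as.integer(round((wait_s + rt_s + mt_s + post_s) / dt)) + 1L
  t <- (seq_len(n) - 1L) * dt

  hand_y <- min_jerk_pos(t - t_move, amplitude_m, mt_s)
  vel_y <- min_jerk_vel(t - t_move, amplitude_m, mt_s)

  t_half <- seq(0, by = dt / (2 * nsub), length.out = 2L * nsub * (n - 1L) + 1L)
  vy_half <- min_jerk_vel(t_half - t_move, amplitude_m, mt_s)

  f_noise <- if (noise && params$motor_noise_sd > 0) {
    ifelse(vel_y > 0, rnorm(n, 0, params$motor_noise_sd), 0)
  } else {
    numeric(n)
  }
  fb_on <- feedback && !isTRUE(is_channel)
  Kp <- if (fb_on) params$feedback$Kp else 0
  Kd <- if (fb_on) params$feedback$Kd else 0
  lat <- .lateral_reach_cpp(vy_half, n, nsub, dt, params$mass,
                            if (is_channel) 0 else B, compensation,
                            isTRUE(is_channel),
                            channel$stiffness, channel$damping,
                            Kp, Kd, f_noise)
  force_y <- if (is_channel) numeric(n) else -B * lat$vx

  speed <- sqrt(lat$vx^2 + vel_y^2)
  onset_i <- which(speed >= 0.035)[1]
  if (is.na(onset_i)) stop("reach never crossed the online velocity threshold")
  peak_i <- which.max(speed)
  off_i <- which(speed < 0.035 & seq_len(n) > peak_i)[1]
  if (is.na(off_i)) off_i <- n

  out <- tibble::new_tibble(list(
    t = t, hand_x = lat$x, hand_y = hand_y,
    vel_x = lat$vx, vel_y = vel_y,
    force_x = lat$f_env, force_y = force_y
  ), nrow = n)
  attr(out, "events") <- list(
    go_cue = wait_s, movement_onset = t[onset_i], movement_offset = t[off_i]
  )
  out
}

# Gamma-family pupil dilation impulse response, normalized to peak 1 at
# t = peak_time: h(t) = (t/tp)^shape * exp(shape * (1 - t/tp)).
pupil_irf <- function(t, shape = 10.1, peak_time = 0.93) {
  h <- numeric(length(t))
  pos <- t > 0
  r <- t[pos] / peak_time
  h[pos] <- exp(shape * (log(r) + 1 - r))
  h
}

#' Simulate a pupil-diameter trace for one trial
#'
#' The normalized pupil is a constant tonic level plus a phasic dilation:
#' the trial's surprise (capped at `s_cap`) scales a gamma-family impulse
#' response locked to movement onset and peaking `irf_peak_time` later, plus
#' AR(1) measurement noise.  The percent trace maps affinely to millimetres
#' using the participant's light-reflex range.  Blink events are drawn at
#' `blink_rate` per trial and overwritten with a near-zero artifact value, as
#' a video eye tracker would record.
#'
#' @param t Time grid of the trial (s, 200 Hz).
#' @param events List with at least `movement_onset` (s), inside the trial.
#' @param surprise Non-negative surprise driving the phasic response.
#' @param tonic Tonic level (% of the light-reflex range).
#' @param params A [participant_params()] object.
#' @param noise Logical; add AR(1) noise and blinks?
#' @return Tibble with `t`, `pupil_mm`, `is_blink`; attribute
#'   `blink_intervals` (two-column matrix of start/end times in s).
#' @export
simulate_pupil_trace <- function(t, events, surprise, tonic,
                                 params = participant_params(),
                                 noise = TRUE) {
  stopifnot(surprise >= 0)
  on <- events$movement_onset
  if (is.null(on) || on < t[1] || on > t[length(t)]) {
    stop("movement_onset must lie inside the trial window")
  }
  pp <- params$pupil
  s <- min(surprise, pp$s_cap)
  pct <- tonic + pp$surprise_gain * s *
    pupil_irf(t - on, pp$irf_shape, pp$irf_peak_time)
  if (noise && pp$noise_sd > 0) {
    innov <- rnorm(length(t), 0, pp$noise_sd * sqrt(1 - pp$noise_phi^2))
    pct <- pct + as.numeric(stats::filter(innov, pp$noise_phi,
                                          method = "recursive"))
  }
  mm <- params$calib_min_mm +
    pct / 100 * (params$calib_max_mm - params$calib_min_mm)

  blink_iv <- matrix(numeric(0), ncol = 2)
  is_blink <- rep(FALSE, length(t))
  if (noise && params$blink_rate > 0) {
    nb <- rpois(1, params$blink_rate)
    if (nb > 0) {
      starts <- sort(runif(nb, t[1], t[length(t)] - 0.2))
      durs <- runif(nb, 0.08, 0.15)
      blink_iv <- cbind(starts, pmin(starts + durs, t[length(t)]))
      for (k in seq_len(nrow(blink_iv))) {
        sel <- t >= blink_iv[k, 1] & t <= blink_iv[k, 2]
        mm[sel] <- 0.2
        is_blink[sel] <- TRUE
      }
    }
  }
  out <- tibble::new_tibble(list(t = t, pupil_mm = mm, is_blink = is_blink),
                            nrow = length(t))
  attr(out, "blink_intervals") <- unname(blink_iv)
  out
}

# Fixation gaze in display millimetres around the target, with optional
# saccade pulses (smooth logistic displacement out and back).  Returns gaze
# plus the ground-truth saccade times.
simulate_gaze <- function(t, events, params, eye_distance_mm,
                          noise = TRUE, gaze_noise_deg = 0.05) {
  n <- length(t)
  sd_mm <- tan(gaze_noise_deg * pi / 180) * eye_distance_mm
  gx <- if (noise) rnorm(n, 0, sd_mm) else numeric(n)
  gy <- if (noise) rnorm(n, 0, sd_mm) else numeric(n)
  sacc <- tibble::tibble(onset = numeric(0), amplitude_deg = numeric(0))
  if (noise && params$saccade_rate > 0 &&
      runif(1) < params$saccade_rate) {
    t0 <- runif(1, events$movement_onset,
                max(events$movement_onset + 0.05, events$movement_offset - 0.1))
    amp_deg <- runif(1, 2.5, 4)
    amp_mm <- tan(amp_deg * pi / 180) * eye_distance_mm
    ang <- runif(1, 0, 2 * pi)
    dur <- 0.04
    prof <- amp_mm * (plogis((t - t0) / (dur / 8)) -
                        plogis((t - (t0 + 0.25)) / (dur / 8)))
    gx <- gx + cos(ang) * prof
    gy <- gy + sin(ang) * prof
    sacc <- tibble::tibble(onset = t0, amplitude_deg = amp_deg)
  }
  out <- tibble::new_tibble(list(t = t, gaze_x = gx, gaze_y = gy),
                            nrow = n)
  attr(out, "saccades") <- sacc
  out
}

#' Simulate a pair of pupillary light-reflex calibration trials
#'
#' A dark stimulus drives the pupil from its resting diameter toward the
#' participant's dilation ceiling and a bright stimulus toward the
#' constriction floor, each with first-order dynamics (time constant `tau_s`)
#' during the stimulus and relaxation back to rest afterwards, plus AR(1)
#' measurement noise.
#'
#' @param params A [participant_params()] object.
#' @param stimulus_s Stimulus duration (s).
#' @param post_s Recorded duration after stimulus offset (s).
#' @param tau_s First-order time constant (s).
#' @param noise Logical; add measurement noise?
#' @return A list with tibbles `dark` and `bright` (`t`, `pupil_mm`).
#' @export
simulate_light_reflex <- function(params = participant_params(),
                                  stimulus_s = 1.5, post_s = 3.5,
                                  tau_s = 0.25, noise = TRUE) {
  stopifnot(stimulus_s >= 0, post_s > 0, tau_s > 0)
  dt <- 1 / SAMPLE_RATE
  t <- seq(0, stimulus_s + post_s, by = dt)
  rest <- (params$calib_min_mm + params$calib_max_mm) / 2
  one <- function(target) {
    d <- ifelse(t <= stimulus_s,
                target + (rest - target) * exp(-t / tau_s),
                NA_real_)
    d_off <- if (stimulus_s > 0) {
      target + (rest - target) * exp(-stimulus_s / tau_s)
    } else {
      rest
    }
    idx <- t > stimulus_s
    d[idx] <- rest + (d_off - rest) * exp(-(t[idx] - stimulus_s) / tau_s)
    if (noise && params$pupil$noise_sd > 0) {
      scale_mm <- params$pupil$noise_sd / 100 *
        (params$calib_max_mm - params$calib_min_mm)
      innov <- rnorm(length(t), 0, scale_mm * sqrt(1 - params$pupil$noise_phi^2))
      d <- d + as.numeric(stats::filter(innov, params$pupil$noise_phi,
                                        method = "recursive"))
    }
    tibble::tibble(t = t, pupil_mm = d)
  }
  list(dark = one(params$calib_max_mm), bright = one(params$calib_min_mm))
}
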