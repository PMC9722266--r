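#' Analysis-grade reach segmentation
#'
#' Onset is the first sample at which the tangential speed exceeds 10% of its
#' peak; offset is the first later sample at which it drops back below that
#' same trial-specific threshold (if it never does, the last sample is used
#' and flagged).
#'
#' @param speed Tangential speed series (m/s).
#' @param t Time stamps (s).
#' @return List with `onset`, `offset` (s), `peak_time`, `peak_speed`, and
#'   `offset_flagged`.
#' @export
reach_onset_offset <- function(speed, t) {
  peak <- max(speed)
  if (!is.finite(peak) || peak <= 0) stop("speed series has no positive peak")
  thr <- 0.1 * peak
  on_i <- which(speed > thr)[1]
  later <- which(speed < thr & seq_along(speed) > on_i)
  flagged <- length(later) == 0
  off_i <- if (flagged) length(speed) else later[1]
  peak_i <- which.max(speed)
  list(onset = t[on_i], offset = t[off_i], peak_time = t[peak_i],
       peak_speed = peak, offset_flagged = flagged)
}

#' Kinematic error measures of one reach
#'
#' `PVE` is the signed perpendicular displacement from the straight
#' start-to-target line at the time of peak tangential velocity (positive =
#' rightward of the line); `EPE` is the Euclidean hand-to-target distance at
#' movement offset.
#'
#' @param hand_x,hand_y Hand path (m).
#' @param t Time stamps (s).
#' @param seg Segmentation from [reach_onset_offset()].
#' @param start,target Endpoints of the nominal straight path (m).
#' @return List with `pve`, `epe` (m) and `peak_outside_flag`.
#' @export
kinematic_errors <- function(hand_x, hand_y, t, seg,
                             start = c(0, 0), target = c(0, 0.12)) {
  u <- target - start
  u <- u / sqrt(sum(u^2))
  # rightward normal of the start->target direction
  nvec <- c(u[2], -u[1])
  pk <- which.min(abs(t - seg$peak_time))
  off <- which.min(abs(t - seg$offset))
  pve <- (hand_x[pk] - start[1]) * nvec[1] + (hand_y[pk] - start[2]) * nvec[2]
  epe <- sqrt((hand_x[off] - target[1])^2 + (hand_y[off] - target[2])^2)
  list(pve = pve, epe = epe,
       peak_outside_flag = seg$peak_time < seg$onset ||
         seg$peak_time > seg$offset)
}

#' Channel-trial learning index
#'
#' The lateral channel force at the time of peak tangential velocity divided
#' by the peak tangential velocity; in viscosity units, positive when the
#' force compensates the clockwise field, and equal to the field viscosity
#' under full adaptation.
#'
#' @param force_x Lateral force recorded on the channel (N).
#' @param t Time stamps (s).
#' @param seg Segmentation from [reach_onset_offset()].
#' @param min_peak_speed Peak speeds below this (m/s) yield `NA`.
#' @return Learning index in N/(m/s), or `NA`.
#' @export
learning_index <- function(force_x, t, seg, min_peak_speed = 0.01) {
  if (seg$peak_speed < min_peak_speed) return(NA_real_)
  pk <- which.min(abs(t - seg$peak_time))
  force_x[pk] / seg$peak_speed
}

#' Trial-level pupil features
#'
#' Baseline pupil is the mean normalized diameter over the waiting window
#' before the go cue (default: its final 1 s); dilation velocity is the mean
#' pupil velocity over 300--700 ms after movement onset, and is missing when
#' any detected saccade overlaps the movement period.
#'
#' @param pupil_norm,pupil_vel Normalized pupil (%) and its velocity (%/s).
#' @param t Time stamps (s).
#' @param go_cue Go-cue time (s).
#' @param seg Segmentation from [reach_onset_offset()].
#' @param saccades Tibble with `start`/`end` of detected saccades (possibly
#'   zero rows).
#' @param baseline_window_s Length of the baseline window before the go cue.
#' @param vel_window_s Two-element window after movement onset (s).
#' @return List with `baseline_pupil` (%), `dilation_velocity` (%/s or
#'   `NA`), `saccade_in_movement`, `short_baseline_flag`.
#' @export
pupil_features <- function(pupil_norm, pupil_vel, t, go_cue, seg, saccades,
                           baseline_window_s = 1.0,
                           vel_window_s = c(0.3, 0.7)) {
  base_sel <- t >= go_cue - baseline_window_s & t <= go_cue
  short_flag <- (go_cue - t[1]) < 0.5
  baseline <- mean(pupil_norm[base_sel])
  sac_in_move <- nrow(saccades) > 0 &&
    any(saccades$start <= seg$offset & saccades$end >= seg$onset)
  dil <- if (sac_in_move) NA_real_ else {
    sel <- t >= seg$onset + vel_window_s[1] & t <= seg$onset + vel_window_s[2]
    mean(pupil_vel[sel])
  }
  list(baseline_pupil = baseline, dilation_velocity = dil,
       saccade_in_movement = sac_in_move, short_baseline_flag = short_flag)
}

# Extract an event-locked window of a series by sample index.
extract_locked <- function(x, t, center, window = c(-0.5, 1.5),
                           rate_hz = SAMPLE_RATE) {
  offs <- seq(window[1], window[2], by = 1 / rate_hz)
  idx <- round((center - t[1] + offs) * rate_hz) + 1
  out <- rep(NA_real_, length(offs))
  ok <- idx >= 1 & idx <= length(x)
  out[ok] <- x[idx[ok]]
  out
}

# Full feature extraction for one simulated participant: preprocess, then
# reduce each trial to scalars and an onset-locked pupil-velocity trace.
participant_features <- function(sim, schedule, participant_id,
                                 baseline_window_s = 1.0,
                                 vel_window_s = c(0.3, 0.7),
                                 lock_window = c(-0.5, 1.5)) {
  calib <- calibrate_pupil(sim$calib)
  eye_mm <- attr(schedule, "eye_distance_mm")
  amp <- attr(schedule, "amplitude_m")
  pre <- preprocess_trials(sim$timeseries, sim$blinks, calib, eye_mm)
  sac_all <- attr(pre, "saccades")
  rt_rows <- reaching_trials(schedule)

  trials <- split(pre, pre$reach_index)
  trials <- trials[order(as.integer(names(trials)))]
  nT <- length(trials)
  offs <- seq(lock_window[1], lock_window[2], by = 1 / SAMPLE_RATE)
  locked <- matrix(NA_real_, nrow = nT, ncol = length(offs))
  col <- list(reach_index = integer(nT), pve = numeric(nT),
              epe = numeric(nT), learning_index = numeric(nT),
              baseline_pupil = numeric(nT), dilation_velocity = numeric(nT),
              saccade_in_movement = logical(nT), peak_speed = numeric(nT))
  for (j in seq_len(nT)) {
    tr <- trials[[j]]
    ri <- tr$reach_index[1]
    speed <- sqrt(gaussian_smooth(tr$vel_x, 35)^2 +
                    gaussian_smooth(tr$vel_y, 35)^2)
    seg <- reach_onset_offset(speed, tr$t)
    ke <- kinematic_errors(tr$hand_x, tr$hand_y, tr$t, seg,
                           target = c(0, amp))
    is_ch <- rt_rows$is_channel[rt_rows$reach_index == ri]
    sac <- if (is.null(sac_all) || nrow(sac_all) == 0) {
      tibble::tibble(start = numeric(0), end = numeric(0))
    } else {
      sac_all[sac_all$reach_index == ri, ]
    }
    go_cue <- sim$events$go_cue[sim$events$reach_index == ri]
    pf <- pupil_features(tr$pupil_norm, tr$pupil_vel, tr$t, go_cue, seg,
                         sac, baseline_window_s, vel_window_s)
    locked[j, ] <- extract_locked(tr$pupil_vel, tr$t, seg$onset, lock_window)
    col$reach_index[j] <- ri
    col$pve[j] <- ke$pve
    col$epe[j] <- ke$epe
    col$learning_index[j] <- if (is_ch) {
      learning_index(tr$force_x, tr$t, seg)
    } else {
      NA_real_
    }
    col$baseline_pupil[j] <- pf$baseline_pupil
    col$dilation_velocity[j] <- pf$dilation_velocity
    col$saccade_in_movement[j] <- pf$saccade_in_movement
    col$peak_speed[j] <- seg$peak_speed
  }
  sch_idx <- match(col$reach_index, rt_rows$reach_index)
  ev_idx <- match(col$reach_index, sim$events$reach_index)
  trials_tbl <- tibble::new_tibble(list(
    participant = rep(participant_id, nT),
    reach_index = col$reach_index,
    block = rt_rows$block[sch_idx],
    cycle = ceiling(col$reach_index / 5),
    B = rt_rows$B[sch_idx],
    is_channel = rt_rows$is_channel[sch_idx],
    is_change_point = rt_rows$is_change_point[sch_idx],
    pve = col$pve, epe = col$epe, learning_index = col$learning_index,
    baseline_pupil = col$baseline_pupil,
    dilation_velocity = col$dilation_velocity,
    rt = sim$events$movement_onset[ev_idx] - sim$events$go_cue[ev_idx],
    mt = sim$events$movement_offset[ev_idx] -
      sim$events$movement_onset[ev_idx],
    saccade_in_movement = col$saccade_in_movement,
    peak_speed = col$peak_speed
  ), nrow = nT)
  trials_tbl <- dplyr::arrange(trials_tbl, .data$reach_index)
  list(trials = trials_tbl, locked = locked, lock_offsets = offs)
}

#' Assemble the analysis trial table for a cohort
#'
#' Preprocesses every participant of an in-memory cohort and reduces each
#' reaching trial to the analysis scalars (kinematic errors, channel learning
#' index, baseline pupil, dilation velocity, reaction and movement time).
#' The lateral error and learning index of participants who learned with the
#' counter-clockwise field are sign-flipped so the group shares the
#' clockwise convention; `sign_flipped` records this.
#'
#' @param cohort A `pupil_cohort` from [simulate_cohort()] with time series
#'   kept in memory.
#' @param ... Passed to the per-trial feature extraction (window knobs).
#' @return A tibble with one row per participant x reaching trial; attribute
#'   `locked` (list with per-participant onset-locked pupil-velocity
#'   matrices and their time offsets).
#' @export
build_trial_table <- function(cohort, ...) {
  parts <- cohort$participants
  if (is.null(parts[[1]]$timeseries)) {
    stop("cohort was simulated without keep_timeseries = TRUE")
  }
  out <- vector("list", length(parts))
  locked <- vector("list", length(parts))
  offs <- NULL
  for (p in seq_along(parts)) {
    pf <- participant_features(parts[[p]], cohort$schedule, p, ...)
    flip <- parts[[p]]$direction == "CCW"
    pf$trials <- dplyr::mutate(pf$trials,
      pve = if (flip) -.data$pve else .data$pve,
      learning_index = if (flip) -.data$learning_index else .data$learning_index,
      sign_flipped = flip
    )
    out[[p]] <- pf$trials
    locked[[p]] <- pf$locked
    offs <- pf$lock_offsets
  }
  res <- dplyr::bind_rows(out)
  attr(res, "locked") <- list(per_participant = locked, offsets = offs)
  res
}
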