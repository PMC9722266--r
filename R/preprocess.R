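#' Mask blink-contaminated samples and interpolate across the gaps
#'
#' Discards 100 ms of data before each blink and 150 ms after it, then fills
#' the gaps by shape-preserving piecewise-cubic (monotone Hermite, PCHIP)
#' interpolation through the surviving samples.  Samples outside the masked
#' windows are returned bit-identical.  Gaps touching the trace edge are
#' filled by nearest-value extension and flagged.
#'
#' @param x Uniformly sampled signal.
#' @param t Time stamps of `x` (s).
#' @param blink_intervals Two-column matrix (or data frame) of blink start /
#'   end times in s; may have zero rows.
#' @param pre_s,post_s Margins discarded before/after each blink (s).
#' @return `x` with gaps filled; attributes `masked` (logical vector) and
#'   `edge_extended` (logical flag).
#' @export
deblink <- function(x, t, blink_intervals, pre_s = 0.100, post_s = 0.150) {
  bi <- as.matrix(blink_intervals)
  if (length(bi) == 0 || nrow(bi) == 0) {
    attr(x, "masked") <- rep(FALSE, length(x))
    attr(x, "edge_extended") <- FALSE
    return(x)
  }
  stopifnot(ncol(bi) == 2, all(bi[, 1] <= bi[, 2]))
  masked <- rep(FALSE, length(x))
  for (k in seq_len(nrow(bi))) {
    masked <- masked | (t >= bi[k, 1] - pre_s & t <= bi[k, 2] + post_s)
  }
  keep <- which(!masked)
  if (length(keep) < 2) stop("blink mask covers the entire trace")
  edge <- masked[1] || masked[length(x)]
  out <- x
  inner <- masked & t >= t[keep[1]] & t <= t[keep[length(keep)]]
  if (any(inner)) {
    out[inner] <- pracma::pchip(t[keep], x[keep], t[inner])
  }
  if (masked[1]) out[t < t[keep[1]]] <- x[keep[1]]
  if (masked[length(x)]) out[t > t[keep[length(keep)]]] <- x[keep[length(keep)]]
  attr(out, "masked") <- masked
  attr(out, "edge_extended") <- edge
  out
}

# Fallback blink detector for data without annotated blink events: samples
# below a physiologically implausible pupil diameter are flagged and merged
# into intervals.
detect_blinks_floor <- function(pupil_mm, t, floor_mm = 1.0) {
  low <- pupil_mm < floor_mm | !is.finite(pupil_mm)
  if (!any(low)) return(matrix(numeric(0), ncol = 2))
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(t[starts[r$values]], t[ends[r$values]])
}

#' Gaussian smoothing with an FWHM-specified kernel
#'
#' Convolves the series with a normalized Gaussian kernel of the given full
#' width at half maximum; edges are handled by reflection so the output has
#' the input length and no edge attenuation.
#'
#' @param x Series to smooth.
#' @param fwhm_ms Kernel full width at half maximum (ms).
#' @param rate_hz Sampling rate (Hz).
#' @return Smoothed series, same length as `x`.
#' @export
gaussian_smooth <- function(x, fwhm_ms, rate_hz = SAMPLE_RATE) {
  stopifnot(fwhm_ms > 0)
  sigma <- fwhm_ms / 1000 / (2 * sqrt(2 * log(2))) * rate_hz  # in samples
  if (sigma * 2.355 < 1) {
    warning("FWHM shorter than one sample; returning input unchanged")
    return(x)
  }
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  n <- length(x)
  pad <- min(half, n - 1)
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  sm <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(sm[(pad + 1):(pad + n)])
}

#' Savitzky--Golay differentiation of a position series
#'
#' Applies a second-order Savitzky--Golay filter with the given frame length
#' to the position series and differentiates the filtered series by first
#' difference scaled by the sampling rate, as is conventional for eye
#' velocity computation.  The last sample is repeated so the output matches
#' the input length.
#'
#' @param x Position series.
#' @param order Polynomial order of the filter.
#' @param frame_ms Frame length (ms); must span an odd number >= 3 of
#'   samples (55 ms at 200 Hz spans 11).
#' @param rate_hz Sampling rate (Hz).
#' @return Velocity series (units of `x` per second), same length as `x`.
#' @export
savgol_velocity <- function(x, order = 2, frame_ms = 55,
                            rate_hz = SAMPLE_RATE) {
  n_frame <- round(frame_ms / 1000 * rate_hz)
  if (n_frame %% 2 == 0) n_frame <- n_frame + 1
  if (n_frame < 3) stop("frame must span at least 3 samples")
  if (length(x) <= n_frame) stop("series shorter than the filter frame")
  xf <- signal::sgolayfilt(x, sgolay_cached(order, n_frame))
  v <- diff(xf) * rate_hz
  c(v, v[length(v)])
}

# signal::sgolay recomputes an SVD per call; cache the projection matrix.
.sgolay_cache <- new.env(parent = emptyenv())
sgolay_cached <- function(p, n) {
  key <- paste(p, n, sep = "_")
  if (is.null(.sgolay_cache[[key]])) {
    .sgolay_cache[[key]] <- signal::sgolay(p = p, n = n)
  }
  .sgolay_cache[[key]]
}

#' Convert display-coordinate gaze to visual angle
#'
#' Per-axis small-rotation transform: `theta = atan(offset / eye_distance)`
#' in degrees, with offsets measured from the screen center.
#'
#' @param gaze_x,gaze_y Gaze position on the display (mm, screen-centered).
#' @param eye_distance_mm Eye-to-screen distance (mm).
#' @return Tibble with `theta_x`, `theta_y` (deg).
#' @export
to_visual_angle <- function(gaze_x, gaze_y, eye_distance_mm) {
  stopifnot(eye_distance_mm > 0)
  tibble::tibble(theta_x = atan(gaze_x / eye_distance_mm) * 180 / pi,
                 theta_y = atan(gaze_y / eye_distance_mm) * 180 / pi)
}

#' Velocity-threshold saccade detection
#'
#' Flags maximal runs of samples whose angular speed (Euclidean norm of the
#' two axis velocities) is at or above the threshold; runs separated by less
#' than `merge_ms` are merged.
#'
#' @param vel_x,vel_y Angular velocity per axis (deg/s), computed on
#'   visual-angle coordinates.
#' @param t Time stamps (s).
#' @param threshold Speed threshold (deg/s).
#' @param merge_ms Merge gap (ms).
#' @return Tibble with `start`, `end` (s) and `peak_velocity` (deg/s); zero
#'   rows when no saccade is detected.
#' @export
detect_saccades <- function(vel_x, vel_y, t, threshold = 30, merge_ms = 10) {
  speed <- sqrt(vel_x^2 + vel_y^2)
  above <- speed >= threshold
  if (!any(above)) {
    return(tibble::tibble(start = numeric(0), end = numeric(0),
                          peak_velocity = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  iv <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by < merge_ms
  if (nrow(iv) > 1) {
    merged <- list(iv[1, ])
    for (k in 2:nrow(iv)) {
      last <- merged[[length(merged)]]
      if (t[iv[k, 1]] - t[last[2]] < merge_ms / 1000) {
        merged[[length(merged)]] <- c(last[1], iv[k, 2])
      } else {
        merged[[length(merged) + 1]] <- iv[k, ]
      }
    }
    iv <- do.call(rbind, merged)
  }
  tibble::tibble(
    start = t[iv[, 1]], end = t[iv[, 2]],
    peak_velocity = vapply(seq_len(nrow(iv)),
                           function(k) max(speed[iv[k, 1]:iv[k, 2]]), 0)
  )
}

#' Light-reflex pupil calibration
#'
#' Extracts, per block, the trough of the bright-stimulus traces
#' (constriction floor) and the peak of the dark-stimulus traces (dilation
#' ceiling), then averages the per-block values into the participant's
#' normalization range.
#'
#' @param calib Tibble of light-reflex traces with columns `block`,
#'   `stimulus` (`"dark"`/`"bright"`), `t`, `pupil_mm` (as produced by
#'   [simulate_participant()]).
#' @return A list of class `pupil_calibration` with `d_min`, `d_max` (mm)
#'   and the tibble `per_block`.
#' @export
calibrate_pupil <- function(calib) {
  stopifnot(all(c("dark", "bright") %in% calib$stimulus))
  per_block <- dplyr::summarise(
    dplyr::group_by(calib, .data$block),
    d_min = min(.data$pupil_mm[.data$stimulus == "bright"]),
    d_max = max(.data$pupil_mm[.data$stimulus == "dark"]),
    .groups = "drop"
  )
  d_min <- mean(per_block$d_min)
  d_max <- mean(per_block$d_max)
  if (d_min >= d_max) stop("corrupt calibration: d_min >= d_max")
  structure(list(d_min = d_min, d_max = d_max, per_block = per_block),
            class = "pupil_calibration")
}

#' Normalize a pupil trace to the light-reflex range
#'
#' Affine map of millimetre diameter to percent of the participant's
#' light-reflex range: `100 * (v - d_min) / (d_max - d_min)`, so the
#' constriction trough maps to 0% and the dilation peak to 100%.
#'
#' @param pupil_mm Pupil diameter trace (mm).
#' @param calibration A `pupil_calibration` from [calibrate_pupil()].
#' @return Normalized trace (%).
#' @export
normalize_pupil <- function(pupil_mm, calibration) {
  if (calibration$d_max == calibration$d_min) {
    stop("degenerate calibration: d_max == d_min")
  }
  100 * (pupil_mm - calibration$d_min) /
    (calibration$d_max - calibration$d_min)
}

#' Pupil dilation velocity
#'
#' First difference of the (already normalized and smoothed) pupil trace
#' scaled by the sampling rate; the last sample is repeated to preserve
#' length.
#'
#' @param pupil_norm Normalized pupil trace (%).
#' @param rate_hz Sampling rate (Hz).
#' @return Velocity in %/s, same length as the input.
#' @export
pupil_velocity <- function(pupil_norm, rate_hz = SAMPLE_RATE) {
  v <- diff(pupil_norm) * rate_hz
  c(v, v[length(v)])
}

#' Preprocess the trials of one participant
#'
#' Runs the full conditioning chain on a participant's raw traces, trial by
#' trial (no interpolation across trial boundaries): blink masking and PCHIP
#' interpolation of pupil and gaze, 35 ms-FWHM Gaussian smoothing of gaze,
#' Savitzky--Golay differentiation of the visual-angle gaze and 30 deg/s
#' saccade detection, 235 ms-FWHM pupil smoothing, light-reflex
#' normalization and dilation velocity.
#'
#' @param timeseries Long tibble of one participant's trials (columns as
#'   produced by [simulate_participant()]; must include `reach_index`, `t`,
#'   `gaze_x`, `gaze_y`, `pupil_mm`).
#' @param blinks Tibble of blink intervals (`reach_index`, `start`, `end`);
#'   when `NULL` the fallback floor detector is used per trial.
#' @param calibration A `pupil_calibration`.
#' @param eye_distance_mm Eye-to-screen distance (mm).
#' @param fwhm_gaze_ms,fwhm_pupil_ms Smoothing kernels (ms).
#' @param saccade_threshold Saccade speed threshold (deg/s).
#' @return The input tibble with added columns `pupil_norm`, `pupil_vel`,
#'   `gaze_deg_x`, `gaze_deg_y`, `in_saccade`; attribute `saccades` (tibble
#'   with `reach_index`, `start`, `end`, `peak_velocity`).
#' @export
preprocess_trials <- function(timeseries, blinks, calibration,
                              eye_distance_mm,
                              fwhm_gaze_ms = 35, fwhm_pupil_ms = 235,
                              saccade_threshold = 30) {
  per_trial <- function(tr) {
    bi <- if (is.null(blinks)) {
      detect_blinks_floor(tr$pupil_mm, tr$t)
    } else if (nrow(blinks) == 0) {
      matrix(numeric(0), ncol = 2)
    } else {
      b <- blinks[blinks$reach_index == tr$reach_index[1], , drop = FALSE]
      cbind(b$start, b$end)
    }
    pup <- deblink(tr$pupil_mm, tr$t, bi)
    gx <- deblink(tr$gaze_x, tr$t, bi)
    gy <- deblink(tr$gaze_y, tr$t, bi)

    ang <- to_visual_angle(as.numeric(gx), as.numeric(gy), eye_distance_mm)
    vx <- savgol_velocity(ang$theta_x)
    vy <- savgol_velocity(ang$theta_y)
    sac <- detect_saccades(vx, vy, tr$t, threshold = saccade_threshold)

    pup_sm <- gaussian_smooth(as.numeric(pup), fwhm_pupil_ms)
    pnorm <- normalize_pupil(pup_sm, calibration)
    pvel <- pupil_velocity(pnorm)

    in_sac <- rep(FALSE, nrow(tr))
    for (k in seq_len(nrow(sac))) {
      in_sac <- in_sac | (tr$t >= sac$start[k] & tr$t <= sac$end[k])
    }
    gxs <- gaussian_smooth(as.numeric(gx), fwhm_gaze_ms)
    gys <- gaussian_smooth(as.numeric(gy), fwhm_gaze_ms)
    out <- tibble::new_tibble(c(as.list(tr), list(
      pupil_norm = pnorm, pupil_vel = pvel,
      gaze_deg_x = atan(gxs / eye_distance_mm) * 180 / pi,
      gaze_deg_y = atan(gys / eye_distance_mm) * 180 / pi,
      in_saccade = in_sac
    )), nrow = nrow(tr))
    attr(out, "saccades") <- sac
    out
  }
  trials <- split(timeseries, timeseries$reach_index)
  done <- purrr::map(trials, per_trial)
  sacc <- dplyr::bind_rows(purrr::imap(done, function(d, ri) {
    s <- attr(d, "saccades")
    if (nrow(s) == 0) return(NULL)
    tibble::tibble(reach_index = as.integer(ri), s)
  }))
  out <- dplyr::arrange(dplyr::bind_rows(done), .data$reach_index, .data$t)
  attr(out, "saccades") <- sacc
  out
}
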