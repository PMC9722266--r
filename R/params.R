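#' Ground-truth parameters for one synthetic participant
#'
#' Bundles every constant of the generative model: the two-state motor
#' learner, execution noise, the tonic/phasic pupil model, blink and saccade
#' contamination rates, and the pupillary light-reflex range used for
#' normalization.  Defaults emulate a typical adult participant in a
#' force-field reaching study; see the methods vignette for the rationale
#' behind each value.
#'
#' @param two_state List with per-trial retentions `A_f < A_s` in (0,1) and
#'   learning rates `B_f > B_s` in (0,1).
#' @param motor_noise_sd SD of the lateral execution-force noise (N).
#' @param learn_noise_sd SD of trial-to-trial noise on the learner's error
#'   signal (normalized field units).
#' @param pupil List of pupil-model constants: `tonic_floor` (%), the
#'   asymptotic baseline; `novelty_bump` (%), added to the tonic level on the
#'   first trial of each block; `tonic_decay`, per-trial retention of tonic
#'   elevation in (0,1); `surprise_gain_tonic` (% per unit excess surprise);
#'   `surprise_gain` (% peak dilation per unit surprise); `s_cap`, saturation
#'   of the surprise input; `habituation_rate` in (0,1), tracking speed of the
#'   expected error; `irf_shape` and `irf_peak_time` (s) of the gamma-family
#'   dilation impulse response; `noise_sd` (%) and `noise_phi` of the AR(1)
#'   measurement noise; `tonic_noise_sd` (%), trial-level baseline jitter;
#'   `tonic_init` (%), tonic elevation above floor at the start of the
#'   session; `expected_error0` (m), initial expected error magnitude.
#' @param blink_rate Expected blinks per trial (Poisson).
#' @param saccade_rate Probability of a saccade during the movement period.
#' @param calib_min_mm,calib_max_mm Light-reflex constriction trough and
#'   dilation peak (mm); must satisfy `calib_min_mm < calib_max_mm`.
#' @param rt List `base` (s), `tonic_gain` (s per % tonic elevation), `sd`.
#' @param mt Same fields for the movement duration.
#' @param feedback List with lateral PD feedback gains `Kp` (N/m), `Kd`
#'   (N s/m).
#' @param mass Effective lateral hand + handle mass (kg).
#' @return A list of class `participant_params`.
#' @export
participant_params <- function(
    two_state = list(A_f = 0.90, A_s = 0.995, B_f = 0.15, B_s = 0.02),
    motor_noise_sd = 0.1,
    learn_noise_sd = 0.02,
    pupil = list(),
    blink_rate = 0.2,
    saccade_rate = 0.1,
    calib_min_mm = 2.0,
    calib_max_mm = 7.0,
    rt = list(base = 0.30, tonic_gain = 0.004, sd = 0.03),
    mt = list(base = 0.60, tonic_gain = 0.002, sd = 0.02),
    feedback = list(Kp = 20, Kd = 4),
    mass = 0.3) {
  pupil_default <- list(
    tonic_floor = 40, novelty_bump = 10, tonic_decay = 0.85,
    surprise_gain_tonic = 2, surprise_gain = 4, s_cap = 6,
    habituation_rate = 0.2, irf_shape = 10.1, irf_peak_time = 0.93,
    noise_sd = 0.5, noise_phi = 0.95, tonic_noise_sd = 1,
    tonic_init = 15, expected_error0 = 0.004
  )
  pupil <- utils::modifyList(pupil_default, pupil)
  p <- list(
    two_state = two_state, motor_noise_sd = motor_noise_sd,
    learn_noise_sd = learn_noise_sd, pupil = pupil,
    blink_rate = blink_rate, saccade_rate = saccade_rate,
    calib_min_mm = calib_min_mm, calib_max_mm = calib_max_mm,
    rt = rt, mt = mt, feedback = feedback, mass = mass
  )
  validate_participant_params(p)
  structure(p, class = "participant_params")
}

validate_participant_params <- function(p) {
  ts <- p$two_state
  stopifnot(
    ts$A_f > 0, ts$A_f < 1, ts$A_s > 0, ts$A_s < 1, ts$A_s > ts$A_f,
    ts$B_f > 0, ts$B_f < 1, ts$B_s > 0, ts$B_s < 1, ts$B_f > ts$B_s,
    p$calib_min_mm < p$calib_max_mm,
    p$pupil$tonic_decay > 0, p$pupil$tonic_decay < 1,
    p$pupil$habituation_rate >= 0, p$pupil$habituation_rate <= 1,
    p$blink_rate >= 0, p$saccade_rate >= 0, p$saccade_rate <= 1,
    is.finite(p$motor_noise_sd), p$motor_noise_sd >= 0, p$mass > 0
  )
  invisible(p)
}

#' Update the tonic/uncertainty latent state after one trial
#'
#' One step of the generative latent dynamics that drive the synthetic pupil:
#' the surprise of the just-observed movement error is its magnitude relative
#' to the running expectation, `s = e / max(E, eps)`; tonic arousal relaxes
#' geometrically toward its floor, is pushed up by excess surprise
#' (`max(s - 1, 0)`), and receives a fixed novelty bump when a new block
#' starts; the expected error tracks observed errors at the habituation rate.
#'
#' @param latents List with `tonic` (%) and `expected_error` (m).
#' @param observed_abs_error Non-negative observed error magnitude (m).
#' @param block_start Logical; is the *next* trial the first of a new block?
#' @param params A [participant_params()] object (its `pupil` element is
#'   used).
#' @param eps Floor for the expected error in the surprise ratio.
#' @return A list with updated `tonic`, `expected_error`, and the realized
#'   `surprise` for the observed error.
#' @export
update_latents <- function(latents, observed_abs_error, block_start = FALSE,
                           params = participant_params(), eps = 1e-4) {
  stopifnot(is.finite(latents$tonic), is.finite(latents$expected_error))
  if (!is.finite(observed_abs_error) || observed_abs_error < 0) {
    stop("observed_abs_error must be a non-negative number")
  }
  pp <- params$pupil
  s <- observed_abs_error / max(latents$expected_error, eps)
  tonic <- pp$tonic_floor + pp$tonic_decay * (latents$tonic - pp$tonic_floor) +
    pp$surprise_gain_tonic * max(s - 1, 0) +
    if (isTRUE(block_start)) pp$novelty_bump else 0
  expected <- latents$expected_error +
    pp$habituation_rate * (observed_abs_error - latents$expected_error)
  list(tonic = tonic, expected_error = expected, surprise = s)
}
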