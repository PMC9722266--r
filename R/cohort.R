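#' Simulate one synthetic participant through a schedule
#'
#' Runs the full generative model for a single participant: a two-state
#' learner adapts trial-by-trial to the (normalized) field schedule, each
#' reaching trial's kinematics are simulated with [simulate_reach()], the
#' observed lateral error drives the tonic/phasic latent dynamics
#' ([update_latents()]), and pupil and gaze traces are generated per trial.
#' Channel trials clamp the error, so neither the learner nor the latent
#' expectation is updated by them (retention only), and their phasic surprise
#' input is zero.  Light-reflex trials in the schedule produce calibration
#' traces.
#'
#' @param schedule A `pupil_schedule` (canonical CW version).
#' @param params A [participant_params()] object.
#' @param direction `"CW"` or `"CCW"`; flips the field sign for designs with
#'   counterbalanced direction.
#' @param seed Integer seed for all of this participant's noise streams.
#' @param noise Logical; disable for a fully deterministic participant
#'   (no execution, pupil, blink, saccade or report noise).
#' @param wait_s,post_s Recorded pre-cue and post-movement durations (s).
#' @param recall_intercept,recall_slope Logistic coefficients mapping the
#'   participant's mean tonic elevation in a block to the probability of
#'   later reporting a perturbation in that block.
#' @return A list with tibbles `timeseries`, `events`, `blinks`, `calib`,
#'   `latents` (per-trial ground truth), `saccades`, the `report` vector and
#'   the `direction`.
#' @export
simulate_participant <- function(schedule, params = participant_params(),
                                 direction = "CW", seed = 1L, noise = TRUE,
                                 wait_s = 1.5, post_s = 1.0,
                                 recall_intercept = -2, recall_slope = 0.3) {
  set.seed(as.integer(seed %% 2147483647))
  des_amp <- attr(schedule, "amplitude_m")
  des_ch <- attr(schedule, "channel")
  eye_mm <- attr(schedule, "eye_distance_mm")
  B_full <- attr(schedule, "B_full")
  flip <- attr(schedule, "flip_direction") && direction == "CCW"

  rt_rows <- reaching_trials(schedule)
  nR <- nrow(rt_rows)
  B_p <- if (flip) -rt_rows$B else rt_rows$B
  f <- B_p / B_full
  block_first <- !duplicated(rt_rows$block)

  ts <- params$two_state
  pp <- params$pupil
  xf <- 0; xs <- 0
  latents <- list(tonic = pp$tonic_floor + pp$tonic_init,
                  expected_error = pp$expected_error0)

  series <- vector("list", nR)
  blinks <- vector("list", nR)
  saccs <- vector("list", nR)
  ev_go <- ev_on <- ev_off <- numeric(nR)
  lat <- list(tonic = numeric(nR), tonic_measured = numeric(nR),
              expected_error = numeric(nR), surprise = numeric(nR),
              pve_true = numeric(nR), x_net = numeric(nR),
              x_f = numeric(nR), x_s = numeric(nR),
              compensation = numeric(nR), rt = numeric(nR), mt = numeric(nR))

  for (i in seq_len(nR)) {
    x <- xf + xs
    comp <- x * B_full * (if (flip) -1 else 1)
    tonic_meas <- latents$tonic +
      if (noise) rnorm(1, 0, pp$tonic_noise_sd) else 0
    excess <- latents$tonic - pp$tonic_floor
    rt_i <- max(0.15, params$rt$base + params$rt$tonic_gain * excess +
                  if (noise) rnorm(1, 0, params$rt$sd) else 0)
    mt_i <- max(0.4, params$mt$base + params$mt$tonic_gain * excess +
                  if (noise) rnorm(1, 0, params$mt$sd) else 0)

    tr <- simulate_reach(
      B = B_p[i], is_channel = rt_rows$is_channel[i], compensation = comp,
      params = params, amplitude_m = des_amp, channel = des_ch,
      wait_s = wait_s, rt_s = rt_i, mt_s = mt_i, post_s = post_s,
      noise = noise
    )
    events <- attr(tr, "events")
    speed <- sqrt(tr$vel_x^2 + tr$vel_y^2)
    pve <- tr$hand_x[which.max(speed)]

    is_ch <- rt_rows$is_channel[i]
    obs <- if (is_ch) latents$expected_error else abs(pve)
    upd <- update_latents(latents, obs, block_start = FALSE, params = params)
    s_phasic <- if (is_ch) 0 else upd$surprise

    pup <- simulate_pupil_trace(tr$t, events, s_phasic, tonic_meas,
                                params, noise = noise)
    gz <- simulate_gaze(tr$t, events, params, eye_mm, noise = noise)

    nS <- nrow(tr)
    series[[i]] <- tibble::new_tibble(c(
      list(reach_index = rep(rt_rows$reach_index[i], nS)),
      as.list(tr),
      list(gaze_x = gz$gaze_x, gaze_y = gz$gaze_y,
           pupil_mm = pup$pupil_mm, is_blink = pup$is_blink)
    ), nrow = nS)
    ev_go[i] <- events$go_cue
    ev_on[i] <- events$movement_onset
    ev_off[i] <- events$movement_offset
    bi <- attr(pup, "blink_intervals")
    if (nrow(bi) > 0) {
      blinks[[i]] <- tibble::tibble(reach_index = rt_rows$reach_index[i],
                                    start = bi[, 1], end = bi[, 2])
    }
    sc <- attr(gz, "saccades")
    if (nrow(sc) > 0) {
      saccs[[i]] <- tibble::tibble(reach_index = rt_rows$reach_index[i], sc)
    }
    lat$tonic[i] <- latents$tonic
    lat$tonic_measured[i] <- tonic_meas
    lat$expected_error[i] <- latents$expected_error
    lat$surprise[i] <- s_phasic
    lat$pve_true[i] <- pve
    lat$x_net[i] <- x; lat$x_f[i] <- xf; lat$x_s[i] <- xs
    lat$compensation[i] <- comp
    lat$rt[i] <- rt_i; lat$mt[i] <- mt_i

    # latent carry-over; the novelty bump lands on the next trial when it
    # opens a new block
    next_block_start <- i < nR && block_first[i + 1]
    latents <- update_latents(latents, obs, block_start = next_block_start,
                              params = params)[c("tonic", "expected_error")]

    # two-state learner update in normalized field units
    e <- if (is_ch) 0 else {
      f[i] - x + if (noise) rnorm(1, 0, params$learn_noise_sd) else 0
    }
    xf <- ts$A_f * xf + ts$B_f * e
    xs <- ts$A_s * xs + ts$B_s * e
  }

  lr_rows <- dplyr::filter(tibble::as_tibble(schedule), .data$is_light_reflex)
  calib <- purrr::pmap(
    list(lr_rows$trial_index, lr_rows$block, lr_rows$lr_stimulus),
    function(ti, bl, stim) {
      pair <- simulate_light_reflex(params, noise = noise)
      tr <- if (stim == "dark") pair$dark else pair$bright
      tibble::tibble(trial_index = ti, block = bl, stimulus = stim, tr)
    }
  )

  lat_tbl <- tibble::new_tibble(
    c(list(reach_index = rt_rows$reach_index, block = rt_rows$block), lat),
    nrow = nR)
  blocks_main <- attr(schedule, "blocks")$block
  block_tonic <- dplyr::summarise(
    dplyr::group_by(lat_tbl, .data$block),
    excess = mean(.data$tonic - pp$tonic_floor), .groups = "drop"
  )
  p_rep <- plogis(recall_intercept + recall_slope * block_tonic$excess)
  report <- if (noise) rbinom(length(p_rep), 1, p_rep) else as.integer(p_rep > 0.5)

  list(
    timeseries = dplyr::bind_rows(series),
    events = tibble::new_tibble(list(
      reach_index = rt_rows$reach_index, go_cue = ev_go,
      movement_onset = ev_on, movement_offset = ev_off), nrow = nR),
    blinks = dplyr::bind_rows(blinks),
    saccades = dplyr::bind_rows(saccs),
    calib = dplyr::bind_rows(calib),
    latents = lat_tbl,
    report = setNames(report, paste0("block", blocks_main)),
    direction = direction
  )
}

# Jitter a participant_params object to create between-subject variability
# while preserving the parameter invariants.
jitter_params <- function(params, sd_rel = 0.1) {
  if (sd_rel <= 0) return(params)
  lj <- function(x) x * exp(rnorm(1, 0, sd_rel))
  ts <- params$two_state
  ts$A_f <- min(max(plogis(qlogis(ts$A_f) + rnorm(1, 0, sd_rel)), 0.5), 0.97)
  ts$A_s <- min(max(plogis(qlogis(ts$A_s) + rnorm(1, 0, sd_rel)), ts$A_f + 0.01), 0.999)
  ts$B_f <- min(max(lj(ts$B_f), 0.02), 0.6)
  ts$B_s <- min(max(lj(ts$B_s), 0.002), ts$B_f - 0.001)
  pp <- params$pupil
  for (nm in c("novelty_bump", "surprise_gain", "surprise_gain_tonic",
               "tonic_init")) {
    pp[[nm]] <- lj(pp[[nm]])
  }
  params$two_state <- ts
  params$pupil <- pp
  params$calib_min_mm <- max(1.5, lj(params$calib_min_mm))
  params$calib_max_mm <- max(params$calib_min_mm + 2, lj(params$calib_max_mm))
  validate_participant_params(params)
  params
}

#' Simulate a full synthetic cohort
#'
#' Generates `n_participants` synthetic participants through the requested
#' design, with per-participant parameter jitter around `params` and a field
#' direction assignment matching the design's counterbalancing.  Everything
#' is reproducible from `seed`; the channel-placement stream is separate from
#' all noise streams.  With `out` set, writes the dataset to disk as plain
#' CSV files (one directory per participant, plus `schedule.csv`,
#' `truth.csv`, `reports.csv` and a JSON manifest).
#'
#' @param n_participants Number of participants (>= 1).
#' @param experiment_id Design name, see [make_schedule()].
#' @param seed Integer master seed.
#' @param params Baseline [participant_params()].
#' @param participant_sd Relative SD of the between-participant jitter
#'   (0 for an identical cohort).
#' @param out Optional output directory; created if needed.
#' @param keep_timeseries Keep the per-sample traces in memory (default: only
#'   when not writing to disk).  Feature-level tibbles are always kept.
#' @param noise Passed to [simulate_participant()].
#' @param ... Further arguments to [simulate_participant()].
#' @return A list of class `pupil_cohort`: `schedule`, `truth`, `reports`,
#'   `latents`, `events`, `blinks`, `saccades`, `calib`, `timeseries` (or
#'   `NULL`), and `config`.
#' @export
simulate_cohort <- function(n_participants, experiment_id = "exp1", seed = 1L,
                            params = participant_params(),
                            participant_sd = 0.1, out = NULL,
                            keep_timeseries = is.null(out), noise = TRUE,
                            ...) {
  stopifnot(n_participants >= 1)
  schedule <- make_schedule(experiment_id, channel_seed = seed)
  prop_cw <- switch(experiment_id,
                    exp1 = 20 / 28, exp3 = 0.5, exp4 = 19 / 34, 1)
  n_cw <- if (attr(schedule, "flip_direction")) {
    max(1L, round(prop_cw * n_participants))
  } else {
    n_participants
  }
  directions <- rep(c("CW", "CCW"),
                    c(n_cw, n_participants - n_cw))[seq_len(n_participants)]

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out)) stop("cannot create output directory: ", out)
    readr::write_csv(schedule_to_csv(schedule), file.path(out, "schedule.csv"))
  }

  truth <- vector("list", n_participants)
  parts <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    set.seed(as.integer(child_seed(seed, 1000 + p)))
    pp <- jitter_params(params, participant_sd)
    sim <- simulate_participant(schedule, pp, directions[p],
                                seed = child_seed(seed, p), noise = noise, ...)
    truth[[p]] <- tibble::tibble(
      participant = p, direction = directions[p],
      A_f = pp$two_state$A_f, A_s = pp$two_state$A_s,
      B_f = pp$two_state$B_f, B_s = pp$two_state$B_s,
      tonic_floor = pp$pupil$tonic_floor,
      novelty_bump = pp$pupil$novelty_bump,
      tonic_decay = pp$pupil$tonic_decay,
      surprise_gain = pp$pupil$surprise_gain,
      surprise_gain_tonic = pp$pupil$surprise_gain_tonic,
      habituation_rate = pp$pupil$habituation_rate,
      calib_min_mm = pp$calib_min_mm, calib_max_mm = pp$calib_max_mm,
      blink_rate = pp$blink_rate, saccade_rate = pp$saccade_rate
    )
    if (!is.null(out)) {
      pdir <- file.path(out, sprintf("participant_%02d", p))
      dir.create(pdir, showWarnings = FALSE)
      readr::write_csv(sim$timeseries, file.path(pdir, "timeseries.csv"))
      readr::write_csv(sim$events, file.path(pdir, "events.csv"))
      readr::write_csv(sim$blinks, file.path(pdir, "blinks.csv"))
      readr::write_csv(sim$calib, file.path(pdir, "calib.csv"))
      readr::write_csv(sim$latents, file.path(pdir, "latents.csv"))
    }
    if (!keep_timeseries) sim$timeseries <- NULL
    parts[[p]] <- sim
  }

  truth <- dplyr::bind_rows(truth)
  reports <- dplyr::bind_rows(purrr::imap(parts, function(s, p) {
    tibble::tibble(participant = p, block = seq_along(s$report),
                   present = as.integer(s$report))
  }))
  add_pid <- function(field) {
    dplyr::bind_rows(purrr::imap(parts, function(s, p) {
      if (is.null(s[[field]]) || nrow(s[[field]]) == 0) return(NULL)
      tibble::tibble(participant = p, s[[field]])
    }))
  }
  config <- list(n_participants = n_participants,
                 experiment_id = experiment_id, seed = seed,
                 participant_sd = participant_sd, noise = noise)
  res <- structure(list(
    schedule = schedule, truth = truth, reports = reports,
    latents = add_pid("latents"), events = add_pid("events"),
    blinks = add_pid("blinks"), saccades = add_pid("saccades"),
    calib = add_pid("calib"),
    timeseries = if (keep_timeseries) add_pid("timeseries") else NULL,
    participants = parts, config = config
  ), class = "pupil_cohort")
  if (!is.null(out)) {
    readr::write_csv(truth, file.path(out, "truth.csv"))
    readr::write_csv(reports, file.path(out, "reports.csv"))
    jsonlite::write_json(config, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

schedule_to_csv <- function(schedule) {
  dplyr::select(tibble::as_tibble(schedule), "trial_index", "reach_index",
                "block", "B", "is_channel", "is_light_reflex",
                "is_change_point")
}

#' Read a cohort dataset written by [simulate_cohort()]
#'
#' @param dir Directory previously passed as `out`.
#' @return A list with `schedule`, `truth`, `reports`, `manifest`, and the
#'   per-participant directory names.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  list(
    schedule = readr::read_csv(file.path(dir, "schedule.csv"),
                               show_col_types = FALSE),
    truth = readr::read_csv(file.path(dir, "truth.csv"),
                            show_col_types = FALSE),
    reports = readr::read_csv(file.path(dir, "reports.csv"),
                              show_col_types = FALSE),
    manifest = manifest,
    participant_dirs = sort(list.dirs(dir, recursive = FALSE))
  )
}
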