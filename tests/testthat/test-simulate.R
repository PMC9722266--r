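test_that("unperturbed noiseless reaches are perfectly straight", {
  tr <- simulate_reach(B = 0, compensation = 0, noise = FALSE)
  expect_true(all(abs(tr$hand_x) < 1e-12))
  expect_true(all(abs(tr$vel_x) < 1e-12))
  expect_true(all(tr$force_x == 0))
  ev <- attr(tr, "events")
  expect_lt(ev$movement_onset, ev$movement_offset)
  expect_equal(ev$go_cue, 1.5)
})

test_that("curl-field deflection matches a fine-step RK4 reference", {
  p <- participant_params()
  tr <- simulate_reach(B = 0.15, compensation = 0, noise = FALSE,
                       feedback = FALSE)
  oracle <- rk4_lateral_oracle(B = 0.15, comp = 0, mass = p$mass,
                               amplitude = 0.12, mt_s = 0.6, t_move = 1.8,
                               t_end = max(tr$t))
  ref <- approx(oracle$t, oracle$x, xout = tr$t)$y
  expect_lt(max(abs(tr$hand_x - ref)), 1e-6)
  # rightward (positive) deviation at peak speed for a CW field
  pk <- which.max(sqrt(tr$vel_x^2 + tr$vel_y^2))
  expect_gt(tr$hand_x[pk], 0)
})

test_that("the curl field delivers zero power at every sample", {
  for (B in c(0.15, -0.12)) {
    tr <- simulate_reach(B = B, compensation = 0.03, noise = FALSE)
    power <- tr$force_x * tr$vel_x + tr$force_y * tr$vel_y
    expect_lt(max(abs(power)), 1e-12)
  }
})

test_that("the channel contains the hand within its static deflection bound", {
  # feedforward force up to ~5 N against the stiff channel
  tr <- simulate_reach(B = 0, is_channel = TRUE, compensation = 8,
                       noise = FALSE)
  expect_lt(max(abs(tr$hand_x)), 2e-3)
})

test_that("latent updates have the stated fixed points and additive novelty bump", {
  p <- participant_params()
  pf <- p$pupil
  lat <- list(tonic = pf$tonic_floor + 20, expected_error = 0.01)
  # error at expectation: unit surprise, geometric relaxation to the floor
  up <- update_latents(lat, 0.01, block_start = FALSE, params = p)
  expect_equal(up$surprise, 1)
  expect_equal(up$tonic, pf$tonic_floor + pf$tonic_decay * 20)
  expect_equal(up$expected_error, 0.01)
  # block start with zero error adds exactly the novelty bump
  up0 <- update_latents(lat, 0, block_start = FALSE, params = p)
  up1 <- update_latents(lat, 0, block_start = TRUE, params = p)
  expect_equal(up1$tonic - up0$tonic, pf$novelty_bump)
  expect_error(update_latents(lat, -0.1, params = p), "non-negative")
})

test_that("expected error converges under repeated constant input (recursion oracle)", {
  p <- participant_params(pupil = list(habituation_rate = 0.5))
  lat <- list(tonic = 50, expected_error = 0.001)
  e0 <- 0.02
  expect_ref <- lat$expected_error
  for (i in 1:40) {
    lat <- update_latents(lat, e0, params = p)[c("tonic", "expected_error")]
    expect_ref <- expect_ref + 0.5 * (e0 - expect_ref)  # direct recursion
    expect_equal(lat$expected_error, expect_ref)
  }
  expect_equal(lat$expected_error, e0, tolerance = 1e-6)
  s <- update_latents(lat, e0, params = p)$surprise
  expect_equal(s, 1, tolerance = 1e-6)
})

test_that("the phasic pupil kernel peaks at onset + peak time and drives dilation velocity", {
  p <- participant_params()
  t <- seq(0, 4, by = 1 / 200)
  ev <- list(movement_onset = 1.8)
  flat <- simulate_pupil_trace(t, ev, surprise = 0, tonic = 55, params = p,
                               noise = FALSE)
  mm55 <- p$calib_min_mm + 0.55 * (p$calib_max_mm - p$calib_min_mm)
  expect_true(all(abs(flat$pupil_mm - mm55) < 1e-12))

  one <- simulate_pupil_trace(t, ev, surprise = 1, tonic = 55, params = p,
                              noise = FALSE)
  peak_t <- t[which.max(one$pupil_mm - mm55)]
  expect_equal(peak_t, 1.8 + p$pupil$irf_peak_time, tolerance = 1 / 200)

  s3 <- simulate_pupil_trace(t, ev, surprise = 3, tonic = 55, params = p,
                             noise = FALSE)
  norm <- 100 * (s3$pupil_mm - p$calib_min_mm) /
    (p$calib_max_mm - p$calib_min_mm)
  win <- t >= 1.8 + 0.3 & t <= 1.8 + 0.7
  expect_gt(mean(diff(norm)[win[-1]]) * 200, 0)  # numeric differentiation
  expect_error(simulate_pupil_trace(t, list(movement_onset = 9), 1, 55, p),
               "inside the trial")
})

test_that("light-reflex traces reach the calibration limits", {
  p <- participant_params()
  lr <- simulate_light_reflex(p, noise = FALSE)
  expect_lt(abs(max(lr$dark$pupil_mm) - p$calib_max_mm),
            0.01 * p$calib_max_mm)
  expect_lt(abs(min(lr$bright$pupil_mm) - p$calib_min_mm),
            0.01 * p$calib_min_mm)
  rest <- (p$calib_min_mm + p$calib_max_mm) / 2
  still <- simulate_light_reflex(p, stimulus_s = 0, noise = FALSE)
  expect_true(all(abs(still$dark$pupil_mm - rest) < 1e-12))
  # noisy extrema averaged over 5 repetitions stay within 2% of truth
  set.seed(41)
  dark_max <- replicate(5, max(simulate_light_reflex(p)$dark$pupil_mm))
  bright_min <- replicate(5, min(simulate_light_reflex(p)$bright$pupil_mm))
  expect_lt(abs(mean(dark_max) - p$calib_max_mm), 0.02 * p$calib_max_mm)
  expect_lt(abs(mean(bright_min) - p$calib_min_mm), 0.02 * p$calib_min_mm)
})

test_that("cohort simulation is deterministic and round-trips through disk", {
  dir1 <- file.path(tempdir(), "coh1")
  on.exit(unlink(dir1, recursive = TRUE), add = TRUE)
  a <- simulate_cohort(2, "exp1", seed = 9)
  b <- simulate_cohort(2, "exp1", seed = 9, out = dir1,
                       keep_timeseries = TRUE)
  expect_identical(a$latents, b$latents)
  expect_identical(a$truth, b$truth)
  expect_identical(a$timeseries, b$timeseries)
  expect_false(identical(a$latents,
                         simulate_cohort(2, "exp1", seed = 10)$latents))

  rc <- read_cohort(dir1)
  expect_equal(nrow(rc$schedule), nrow(a$schedule))
  expect_equal(rc$truth, a$truth, tolerance = 1e-12)
  expect_equal(rc$manifest$seed, 9)
  expect_equal(rc$manifest$experiment_id, "exp1")
  expect_length(rc$participant_dirs, 2)
  ev <- readr::read_csv(file.path(rc$participant_dirs[1], "events.csv"),
                        show_col_types = FALSE)
  expect_equal(nrow(ev), 260)  # one row per reaching trial of the design
})
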