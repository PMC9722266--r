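t200 <- function(n) (seq_len(n) - 1) / 200

test_that("blink interpolation is exact on lines, inert without blinks, and local", {
  t <- t200(400)
  x <- 2 + 3 * t                       # linear ramp
  iv <- matrix(c(0.8, 1.0), ncol = 2)
  out <- deblink(x, t, iv)
  expect_equal(as.numeric(out), x, tolerance = 1e-12)

  x2 <- sin(2 * pi * t) + rnorm(400)
  out2 <- deblink(x2, t, matrix(numeric(0), ncol = 2))
  expect_identical(as.numeric(out2), x2)

  # samples outside the masked window are bit-identical
  out3 <- deblink(x2, t, iv)
  masked <- attr(out3, "masked")
  expect_identical(as.numeric(out3)[!masked], x2[!masked])
  expect_true(all(t[masked] >= 0.8 - 0.100 - 1e-9 &
                    t[masked] <= 1.0 + 0.150 + 1e-9))
})

test_that("blink interpolation tracks a slow sine and handles edges", {
  t <- t200(800)                       # 4 s
  x <- sin(2 * pi * t / 4)             # period 4 s
  out <- deblink(x, t, matrix(c(1.5, 1.8), ncol = 2))  # 300 ms gap
  expect_lt(max(abs(as.numeric(out) - x)), 0.02)       # < 2% of amplitude

  edge <- deblink(x, t, matrix(c(0, 0.1), ncol = 2))
  expect_true(attr(edge, "edge_extended"))
  expect_error(deblink(x, t, matrix(c(-1, 10), ncol = 2)), "entire trace")
})

test_that("Gaussian smoothing matches its closed-form kernel and preserves constants", {
  x <- rep(3.7, 200)
  expect_equal(gaussian_smooth(x, 235), x, tolerance = 1e-12)

  imp <- c(rep(0, 100), 1, rep(0, 100))
  sm <- gaussian_smooth(imp, 35, 200)
  sigma <- 35 / 1000 / (2 * sqrt(2 * log(2))) * 200
  half <- ceiling(4 * sigma)
  kern <- dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  expect_lt(max(abs(sm[101 + (-half:half)] - kern)), 1e-9)

  # white-noise variance shrinks by the kernel's sum of squares
  set.seed(5)
  w <- rnorm(20000)
  sw <- gaussian_smooth(w, 235, 200)
  sigma2 <- 235 / 1000 / (2 * sqrt(2 * log(2))) * 200
  half2 <- ceiling(4 * sigma2)
  k2 <- dnorm(-half2:half2, sd = sigma2)
  k2 <- k2 / sum(k2)
  expect_equal(var(sw) / var(w), sum(k2^2), tolerance = 0.05)
  expect_warning(gaussian_smooth(w[1:50], 1, 200), "unchanged")
})

test_that("Gaussian smoothing is linear and shift-equivariant on interior samples", {
  set.seed(7)
  x <- rnorm(300); y <- rnorm(300)
  sboth <- gaussian_smooth(2 * x + 3 * y, 35)
  expect_equal(sboth, 2 * gaussian_smooth(x, 35) + 3 * gaussian_smooth(y, 35),
               tolerance = 1e-12)
  shift <- 10
  a <- gaussian_smooth(x, 35)
  b <- gaussian_smooth(c(rep(0, shift), x), 35)
  interior <- 30:270
  expect_equal(b[interior + shift], a[interior], tolerance = 1e-12)
})

test_that("Savitzky-Golay differentiation is exact on low-order polynomials", {
  t <- t200(200)
  v <- savgol_velocity(5 + 10 * t)           # slope 10/s
  expect_lt(max(abs(v[10:190] - 10)), 1e-9)
  vq <- savgol_velocity(1 + 2 * t + 4 * t^2) # derivative 2 + 8 t
  d_true <- 2 + 8 * (t + 0.5 / 200)          # forward difference midpoint
  expect_lt(max(abs(vq[10:180] - d_true[10:180])), 1e-9)
  expect_error(savgol_velocity(1:5), "shorter")
})

test_that("Savitzky-Golay smoothing agrees with a per-window least-squares oracle", {
  set.seed(11)
  t <- t200(300)
  x <- ifelse(t > 0.7, 3 * (t - 0.7), 0) + rnorm(300, 0, 0.05)  # step-ramp
  ours <- signal::sgolayfilt(x, p = 2, n = 11)
  ref <- sg_ls_oracle(x, 2, 11)
  interior <- which(!is.na(ref))
  expect_lt(max(abs(ours[interior] - ref[interior])), 1e-9)
})

test_that("visual-angle transform follows the arctangent exactly", {
  expect_equal(unlist(to_visual_angle(0, 0, 440)), c(theta_x = 0, theta_y = 0))
  expect_equal(to_visual_angle(440, 0, 440)$theta_x, 45)
  expect_equal(to_visual_angle(10, -10, 440)$theta_x,
               atan(10 / 440) * 180 / pi, tolerance = 1e-12)
})

test_that("saccade detection respects the threshold, merges and recovers events", {
  t <- t200(200)
  none <- detect_saccades(rep(29.9, 200), rep(0, 200), t)
  expect_equal(nrow(none), 0)
  expect_equal(nrow(detect_saccades(rep(0, 200), rep(0, 200), t)), 0)

  set.seed(13)
  vx <- rnorm(200, 0, 2)
  vx[100:106] <- 40                           # 35 ms pulse
  sac <- detect_saccades(vx, rnorm(200, 0, 2), t)
  expect_equal(nrow(sac), 1)
  expect_lte(sac$start, t[100])
  expect_gte(sac$end, t[106])
  expect_gte(sac$peak_velocity, 40)

  # full-chain recall and precision on synthetic saccades >= 2 deg
  hits <- 0; false_pos <- 0; total <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    n <- 600
    tt <- t200(n)
    amp <- runif(1, 2, 4)
    t0 <- runif(1, 1, 2)
    theta <- rnorm(n, 0, 0.05) +
      amp * plogis((tt - t0) / 0.005)
    vel <- savgol_velocity(theta)
    det <- detect_saccades(vel, rep(0, n), tt)
    total <- total + 1
    covered <- nrow(det) > 0 && any(det$start <= t0 + 0.02 &
                                      det$end >= t0 - 0.02)
    if (covered) hits <- hits + 1
    false_pos <- false_pos + sum(det$end < t0 - 0.05 | det$start > t0 + 0.05)
  }
  expect_equal(hits, total)      # recall 1
  expect_equal(false_pos, 0)     # precision 1
})

test_that("light-reflex calibration averages per-block extrema", {
  calib <- dplyr::bind_rows(
    tibble::tibble(block = 1, stimulus = "bright", t = t200(5),
                   pupil_mm = c(3, 2, 2.5, 3, 3)),
    tibble::tibble(block = 1, stimulus = "dark", t = t200(5),
                   pupil_mm = c(5, 6, 5.5, 5, 5)),
    tibble::tibble(block = 2, stimulus = "bright", t = t200(5),
                   pupil_mm = c(4, 3, 3.5, 4, 4)),
    tibble::tibble(block = 2, stimulus = "dark", t = t200(5),
                   pupil_mm = c(6, 7, 6.5, 6, 6))
  )
  cal <- calibrate_pupil(calib)
  expect_equal(cal$d_min, 2.5)
  expect_equal(cal$d_max, 6.5)
  one <- calibrate_pupil(calib[calib$block == 1, ])
  expect_equal(one$d_min, 2)
  expect_equal(one$d_max, 6)
  bad <- calib
  bad$pupil_mm[bad$stimulus == "bright"] <- 10
  expect_error(calibrate_pupil(bad), "d_min >= d_max")

  # generator-truth recovery from noiseless reflex trials
  p <- participant_params(calib_min_mm = 2, calib_max_mm = 6)
  lr <- simulate_light_reflex(p, noise = FALSE)
  cal2 <- calibrate_pupil(dplyr::bind_rows(
    tibble::tibble(block = 1, stimulus = "dark", lr$dark),
    tibble::tibble(block = 1, stimulus = "bright", lr$bright)
  ))
  expect_equal(cal2$d_min, 2, tolerance = 0.01)
  expect_equal(cal2$d_max, 6, tolerance = 0.01)
})

test_that("normalization maps the light-reflex range onto 0-100% and preserves order", {
  cal <- structure(list(d_min = 2, d_max = 6), class = "pupil_calibration")
  expect_equal(normalize_pupil(2, cal), 0)
  expect_equal(normalize_pupil(6, cal), 100)
  expect_equal(normalize_pupil(4, cal), 50)
  set.seed(17)
  x <- runif(100, 1, 7)
  expect_identical(rank(normalize_pupil(x, cal)), rank(x))
  expect_error(normalize_pupil(3, structure(list(d_min = 2, d_max = 2),
                                            class = "pupil_calibration")))
  # ramp covering the range in 1 s differentiates to 100 %/s
  t <- t200(400)
  ramp <- 2 + 4 * t
  vel <- pupil_velocity(normalize_pupil(ramp, cal))
  expect_lt(max(abs(vel[10:380] - 100)), 1e-9)
})
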