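truth_params <- list(A_f = 0.90, A_s = 0.995, B_f = 0.15, B_s = 0.02)

test_that("the two-state recursion has the stated algebraic structure", {
  z <- two_state_simulate(truth_params, rep(0, 50))
  expect_true(all(z$x == 0) && all(z$e == 0))

  p <- list(A_f = 0.9, A_s = 0.99, B_f = 0.2, B_s = 0.02)
  s <- two_state_simulate(p, rep(1, 4000))
  # fixed point: x_i* = B_i e* / (1 - A_i), e* = 1 - x*
  e_star <- 1 / (1 + p$B_f / (1 - p$A_f) + p$B_s / (1 - p$A_s))
  expect_equal(tail(s$x, 1), 1 - e_star, tolerance = 1e-6)
  expect_equal(tail(s$e, 1), e_star, tolerance = 1e-6)
  expect_equal(s$x[2], p$B_f + p$B_s)  # one step from rest

  # channel trials: retention-only update
  ch <- two_state_simulate(p, rep(1, 3), is_channel = c(FALSE, TRUE, FALSE))
  expect_equal(ch$x[3], p$A_f * ch$x_f[2] + p$A_s * ch$x_s[2])

  # superposition: replaying the joint error through each subsystem alone
  # reproduces the joint states exactly
  f <- c(rep(0, 5), rep(1, 30), rep(0, 15))
  joint <- two_state_simulate(truth_params, f)
  xf <- 0; xs <- 0
  for (i in seq_along(f)) {
    expect_identical(joint$x[i], xf + xs)
    xf <- truth_params$A_f * xf + truth_params$B_f * joint$e[i]
    xs <- truth_params$A_s * xs + truth_params$B_s * joint$e[i]
  }
  expect_error(two_state_simulate(list(A_f = 0.99, A_s = 0.9, B_f = 0.1,
                                       B_s = 0.01), rep(1, 5)),
               "violate")
})

test_that("fitting recovers the generating parameters", {
  sch <- make_schedule("exp1")
  rt <- reaching_trials(sch)
  f <- abs(rt$B) / 0.15
  sim <- two_state_simulate(truth_params, f, rt$is_channel)
  obs <- ifelse(rt$is_channel, sim$x, NA)

  fit <- two_state_fit(obs, f, rt$is_channel)
  for (nm in c("A_f", "A_s", "B_f", "B_s")) {
    expect_lt(abs(fit[[nm]] - truth_params[[nm]]), 1e-4)
  }
  # objective at the optimum is no worse than at the truth
  sse_truth <- sum((obs - sim$x)^2, na.rm = TRUE)
  expect_lte(fit$objective, sse_truth + 1e-10)

  flat <- two_state_fit(ifelse(rt$is_channel, 0, NA), f, rt$is_channel)
  expect_true(flat$unidentifiable)
  expect_error(two_state_fit(c(0.1, NA, NA), c(1, 1, 1), rep(FALSE, 3)),
               "fewer observations")
})

test_that("slow-state retention is recovered to within 0.02 under observation noise", {
  sch <- make_schedule("exp1")
  rt <- reaching_trials(sch)
  f <- abs(rt$B) / 0.15
  sim <- two_state_simulate(truth_params, f, rt$is_channel)
  set.seed(31)
  errs <- replicate(30, {
    obs <- ifelse(rt$is_channel,
                  sim$x + rnorm(nrow(rt), 0, 0.02), NA)
    fit <- two_state_fit(obs, f, rt$is_channel, n_starts = 5,
                         seed = sample.int(1e6, 1))
    abs(fit$A_s - truth_params$A_s)
  })
  expect_lt(median(errs), 0.02)
})

test_that("percent-change latency matches the exhaustive-scan oracle", {
  r <- percent_change_latency(c(0, 50, 41, 39, 60, 70), thresholds = 40,
                              n_required = 3)
  expect_equal(r$latency, 5)   # exceedances at positions 2, 3, 5

  all_above <- percent_change_latency(rep(90, 10), n_required = 3)
  expect_true(all(all_above$latency == 3))

  mono <- percent_change_latency(seq(0, 100, length.out = 60),
                                 n_required = 3)
  expect_true(all(diff(mono$latency) >= 0))

  set.seed(37)
  for (k in 1:200) {
    s <- runif(sample(5:60, 1), -20, 120)
    nr <- sample(1:5, 1)
    got <- percent_change_latency(s, n_required = nr)
    want <- vapply(got$threshold, function(x) latency_oracle(s, x, nr), 0)
    expect_identical(got$latency, want)
  }
  expect_error(percent_change_latency(numeric(0)), "empty")
})

test_that("percent-change transform anchors the phase start at 0 and full change at 100", {
  x <- c(10, 7, 5, 3, 2)
  pc <- to_percent_change(x, start = 10, plateau = 2)
  expect_equal(pc[1], 0)
  expect_equal(pc[5], 100)
  expect_error(to_percent_change(x, 3, 3), "plateau")
})

test_that("the bootstrap band is calibrated for model-generated cohorts", {
  sch <- make_schedule("exp1")
  rt <- reaching_trials(sch)
  f <- abs(rt$B) / 0.15
  sim <- two_state_simulate(truth_params, f, rt$is_channel)
  set.seed(43)
  obs_mat <- t(replicate(14, ifelse(rt$is_channel,
                                    sim$x + rnorm(nrow(rt), 0, 0.03), NA)))
  bw <- bootstrap_washout_prediction(obs_mat, f, rt$is_channel,
                                     washout_start = 176, n_boot = 150,
                                     seed = 5)
  expect_equal(nrow(bw$draws), 150)        # draw count matches configuration
  expect_true(all(bw$band$lower <= bw$band$median + 1e-12))
  expect_true(all(bw$band$median <= bw$band$upper + 1e-12))
  # the noise-free truth trajectory lies inside the band nearly everywhere
  cover <- mean(sim$x[bw$band$trial] >= bw$band$lower &
                  sim$x[bw$band$trial] <= bw$band$upper)
  expect_gte(cover, 0.9)

  # under the null (data generated by the model family being fitted), the
  # below-band runs stay far short of the 5-consecutive-trial washout
  # signature: the band tracks fit uncertainty, which is smoother than the
  # per-trial group-mean noise, so isolated 1-3 trial dips are expected
  runs <- vapply(1:6, function(s) {
    set.seed(2000 + s)
    om <- t(replicate(14, ifelse(rt$is_channel,
                                 sim$x + rnorm(nrow(rt), 0, 0.03), NA)))
    bootstrap_washout_prediction(om, f, rt$is_channel, washout_start = 176,
                                 n_boot = 100,
                                 seed = 2000 + s)$below_band_run
  }, 0)
  expect_true(all(runs < 5))
  expect_lte(median(runs), 1)
})

test_that("faster-than-predicted washout is flagged as a below-band run", {
  sch <- make_schedule("exp1")
  rt <- reaching_trials(sch)
  f <- abs(rt$B) / 0.15
  sim <- two_state_simulate(truth_params, f, rt$is_channel)
  # actual washout decays twice as fast as the model's own prediction
  fast <- sim$x
  wash <- 176:nrow(rt)
  fast[wash] <- sim$x[wash] * exp(-0.35 * (seq_along(wash)))
  set.seed(47)
  hits <- replicate(5, {
    obs_mat <- t(replicate(12, ifelse(rt$is_channel,
                                      fast + rnorm(nrow(rt), 0, 0.02), NA)))
    bw <- bootstrap_washout_prediction(obs_mat, f, rt$is_channel,
                                       washout_start = 176, n_boot = 120,
                                       seed = sample.int(1e6, 1))
    bw$below_band_run
  })
  expect_gte(mean(hits >= 3), 0.9)
})

test_that("the error-pupil mixed model predicts washout dilation under the shared law", {
  gen <- function(seed, washout_gain = 1) {
    set.seed(seed)
    n <- 28
    a_i <- rnorm(n, 10, 1.5)
    b_i <- rnorm(n, 300, 30)
    err_base <- abs(rnorm(n, 0.001, 0.0004))
    err_pert <- abs(rnorm(n, 0.012, 0.003))
    err_wash <- abs(rnorm(n, 0.010, 0.003))
    train <- tibble::tibble(
      participant = rep(seq_len(n), 2),
      abs_error = c(err_base, err_pert),
      dilation = rep(a_i, 2) + rep(b_i, 2) * c(err_base, err_pert) +
        rnorm(2 * n, 0, 0.8)
    )
    test <- tibble::tibble(
      participant = seq_len(n), abs_error = err_wash,
      dilation = a_i + washout_gain * b_i * err_wash + rnorm(n, 0, 0.8)
    )
    lme_error_pupil_predict(train, test)
  }
  null_p <- vapply(1:10, function(s) gen(500 + s)$p.value, 0)
  expect_gte(mean(null_p > 0.05), 0.9)

  attn <- vapply(1:10, function(s) {
    r <- gen(700 + s, washout_gain = 0.5)
    (r$p.value < 0.05) && (mean(r$actual - r$predicted) < 0)
  }, TRUE)
  expect_gte(mean(attn), 0.8)

  # zero-variance pupil exercises the fixed-effects fallback
  degen <- tibble::tibble(participant = rep(1:6, 2), abs_error = runif(12),
                          dilation = 5)
  r <- lme_error_pupil_predict(degen, degen[1:6, ])
  expect_true(r$singular_fallback)
})
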