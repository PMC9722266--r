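# Build a synthetic trial table directly (no simulation) so the
# experiment-level analyses can be tested against a known construction.
fake_trial_table <- function(schedule, n_participants, seed = 1,
                             dil_fun = NULL, base_fun = NULL,
                             rt_fun = NULL) {
  rt_rows <- reaching_trials(schedule)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_participants), function(p) {
    n <- nrow(rt_rows)
    dil <- if (is.null(dil_fun)) rnorm(n) else dil_fun(p, rt_rows) + rnorm(n)
    bas <- if (is.null(base_fun)) rnorm(n, 50) else
      base_fun(p, rt_rows) + rnorm(n)
    rtv <- if (is.null(rt_fun)) rnorm(n, 0.3, 0.02) else
      rt_fun(p, rt_rows) + rnorm(n, 0, 0.02)
    tibble::tibble(
      participant = p, reach_index = rt_rows$reach_index,
      block = rt_rows$block, cycle = ceiling(rt_rows$reach_index / 5),
      B = rt_rows$B, is_channel = rt_rows$is_channel,
      is_change_point = rt_rows$is_change_point,
      pve = abs(rt_rows$B) * 0.05 + rnorm(n, 0, 0.001),
      epe = abs(rnorm(n, 0.005, 0.001)),
      learning_index = ifelse(rt_rows$is_channel, abs(rt_rows$B), NA),
      baseline_pupil = bas, dilation_velocity = dil,
      rt = rtv, mt = rnorm(n, 0.6, 0.02),
      saccade_in_movement = FALSE, peak_speed = 0.4, sign_flipped = FALSE
    )
  })
}

test_that("change-point records carry the hand-derived environment run lengths", {
  sch <- make_schedule("exp2A")
  cps <- attr(sch, "change_points")
  expect_identical(cps,
                   c(61L, 90L, 130L, 160L, 170L, 180L, 190L, 210L, 220L,
                     230L, 240L))
  tt <- fake_trial_table(sch, 2, seed = 5)
  rec <- changepoint_table(tt, sch)
  one <- rec[rec$participant == 1, ]
  expect_identical(one$cp_reach_index, cps)
  expect_identical(one$prev_env_length,
                   c(60, 29, 29, 9, 10, 10, 10, 20, 10, 10, 10))
  expect_identical(one$cp_type[1], "introduction")
  expect_identical(one$cp_type[2], "reversal")
  expect_identical(one$cp_type[11], "removal")
  expect_equal(one$amp_dil, one$post_dil - one$pre_dil)

  # the abrupt design has exactly its introduction and removal
  sch1 <- make_schedule("exp1")
  rec1 <- changepoint_table(fake_trial_table(sch1, 1), sch1)
  expect_equal(nrow(rec1), 2)
})

test_that("within-participant z-scoring standardizes each feature vector", {
  sch <- make_schedule("exp2A")
  tt <- fake_trial_table(sch, 3, seed = 7)
  z <- dplyr::mutate(
    dplyr::group_by(tt, participant),
    z_dil = as.numeric(scale(dilation_velocity))
  )
  for (p in 1:3) {
    v <- z$z_dil[z$participant == p]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
})

test_that("the change-point mixed model recovers an amplitude decline over change points", {
  sch <- make_schedule("exp2A")
  signs <- vapply(1:5, function(s) {
    tt <- fake_trial_table(sch, 12, seed = 100 + s,
                           dil_fun = function(p, rt_rows) {
                             cps <- attr(sch, "change_points")
                             v <- numeric(nrow(rt_rows))
                             # response at each cp shrinking by 0.2 z per cp
                             for (k in seq_along(cps)) {
                               v[cps[k]] <- max(2.4 - 0.2 * k, 0)
                             }
                             v
                           })
    rec <- changepoint_table(tt, sch)
    fit <- changepoint_lme(rec, "dilation")
    fit$fixed$estimate[fit$fixed$term == "cp_number"]
  }, 0)
  expect_true(all(signs < 0))

  # constant direction and single group: terms dropped without error
  sch1 <- make_schedule("exp2C")
  rec1 <- changepoint_table(fake_trial_table(sch1, 8, seed = 3), sch1)
  fit1 <- changepoint_lme(rec1, "baseline")
  expect_false(any(grepl("group", fit1$fixed$term)))
  expect_s3_class(fit1$fixed, "tbl_df")
})

test_that("set-break contrasts average positions 1-2 versus 6-10 in the eligible blocks", {
  sch <- make_schedule("exp1")
  # inject a +3 early-trial elevation of baseline pupil in every block
  tt <- fake_trial_table(sch, 15, seed = 11,
                         base_fun = function(p, rt_rows) {
                           pos <- rt_rows$reach_index -
                             c(0, 55, 110, 165, 205)[rt_rows$block]
                           50 + ifelse(pos <= 2, 3, 0)
                         })
  res <- setbreak_contrast(tt, sch, "exp1")
  row <- res[res$measure == "baseline_pupil", ]
  expect_equal(row$delta, 3, tolerance = 0.5)
  expect_lt(row$p.value, 0.05)
  # stationary measures stay centred on zero
  expect_gt(res$p.value[res$measure == "mt"], 0.05)

  # only blocks 1, 2, 5 are eligible for the abrupt design: an effect
  # confined to block 3 must not move the contrast
  tt2 <- fake_trial_table(sch, 15, seed = 13,
                          base_fun = function(p, rt_rows) {
                            pos <- rt_rows$reach_index -
                              c(0, 55, 110, 165, 205)[rt_rows$block]
                            50 + ifelse(pos <= 2 & rt_rows$block == 3, 40, 0)
                          })
  res2 <- setbreak_contrast(tt2, sch, "exp1")
  expect_lt(abs(res2$delta[res2$measure == "baseline_pupil"]), 1)
})

test_that("the recall median split reproduces the tie-driven group asymmetry", {
  reports <- tibble::tibble(
    participant = rep(1:4, each = 7), block = rep(1:7, 4),
    present = as.integer(c(rep(c(1, 0), length.out = 7) * 0 + c(1, 1, 0, 0, 0, 0, 0),
                           c(1, 1, 1, 0, 0, 0, 0),
                           c(1, 1, 1, 1, 1, 0, 0),
                           c(1, 1, 1, 1, 1, 1, 0)))
  )
  sp <- recall_split(reports)
  expect_equal(sort(sp$scores$total), c(2, 3, 5, 6))
  expect_equal(sp$median_score, 4)
  expect_identical(sp$scores$group[order(sp$scores$total)],
                   c("low", "low", "high", "high"))

  # 14 scores of 2 and 16 scores of 4: at-median participants join "high"
  r2 <- tibble::tibble(
    participant = rep(1:30, each = 7), block = rep(1:7, 30),
    present = as.integer(unlist(purrr::map(1:30, function(p) {
      k <- if (p <= 14) 2 else 4
      c(rep(1, k), rep(0, 7 - k))
    })))
  )
  sp2 <- recall_split(r2)
  expect_equal(as.integer(table(sp2$scores$group)[c("low", "high")]), c(14, 16))

  # block-wise chi-squared equals the hand-computed Pearson statistic
  pb <- sp2$per_block[sp2$per_block$block == 3, ]
  tab <- matrix(c(14 - pb$low_present, pb$low_present,
                  16 - pb$high_present, pb$high_present),
                nrow = 2, byrow = TRUE)
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  expect_equal(pb$chisq, sum((tab - expd)^2 / expd), tolerance = 1e-10)

  same <- tibble::tibble(participant = rep(1:6, each = 7),
                         block = rep(1:7, 6), present = 1L)
  expect_error(recall_split(same), "split undefined")
})

test_that("the block x subgroup model flags only the block carrying a group difference", {
  sch <- make_schedule("exp3")
  mkrep <- function(n) tibble::tibble(
    participant = rep(seq_len(n), each = 7), block = rep(1:7, n),
    present = as.integer(unlist(purrr::map(seq_len(n), function(p) {
      k <- if (p <= n / 2) 1 else 5
      c(rep(1, k), rep(0, 7 - k))
    })))
  )
  n <- 20
  tt <- fake_trial_table(sch, n, seed = 17,
                         base_fun = function(p, rt_rows) {
                           bump <- if (p > n / 2) 2.5 else 0   # high group
                           50 + ifelse(rt_rows$block == 4, bump, 0)
                         })
  sp <- recall_split(mkrep(n))
  fit <- subgroup_block_lme(tt, sp, "baseline_pupil")
  hit <- fit$per_block[fit$per_block$block == 4, ]
  expect_lt(hit$p.value, 0.05)
  expect_gt(hit$estimate, 0)
  expect_true(all(fit$per_block$reject_bh[fit$per_block$reject_hb]))

  # identical groups: interaction estimates near zero
  tt0 <- fake_trial_table(sch, n, seed = 19)
  fit0 <- subgroup_block_lme(tt0, sp, "baseline_pupil")
  expect_lt(max(abs(fit0$per_block$estimate)), 1)
  expect_false(any(fit0$per_block$reject_hb))
})
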