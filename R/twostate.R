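#' Simulate the two-state learner
#'
#' Error-driven fast/slow state-space model of trial-by-trial adaptation:
#' `x_i(n+1) = A_i x_i(n) + B_i e(n)` for the fast and slow states, net
#' adaptation `x = x_f + x_s`, and error `e(n) = f(n) - x(n)` where `f` is
#' the perturbation normalized to 1 at full strength.  On channel trials the
#' error signal is clamped (`e = 0`), so the states update by retention
#' only.
#'
#' @param params List with `A_f`, `A_s` (retentions, `A_s > A_f`) and
#'   `B_f`, `B_s` (learning rates, `B_f > B_s`), all in (0,1).
#' @param f Perturbation series in normalized units.
#' @param is_channel Logical vector, same length as `f`.
#' @param x0 Initial fast/slow states (length-2).
#' @return Tibble with `trial`, `x`, `e`, `x_f`, `x_s`.
#' @export
two_state_simulate <- function(params, f, is_channel = rep(FALSE, length(f)),
                               x0 = c(0, 0)) {
  check_two_state(params)
  sim <- .two_state_sim_cpp(params$A_f, params$A_s, params$B_f, params$B_s,
                            as.numeric(f), as.logical(is_channel),
                            x0[1], x0[2])
  tibble::tibble(trial = seq_along(f), x = sim$x, e = sim$e,
                 x_f = sim$xf, x_s = sim$xs)
}

check_two_state <- function(p) {
  ok <- all(vapply(p[c("A_f", "A_s", "B_f", "B_s")],
                   function(v) is.finite(v) && v > 0 && v < 1, TRUE)) &&
    p$A_s > p$A_f && p$B_f > p$B_s
  if (!ok) stop("two-state parameters violate 0 < B_s < B_f < 1, ",
                "0 < A_f < A_s < 1")
  invisible(p)
}

# Map unconstrained optimizer coordinates to valid two-state parameters
# (ordering constraints hold by construction).
u_to_params <- function(u, bounds) {
  sig <- function(z) pmin(pmax(1 / (1 + exp(-z)), 1e-8), 1 - 1e-8)
  A_f <- bounds$A[1] + (bounds$A[2] - bounds$A[1]) * sig(u[1])
  A_s <- A_f + (bounds$A[2] - A_f) * sig(u[2])
  B_s <- bounds$B[1] + (bounds$B[2] - bounds$B[1]) * sig(u[3])
  B_f <- B_s + (bounds$B[2] - B_s) * sig(u[4])
  list(A_f = A_f, A_s = A_s, B_f = B_f, B_s = B_s)
}

#' Fit the two-state model to a channel-trial learning-index series
#'
#' Least-squares fit of the model-predicted net adaptation to the observed
#' learning index (normalized by the full field strength) at channel trials,
#' by multi-start quasi-Newton optimization in a transformed parameter space
#' that enforces `A_s > A_f` and `B_f > B_s` by construction.
#'
#' @param obs Observed normalized learning index per reaching trial (`NA`
#'   on non-channel trials and missing channels).
#' @param f Normalized perturbation series (same length).
#' @param is_channel Logical vector (same length).
#' @param bounds List with ranges `A` and `B`.
#' @param n_starts Number of seeded starting points (best-of-starts kept).
#' @param seed Integer seed for the start draws.
#' @param init Optional warm start (transformed coordinates, as stored in
#'   the `"u"` attribute of a previous fit), prepended to the random starts.
#' @param polish Run a final high-precision optimization from the best
#'   start (used for point estimates; bootstrap refits skip it).
#' @return A list of class `two_state_params`: the four estimates, the
#'   residual `objective`, `n_obs`, and `unidentifiable` (flat series pin
#'   both learning rates at the lower bound); attribute `"u"` holds the
#'   transformed optimum for warm starts.
#' @export
two_state_fit <- function(obs, f, is_channel,
                          bounds = list(A = c(0.10, 0.9999),
                                        B = c(1e-4, 0.9)),
                          n_starts = 20, seed = 1L, init = NULL,
                          polish = TRUE) {
  stopifnot(length(obs) == length(f), length(f) == length(is_channel))
  n_obs <- sum(!is.na(obs))
  if (n_obs < 4) stop("fewer observations than parameters")
  fx <- as.numeric(f)
  ch <- as.logical(is_channel)
  ob <- as.numeric(obs)
  obj <- function(u) {
    p <- u_to_params(u, bounds)
    .two_state_sse_cpp(p$A_f, p$A_s, p$B_f, p$B_s, fx, ch, ob)
  }
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  starts <- matrix(rnorm(4 * n_starts, 0, 1.5), ncol = 4)
  if (!is.null(init)) starts <- rbind(init, starts)
  ctrl <- if (polish) {
    list(maxit = 300, reltol = 1e-12)
  } else {
    list(maxit = 150, reltol = 1e-9)
  }
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[k, ], obj, method = "BFGS", control = ctrl),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed")
  if (polish) {
    best <- optim(best$par, obj, method = "BFGS",
                  control = list(maxit = 1000, reltol = 1e-15))
  }
  p <- u_to_params(best$par, bounds)
  p$objective <- best$value
  p$n_obs <- n_obs
  tolB <- 1e-3 * diff(bounds$B)
  p$unidentifiable <- (p$B_f - bounds$B[1] < tolB) &&
    (p$B_s - bounds$B[1] < tolB)
  structure(p, class = "two_state_params", u = best$par)
}

#' Bootstrap washout prediction from the two-state model
#'
#' Trains the two-state model on the group-average learning-index series up
#' to the last learning trial, with bootstrap resampling over participants:
#' each resample's average series is refit and simulated forward through the
#' washout schedule, giving a percentile band of predicted washout learning
#' indices.  The actual group average is compared against the band, and the
#' longest run of consecutive washout trials on which the group average
#' falls below the lower 95% bound is reported — the signature of faster
#' deadaptation than the fitted learning process predicts.
#'
#' @param obs_mat Participants x reaching-trials matrix of normalized
#'   learning index (`NA` off channel trials).
#' @param f Normalized perturbation series over reaching trials.
#' @param is_channel Logical vector over reaching trials.
#' @param washout_start Reaching-trial index of the first washout trial.
#' @param n_boot Bootstrap draw count.
#' @param seed Integer seed.
#' @param n_starts_boot Random optimizer starts per bootstrap refit, in
#'   addition to a warm start at the full-data point estimate (the point
#'   fit itself always uses 20 starts).
#' @param probs Percentile band probabilities.
#' @return A list of class `two_state_fit`: `point` (two_state_params),
#'   `draws` (tibble of bootstrap parameters), `band` (per washout channel
#'   trial: lower/median/upper, actual, below-band flag), `below_band_run`
#'   (longest consecutive below-band run), `n_boot`.
#' @export
bootstrap_washout_prediction <- function(obs_mat, f, is_channel,
                                         washout_start, n_boot = 1000,
                                         seed = 1L, n_starts_boot = 1,
                                         probs = c(0.025, 0.5, 0.975)) {
  stopifnot(nrow(obs_mat) >= 2, ncol(obs_mat) == length(f))
  if (n_boot < 100) warning("n_boot < 100 gives unstable bands")
  train_sel <- seq_along(f) < washout_start
  wash_ch <- which(!train_sel & as.logical(is_channel))

  group_obs <- colMeans(obs_mat, na.rm = TRUE)
  group_obs[is.nan(group_obs)] <- NA_real_
  mask_train <- function(x) {
    x[!train_sel] <- NA_real_
    x
  }
  point <- two_state_fit(mask_train(group_obs), f, is_channel,
                         n_starts = 20, seed = seed)

  np <- nrow(obs_mat)
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(child_seed(seed, 17)))
  draws <- vector("list", n_boot)
  pred <- matrix(NA_real_, nrow = n_boot, ncol = length(wash_ch))
  b <- 1L
  while (b <= n_boot) {
    idx <- sample.int(np, np, replace = TRUE)
    if (length(unique(idx)) < 2) next  # degenerate resample: draw again
    gm <- colMeans(obs_mat[idx, , drop = FALSE], na.rm = TRUE)
    gm[is.nan(gm)] <- NA_real_
    fit <- tryCatch(
      two_state_fit(mask_train(gm), f, is_channel,
                    n_starts = n_starts_boot, seed = child_seed(seed, b),
                    init = attr(point, "u"), polish = FALSE),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sim <- two_state_simulate(fit, f, is_channel)
    pred[b, ] <- sim$x[wash_ch]
    draws[[b]] <- tibble::tibble(draw = b, A_f = fit$A_f, A_s = fit$A_s,
                                 B_f = fit$B_f, B_s = fit$B_s)
    b <- b + 1L
  }
  qs <- apply(pred, 2, quantile, probs = probs, names = FALSE)
  band <- tibble::tibble(
    trial = wash_ch,
    lower = qs[1, ], median = qs[2, ], upper = qs[3, ],
    actual = group_obs[wash_ch]
  )
  band$below <- !is.na(band$actual) & band$actual < band$lower
  structure(list(
    point = point, draws = dplyr::bind_rows(draws), band = band,
    below_band_run = longest_run(band$below), n_boot = n_boot
  ), class = "two_state_fit")
}

#' @export
tidy.two_state_fit <- function(x, ...) {
  est <- unlist(x$point[c("A_f", "A_s", "B_f", "B_s")])
  qs <- purrr::map(names(est), function(nm) {
    quantile(x$draws[[nm]], c(0.025, 0.975), names = FALSE)
  })
  tibble::tibble(
    term = names(est), estimate = unname(est),
    conf.low = purrr::map_dbl(qs, 1), conf.high = purrr::map_dbl(qs, 2)
  )
}

#' @export
glance.two_state_fit <- function(x, ...) {
  tibble::tibble(
    n_boot = x$n_boot, below_band_run = x$below_band_run,
    objective = x$point$objective, n_obs = x$point$n_obs
  )
}

#' Transform a series to a percent-change index
#'
#' `100 * (x - start) / (plateau - start)`: 0 at the phase-start level, 100
#' at the full change.  For a washout phase pass the pre-removal plateau as
#' `start` and the baseline as `plateau`, which flips the series about its
#' plateau.
#'
#' @param x Series.
#' @param start Phase-start level.
#' @param plateau Full-change level.
#' @return Percent-change series.
#' @export
to_percent_change <- function(x, start, plateau) {
  if (plateau == start) stop("plateau equals start level")
  100 * (x - start) / (plateau - start)
}

#' Trial count to reach a percent-change criterion
#'
#' For each threshold `x`, the latency is the index of the `n_required`-th
#' sample whose percent-change value exceeds `x` — a criterion robust to
#' random fluctuation.  Missing when fewer than `n_required` samples exceed
#' the threshold.
#'
#' @param series Percent-change series (0 = phase start, 100 = full change;
#'   washout series pre-flipped about their plateau).
#' @param thresholds Percent thresholds.
#' @param n_required Number of exceedances required (10 for kinematic
#'   error, 3 for learning index).
#' @return A tibble of class `latency_result` with `threshold`, `latency`
#'   and `n_required`.
#' @export
percent_change_latency <- function(series, thresholds = c(40, 50, 60, 70, 80),
                                   n_required = 10) {
  if (length(series) == 0) stop("empty series")
  lat <- vapply(thresholds, function(x) {
    hits <- which(!is.na(series) & series > x)
    if (length(hits) < n_required) NA_real_ else as.numeric(hits[n_required])
  }, 0)
  structure(
    tibble::tibble(threshold = thresholds, latency = lat,
                   n_required = n_required),
    class = c("latency_result", class(tibble::tibble()))
  )
}

#' Does pupil dilation at force removal follow the error--pupil law?
#'
#' Fits a linear mixed model of pupil dilation velocity on absolute movement
#' error (fixed intercept and slope with random intercept and slope per
#' participant) to training pairs from the baseline and first force-field
#' trials, generates per-participant predictions from the first-washout
#' errors, and compares actual against predicted dilation with a two-sided
#' paired t-test.  A smaller-than-predicted washout response indicates that
#' dilation reflects surprise rather than error per se.  If the random
#' structure is singular, the model falls back to fixed effects only
#' (flagged).
#'
#' @param train Tibble with `participant`, `abs_error`, `dilation`.
#' @param test Tibble with the same columns for the first washout trial.
#' @return List with `predicted`, `actual`, `statistic`, `df`, `p.value`,
#'   `singular_fallback`, and the fitted `model`.
#' @export
lme_error_pupil_predict <- function(train, test) {
  stopifnot(length(unique(train$participant)) >= 5)
  train <- dplyr::filter(train, complete.cases(train))
  test <- dplyr::filter(test, complete.cases(test))
  fallback <- FALSE
  model <- tryCatch({
    m <- lme4::lmer(dilation ~ abs_error + (1 + abs_error | participant),
                    data = train, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
    if (lme4::isSingular(m, tol = 1e-4)) stop("singular")
    m
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(model)) {
    fallback <- TRUE
    model <- stats::lm(dilation ~ abs_error, data = train)
  }
  pred <- as.numeric(predict(model, newdata = test,
                             allow.new.levels = !fallback))
  tt <- t.test(test$dilation, pred, paired = TRUE)
  list(predicted = pred, actual = test$dilation,
       statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, singular_fallback = fallback, model = model)
}
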