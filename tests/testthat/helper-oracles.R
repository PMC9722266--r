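# Independent oracles used across test files.  These deliberately avoid the
# package's own implementations.

# Brute-force Holm-Bonferroni: literal step-down evaluation of the defining
# inequalities.
holm_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) reject[o[i]] <- TRUE else break
  }
  reject
}

# Brute-force Benjamini-Hochberg: literal step-up evaluation.
bh_oracle <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(ks) > 0) reject[o[seq_len(max(ks))]] <- TRUE
  reject
}

# Exhaustive-scan oracle for the percent-change latency.
latency_oracle <- function(series, x, n_required) {
  count <- 0
  for (i in seq_along(series)) {
    if (!is.na(series[i]) && series[i] > x) {
      count <- count + 1
      if (count == n_required) return(i)
    }
  }
  NA_real_
}

# Fine-step RK4 reference for the lateral point-mass under a curl field
# (no feedback, no channel): m x'' = (B - comp) * vy(t) - Kp x - Kd x'.
rk4_lateral_oracle <- function(B, comp, mass, amplitude, mt_s, t_move,
                               t_end, dt = 1e-4, Kp = 0, Kd = 0) {
  vy <- function(t) {
    tau <- (t - t_move) / mt_s
    ifelse(tau > 0 & tau < 1,
           amplitude / mt_s * (30 * tau^2 - 60 * tau^3 + 30 * tau^4), 0)
  }
  acc <- function(t, x, v) ((B - comp) * vy(t) - Kp * x - Kd * v) / mass
  n <- ceiling(t_end / dt)
  x <- 0; v <- 0; t <- 0
  xs <- numeric(n + 1); ts <- numeric(n + 1)
  for (i in seq_len(n)) {
    k1x <- v;               k1v <- acc(t, x, v)
    k2x <- v + dt / 2 * k1v; k2v <- acc(t + dt / 2, x + dt / 2 * k1x, v + dt / 2 * k1v)
    k3x <- v + dt / 2 * k2v; k3v <- acc(t + dt / 2, x + dt / 2 * k2x, v + dt / 2 * k2v)
    k4x <- v + dt * k3v;     k4v <- acc(t + dt, x + dt * k3x, v + dt * k3v)
    x <- x + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
    v <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    t <- t + dt
    xs[i + 1] <- x; ts[i + 1] <- t
  }
  list(t = ts, x = xs)
}

# Direct per-window least-squares Savitzky-Golay smoother (interior samples).
sg_ls_oracle <- function(x, order = 2, n_frame = 11) {
  half <- (n_frame - 1) / 2
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    idx <- (i - half):(i + half)
    fit <- lm.fit(outer(idx - i, 0:order, `^`), x[idx])
    out[i] <- fit$coefficients[1]
  }
  out
}

# Small fast parameter set for cohort-level tests.
quick_params <- function(...) {
  participant_params(...)
}
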