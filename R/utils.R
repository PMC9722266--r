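# Internal helpers shared across modules.

# Sampling rate used throughout (Hz).
SAMPLE_RATE <- 200

# Minimal-jerk position profile: returns position along the reach axis at
# times t for a movement of amplitude D starting at t = 0 lasting T_mt.
min_jerk_pos <- function(t, D, T_mt) {
  tau <- pmin(pmax(t / T_mt, 0), 1)
  D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

# Minimal-jerk velocity (time derivative of min_jerk_pos).
min_jerk_vel <- function(t, D, T_mt) {
  tau <- t / T_mt
  v <- (D / T_mt) * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  v[tau < 0 | tau > 1] <- 0
  v
}

# Derive a child seed from a base seed; keeps results inside 32-bit range.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 1103 * as.numeric(k)) %% 2147483647
}

# Longest run of TRUE in a logical vector (NA counts as FALSE).
longest_run <- function(x) {
  x[is.na(x)] <- FALSE
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
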