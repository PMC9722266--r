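#' Running paired t-tests across time frames
#'
#' Two-sided paired t-test at every time frame between two conditions'
#' subject-level mean traces, with Holm--Bonferroni (family-wise error 0.05)
#' and Benjamini--Hochberg (false-discovery rate 0.05) corrected rejection
#' masks and the first significant frame at or after movement onset for each
#' method.  Subjects missing at a frame are dropped pairwise (the per-frame
#' df is reported).
#'
#' @param a,b Numeric matrices, subjects x frames, on a common frame grid.
#' @param offsets_s Frame times relative to movement onset (s); defaults to
#'   the frame index.
#' @param alpha Family-wise error rate for Holm--Bonferroni.
#' @param q False discovery rate for Benjamini--Hochberg.
#' @return A tibble of class `running_test_result` with per-frame `t`, `df`,
#'   `p`, `reject_hb`, `reject_bh`; attribute `latency_ms` (named vector,
#'   first significant frame at/after onset per method, `NA` if none).
#' @export
running_paired_ttests <- function(a, b, offsets_s = NULL,
                                  alpha = 0.05, q = 0.05) {
  stopifnot(identical(dim(a), dim(b)), nrow(a) >= 2)
  d <- a - b
  nf <- ncol(d)
  offsets_s <- offsets_s %||% (seq_len(nf) - 1)
  n_ok <- colSums(!is.na(d))
  m <- colMeans(d, na.rm = TRUE)
  s <- apply(d, 2, sd, na.rm = TRUE)
  tt <- ifelse(n_ok >= 2, m / (s / sqrt(n_ok)), NA_real_)
  zero_var <- n_ok >= 2 & s == 0 & m != 0
  tt[zero_var] <- sign(m[zero_var]) * Inf
  tt[n_ok >= 2 & s == 0 & m == 0] <- 0  # identical conditions: no evidence
  df <- ifelse(n_ok >= 2, n_ok - 1, NA_real_)
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  p[zero_var] <- 0

  hb <- holm_bonferroni(p, alpha)
  bh <- benjamini_hochberg(p, q)
  res <- tibble::tibble(
    frame = seq_len(nf), time_s = offsets_s, t = tt, df = df, p = p,
    reject_hb = hb, reject_bh = bh, zero_variance = zero_var
  )
  lat <- c(
    hb = first_significant_latency(hb, offsets_s),
    bh = first_significant_latency(bh, offsets_s)
  )
  structure(res, class = c("running_test_result", class(res)),
            latency_ms = lat, alpha = alpha, q = q)
}

#' Holm--Bonferroni rejection mask
#'
#' Step-down familywise-error control: sort the p-values ascending and
#' reject while `p(i) <= alpha / (m - i + 1)`, stopping at the first
#' failure.  Computed through [stats::p.adjust()]; the defining step-down
#' inequalities are equivalent.
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` allowed, never rejected).
#' @param alpha Family-wise error rate.
#' @return Logical rejection mask.
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(p, method = "holm")
  !is.na(adj) & adj <= alpha
}

#' Benjamini--Hochberg rejection mask
#'
#' Step-up false-discovery-rate control: with ordered p-values, find the
#' largest `k` with `p(k) <= k q / m` and reject the `k` smallest.  Computed
#' through [stats::p.adjust()].
#'
#' @param p Vector of p-values in `[0, 1]` (`NA` allowed, never rejected).
#' @param q False discovery rate.
#' @return Logical rejection mask.
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(p, method = "BH")
  !is.na(adj) & adj <= q
}

#' Cluster-mass sign-flip permutation test
#'
#' Tests per-subject difference traces against zero.  Observed clusters are
#' maximal runs of frames whose paired t statistic exceeds the two-sided
#' `cluster_alpha` t-quantile, with positive and negative runs kept
#' separate; each cluster's mass is the sum of t within the run.  The null
#' distribution is the maximum absolute cluster mass over random (or, for
#' `n <= 12` subjects, all `2^n`) sign flips of the subject traces, and each
#' observed cluster's p-value is the add-one permutation estimate (exact
#' enumeration uses the plain proportion, which includes the identity flip
#' and so never returns 0).
#'
#' @param d Numeric matrix of difference traces, subjects x frames.  Frames
#'   containing missing subjects are dropped from cluster formation (and
#'   flagged in the result).
#' @param cluster_alpha Cluster-forming two-sided p threshold.
#' @param alpha Significance level for flagging clusters.
#' @param n_perm Number of random sign flips when sampling.
#' @param exact `"auto"` (enumerate when `2^n <= 2^12`), `"always"`, or
#'   `"never"`.
#' @return A list of class `cluster_result`: tibble `clusters` (`start`,
#'   `end`, `mass`, `p`, `significant`), per-frame `t`, the t `threshold`,
#'   `n_perm_used`, `exact`, and the frames dropped.
#' @export
cluster_mass_permutation <- function(d, cluster_alpha = 0.01, alpha = 0.05,
                                     n_perm = 10000, exact = c("auto",
                                                               "always",
                                                               "never")) {
  exact <- match.arg(exact)
  stopifnot(nrow(d) >= 2)
  if (n_perm < 100) warning("n_perm < 100 gives very coarse p-values")
  dropped <- which(colSums(is.na(d)) > 0)
  keep <- setdiff(seq_len(ncol(d)), dropped)
  dk <- d[, keep, drop = FALSE]
  n <- nrow(dk)
  nf <- ncol(dk)
  thr <- qt(1 - cluster_alpha / 2, df = n - 1)

  tstat <- function(m, ss) {
    v <- pmax((ss - n * m^2) / (n - 1), 0)
    ifelse(v > 0, m / sqrt(v / n), 0)
  }
  ss <- colSums(dk^2)
  t_obs <- tstat(colMeans(dk), ss)

  clusters <- cluster_runs(t_obs, thr)
  use_exact <- exact == "always" || (exact == "auto" && n <= 12)
  if (nrow(clusters) > 0) {
    if (use_exact) {
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    } else {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                      nrow = n_perm)
    }
    M <- (signs %*% dk) / n
    Tn <- t(tstat(t(M), ss))  # recycle ss across rows
    null_max <- .max_cluster_mass_cpp(Tn, thr)
    denom <- nrow(signs)
    clusters$p <- vapply(clusters$mass, function(ms) {
      # tolerance guards the identity flip against float round-off, so the
      # exact p can never fall below 1 / 2^n
      hits <- sum(null_max >= abs(ms) - 1e-9)
      if (use_exact) hits / denom else (1 + hits) / (denom + 1)
    }, 0)
  } else {
    clusters$p <- numeric(0)
  }
  clusters$significant <- clusters$p < alpha
  # map frame indices back to the original grid
  clusters$start <- keep[clusters$start]
  clusters$end <- keep[clusters$end]
  structure(list(
    clusters = clusters, t = t_obs, frames = keep, threshold = thr,
    cluster_alpha = cluster_alpha, alpha = alpha,
    n_perm_used = if (nrow(clusters) > 0) nrow(signs) else 0L,
    exact = use_exact, dropped_frames = dropped
  ), class = "cluster_result")
}

# Maximal suprathreshold same-sign runs of a t series.
cluster_runs <- function(t_obs, thr) {
  lab <- ifelse(t_obs > thr, 1L, ifelse(t_obs < -thr, -1L, 0L))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- r$values != 0
  tibble::tibble(
    start = starts[sel], end = ends[sel],
    mass = vapply(which(sel), function(k) {
      sum(t_obs[starts[k]:ends[k]])
    }, 0)
  )
}

#' Latency of the first significant frame
#'
#' First rejected frame at or after movement onset, in milliseconds relative
#' to onset; `NA` when the mask rejects nothing there.
#'
#' @param mask Logical rejection mask over frames.
#' @param offsets_s Frame times relative to movement onset (s).
#' @return Latency in ms, or `NA`.
#' @export
first_significant_latency <- function(mask, offsets_s) {
  ok <- which(mask & offsets_s >= 0)
  if (length(ok) == 0) return(NA_real_)
  offsets_s[ok[1]] * 1000
}

#' @export
tidy.cluster_result <- function(x, ...) {
  x$clusters
}

#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_significant = sum(x$clusters$significant),
    min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_,
    threshold_t = x$threshold, n_perm = x$n_perm_used, exact = x$exact
  )
}

#' @export
tidy.running_test_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.running_test_result <- function(x, ...) {
  lat <- attr(x, "latency_ms")
  tibble::tibble(
    n_frames = nrow(x), n_reject_hb = sum(x$reject_hb, na.rm = TRUE),
    n_reject_bh = sum(x$reject_bh, na.rm = TRUE),
    latency_hb_ms = lat[["hb"]], latency_bh_ms = lat[["bh"]]
  )
}
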