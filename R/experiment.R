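#' Change-point response records
#'
#' For every change point of the schedule (sudden within-block introduction,
#' reversal, or removal of the field) and every participant, computes the
#' pre/post response amplitudes of the individually z-scored pupil measures:
#' for dilation velocity, pre is the mean of the three trials before the
#' change point and post is the change-point trial itself; for baseline
#' pupil, the same pre window and post is the following trial (the baseline
#' responds one trial later).  Also derives the ordinal change-point number,
#' the length of the preceding constant environment, the change type, and
#' the error-magnitude covariates used by the mixed model.
#'
#' @param trial_table Tibble from [build_trial_table()].
#' @param schedule The `pupil_schedule` the cohort ran.
#' @param pre_window Number of pre-change trials averaged (truncated and
#'   flagged near block starts).
#' @return Tibble with one row per participant x change point.
#' @export
changepoint_table <- function(trial_table, schedule, pre_window = 3) {
  cps <- attr(schedule, "change_points")
  if (length(cps) == 0) {
    stop("schedule contains no within-block change points")
  }
  rt_rows <- reaching_trials(schedule)
  Bseq <- rt_rows$B
  blockseq <- rt_rows$block

  lcp <- vapply(cps, function(i) {
    prevB <- Bseq[i - 1]
    j <- i - 1
    while (j >= 1 && Bseq[j] == prevB) j <- j - 1
    (i - 1) - j
  }, 0)
  cp_type <- vapply(cps, function(i) {
    if (Bseq[i - 1] == 0) "introduction"
    else if (Bseq[i] == 0) "removal"
    else "reversal"
  }, "")
  new_dir <- vapply(cps, function(i) {
    b <- if (Bseq[i] != 0) Bseq[i] else Bseq[i - 1]
    if (b > 0) "CW" else "CCW"
  }, "")

  z <- function(x) as.numeric(scale(x))
  zt <- dplyr::mutate(
    dplyr::group_by(trial_table, .data$participant),
    z_dil = z(.data$dilation_velocity),
    z_base = z(.data$baseline_pupil)
  )
  zt <- dplyr::ungroup(zt)

  purrr::map_dfr(unique(zt$participant), function(p) {
    d <- dplyr::arrange(dplyr::filter(zt, .data$participant == p),
                        .data$reach_index)
    purrr::map_dfr(seq_along(cps), function(k) {
      i <- cps[k]
      blk_start <- min(d$reach_index[d$block == blockseq[i]])
      pre_idx <- max(i - pre_window, blk_start):(i - 1)
      truncated <- length(pre_idx) < pre_window
      pre_rows <- d[d$reach_index %in% pre_idx, ]
      post_dil <- d$z_dil[d$reach_index == i]
      post_base <- d$z_base[d$reach_index == i + 1]
      tibble::tibble(
        participant = p, cp_reach_index = i, cp_number = k,
        prev_env_length = lcp[k], cp_type = cp_type[k], direction = new_dir[k],
        pre_dil = mean(pre_rows$z_dil, na.rm = TRUE),
        post_dil = if (length(post_dil)) post_dil else NA_real_,
        pre_base = mean(pre_rows$z_base, na.rm = TRUE),
        post_base = if (length(post_base)) post_base else NA_real_,
        abs_pve_cp = abs(d$pve[d$reach_index == i]),
        abs_pve_prev = abs(d$pve[d$reach_index == i - 1]),
        abs_epe_prev = abs(d$epe[d$reach_index == i - 1]),
        pre_truncated = truncated
      )
    })
  }) |>
    dplyr::mutate(amp_dil = .data$post_dil - .data$pre_dil,
                  amp_base = .data$post_base - .data$pre_base)
}

#' Mixed-model trend of change-point responses
#'
#' Fits the change-point amplitudes with a linear mixed model containing
#' fixed effects for the change-point number and the preceding environment
#' length (the effects of interest), the perturbation direction, and the
#' error-magnitude covariate; random intercepts for participant (and group,
#' when more than one), and random slopes for the change-point number.  The
#' contribution of the random change-point-number slope is assessed by a
#' restricted-likelihood ratio test against the model without it.  Singular
#' fits fall back to a random-intercept-only model (flagged).
#'
#' @param records Tibble from [changepoint_table()], optionally with a
#'   `group` column.
#' @param response `"dilation"` (amplitude at the change-point trial, error
#'   covariate = absolute lateral error at the change point) or
#'   `"baseline"` (amplitude at the next trial, covariates = absolute
#'   lateral and endpoint error on the trial before the change point).
#' @return List with `fixed` (tibble of estimates, t, p per term), `lrt`
#'   (random-slope likelihood-ratio test), `singular_fallback`, `model`.
#' @export
changepoint_lme <- function(records, response = c("dilation", "baseline")) {
  response <- match.arg(response)
  d <- records
  d$y <- if (response == "dilation") d$amp_dil else d$amp_base
  d$err <- if (response == "dilation") d$abs_pve_cp else d$abs_pve_prev
  d$participant <- factor(d$participant)
  d <- dplyr::filter(d, is.finite(.data$y) & is.finite(.data$err))
  # error covariates are in metres (~1e-3) while trial counts reach ~1e2;
  # standardize them so the optimizer sees comparable scales
  zsafe <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) v - mean(v) else (v - mean(v)) / s
  }
  d$err <- zsafe(d$err)
  if ("abs_epe_prev" %in% names(d)) d$abs_epe_prev <- zsafe(d$abs_epe_prev)

  has_group <- "group" %in% names(d) && length(unique(d$group)) > 1
  has_dir <- length(unique(d$direction)) > 1
  fe <- c("cp_number", "prev_env_length", if (has_dir) "direction", "err",
          if (response == "baseline") "abs_epe_prev")
  fe_str <- paste(fe, collapse = " + ")
  re_full <- paste0("(1 + cp_number | participant)",
                    if (has_group) " + (1 | group)")
  re_red <- paste0("(1 | participant)", if (has_group) " + (1 | group)")
  f_full <- stats::as.formula(paste("y ~", fe_str, "+", re_full))
  f_red <- stats::as.formula(paste("y ~", fe_str, "+", re_red))

  fit_safe <- function(fml) {
    tryCatch(
      lmerTest::lmer(fml, data = d, REML = TRUE,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular =
                                                   lme4::.makeCC("ignore",
                                                                 tol = 1e-4))),
      error = function(e) NULL)
  }
  full <- fit_safe(f_full)
  fallback <- is.null(full) || lme4::isSingular(full, tol = 1e-4)
  red <- fit_safe(f_red)
  model <- if (fallback) red else full
  if (is.null(model)) stop("mixed model failed to fit")

  co <- as.data.frame(summary(model)$coefficients)
  fixed <- tibble::tibble(
    term = rownames(co), estimate = co[, "Estimate"],
    statistic = co[, "t value"], df = co[, "df"], p.value = co[, "Pr(>|t|)"]
  )
  lrt <- if (!is.null(full) && !is.null(red)) {
    stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red))))
    dfd <- 2  # slope variance + intercept-slope covariance
    list(statistic = stat, df = dfd, p.value = pchisq(stat, dfd,
                                                      lower.tail = FALSE))
  } else {
    list(statistic = NA_real_, df = NA_real_, p.value = NA_real_)
  }
  list(fixed = fixed, lrt = lrt, singular_fallback = fallback, model = model)
}

#' Early versus late trials after set breaks
#'
#' Within the blocks where the field is absent or still weak in the first
#' 10 trials (blocks 1, 2 and 5 for exp1; 1 and 2 for exp2; 1--4 for
#' exps 3/4), averages each measure per participant over trial positions
#' 1--2 since block start (early) and 6--10 (late), and compares early
#' against late with a two-sided paired t-test per measure.
#'
#' @param trial_table Tibble from [build_trial_table()].
#' @param schedule The cohort's `pupil_schedule` (for block starts).
#' @param experiment_id Design name, used to resolve eligible blocks (or
#'   pass `eligible_blocks`).
#' @param eligible_blocks Optional explicit block set.
#' @return Tibble with one row per measure: mean `delta` (early - late),
#'   `statistic`, `df`, `p.value`; attribute `per_participant`.
#' @export
setbreak_contrast <- function(trial_table, schedule, experiment_id = NULL,
                              eligible_blocks = NULL) {
  if (is.null(eligible_blocks)) {
    eligible_blocks <- switch(experiment_id,
      exp1 = c(1, 2, 5),
      exp2A = , exp2B = , exp2C = c(1, 2),
      exp3 = , exp4 = 1:4,
      stop("unknown experiment_id; pass eligible_blocks")
    )
  }
  blocks <- attr(schedule, "blocks")
  tt <- dplyr::left_join(trial_table,
                         dplyr::select(blocks, "block", "start"), by = "block")
  tt <- dplyr::mutate(tt, pos = .data$reach_index - .data$start + 1)
  tt <- dplyr::filter(tt, .data$block %in% eligible_blocks, .data$pos <= 10)
  measures <- c("baseline_pupil", "dilation_velocity", "rt", "mt")
  per_part <- purrr::map_dfr(measures, function(ms) {
    d <- dplyr::summarise(
      dplyr::group_by(tt, .data$participant),
      early = mean(.data[[ms]][.data$pos <= 2], na.rm = TRUE),
      late = mean(.data[[ms]][.data$pos >= 6 & .data$pos <= 10],
                  na.rm = TRUE),
      .groups = "drop"
    )
    dplyr::mutate(d, measure = ms, delta = .data$early - .data$late)
  })
  res <- purrr::map_dfr(measures, function(ms) {
    d <- dplyr::filter(per_part, .data$measure == ms,
                       is.finite(.data$delta))
    if (nrow(d) < 2) {
      return(tibble::tibble(measure = ms, delta = NA_real_,
                            statistic = NA_real_, df = NA_real_,
                            p.value = NA_real_))
    }
    tt_ <- t.test(d$early, d$late, paired = TRUE)
    tibble::tibble(measure = ms, delta = mean(d$delta),
                   statistic = unname(tt_$statistic),
                   df = unname(tt_$parameter), p.value = tt_$p.value)
  })
  attr(res, "per_participant") <- per_part
  res
}

#' Median split by perturbation recall
#'
#' Sums each participant's binary block-wise perturbation reports into a
#' total recall score, splits the cohort at the median (participants at the
#' median join the high-recall group, which reproduces the slightly uneven
#' group sizes that discrete scores and ties produce), and tests the
#' block-wise report-rate difference between the groups with a Pearson
#' chi-squared test (no continuity correction).
#'
#' @param reports Tibble with `participant`, `block`, `present` (0/1).
#' @param correct Continuity correction for the chi-squared tests.
#' @return List of class `subgroup_split`: `scores` (participant, total,
#'   group), `per_block` (counts, `chisq`, `p.value`), `median_score`.
#' @export
recall_split <- function(reports, correct = FALSE) {
  scores <- dplyr::summarise(
    dplyr::group_by(reports, .data$participant),
    total = sum(.data$present), .groups = "drop"
  )
  if (length(unique(scores$total)) == 1) {
    stop("all participants share the same recall score; split undefined")
  }
  med <- median(scores$total)
  scores$group <- ifelse(scores$total < med, "low", "high")
  d <- dplyr::left_join(reports, scores, by = "participant")
  per_block <- purrr::map_dfr(sort(unique(d$block)), function(b) {
    db <- dplyr::filter(d, .data$block == b)
    tab <- table(factor(db$group, c("low", "high")),
                 factor(db$present, c(0, 1)))
    ct <- suppressWarnings(tryCatch(chisq.test(tab, correct = correct),
                                    error = function(e) NULL))
    tibble::tibble(
      block = b,
      low_present = sum(db$present[db$group == "low"]),
      low_n = sum(db$group == "low"),
      high_present = sum(db$present[db$group == "high"]),
      high_n = sum(db$group == "high"),
      chisq = if (is.null(ct)) NA_real_ else unname(ct$statistic),
      p.value = if (is.null(ct)) NA_real_ else ct$p.value
    )
  })
  structure(list(scores = scores, per_block = per_block, median_score = med),
            class = "subgroup_split")
}

#' Block-wise subgroup comparison of cycle-binned measures
#'
#' Averages a measure within 5-trial cycles, then fits the mixed model with
#' a fixed intercept, a fixed cycle-within-block slope, random intercepts
#' per participant, random cycle slopes per participant and per block, and a
#' fixed block x subgroup interaction as the effect of interest (subgroup
#' coded +/- 1/2, giving one interaction coefficient per block, the
#' between-group difference in that block).  Interaction p-values
#' (Satterthwaite) are corrected across blocks with both Holm--Bonferroni
#' and Benjamini--Hochberg.
#'
#' @param trial_table Tibble from [build_trial_table()].
#' @param split A `subgroup_split` from [recall_split()].
#' @param response Column of `trial_table` to analyse.
#' @param exclude_cycles Cycles dropped before fitting (e.g. the washout
#'   phase for discontinuous measures).
#' @param alpha,q Correction levels.
#' @return List with `per_block` (estimate, statistic, df, p, `reject_hb`,
#'   `reject_bh`), `model`, `skipped_blocks`.
#' @export
subgroup_block_lme <- function(trial_table, split, response,
                               exclude_cycles = NULL,
                               alpha = 0.05, q = 0.05) {
  d <- dplyr::left_join(trial_table, split$scores, by = "participant")
  if (any(is.na(d$group))) stop("split does not cover all participants")
  d <- dplyr::filter(d, !is.na(.data[[response]]))
  if (!is.null(exclude_cycles)) {
    d <- dplyr::filter(d, !(.data$cycle %in% exclude_cycles))
  }
  cyc <- dplyr::summarise(
    dplyr::group_by(d, .data$participant, .data$group, .data$block,
                    .data$cycle),
    y = mean(.data[[response]], na.rm = TRUE), .groups = "drop"
  )
  cyc <- dplyr::mutate(
    dplyr::group_by(cyc, .data$block),
    cycle_in_block = .data$cycle - min(.data$cycle) + 1
  )
  cyc <- dplyr::ungroup(cyc)

  both <- dplyr::summarise(dplyr::group_by(cyc, .data$block),
                           n_groups = dplyr::n_distinct(.data$group),
                           .groups = "drop")
  skipped <- both$block[both$n_groups < 2]
  cyc <- dplyr::mutate(cyc,
    g = ifelse(.data$group == "high", 0.5, -0.5),
    gx = ifelse(.data$block %in% skipped, 0, .data$g),
    blockf = factor(.data$block), participant = factor(.data$participant)
  )
  model <- lmerTest::lmer(
    y ~ 1 + cycle_in_block + blockf:gx +
      (1 | participant) + (0 + cycle_in_block | participant) +
      (0 + cycle_in_block | blockf),
    data = cyc, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular =
                                  lme4::.makeCC("ignore", tol = 1e-4))
  )
  co <- as.data.frame(summary(model)$coefficients)
  ia <- grepl("^blockf.*:gx$", rownames(co))
  blocks <- as.integer(sub("^blockf(.*):gx$", "\\1", rownames(co)[ia]))
  per_block <- tibble::tibble(
    block = blocks, estimate = co[ia, "Estimate"],
    statistic = co[ia, "t value"], df = co[ia, "df"],
    p.value = co[ia, "Pr(>|t|)"]
  )
  per_block <- dplyr::filter(per_block, !(.data$block %in% skipped))
  per_block$reject_hb <- holm_bonferroni(per_block$p.value, alpha)
  per_block$reject_bh <- benjamini_hochberg(per_block$p.value, q)
  list(per_block = dplyr::arrange(per_block, .data$block), model = model,
       skipped_blocks = skipped)
}
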