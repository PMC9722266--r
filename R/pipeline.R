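#' Pipeline configuration
#'
#' Collects every knob of the simulate--preprocess--analyse pipeline in one
#' validated list.  The defaults are the analysis constants of the study
#' design this package models: 100/150 ms blink margins, 35 and 235 ms FWHM
#' smoothing kernels, a 55 ms second-order Savitzky--Golay frame, a
#' 30 deg/s saccade threshold, the 300--700 ms dilation-velocity window,
#' alpha = 0.05 and q = 0.05 corrections, a 0.01 cluster-forming p, 1,000
#' bootstrap draws, and 10/3 required exceedances for the percent-change
#' latency of kinematic error / learning index.
#'
#' @param experiment_id Design to simulate (see [make_schedule()]).
#' @param n_participants Cohort size.
#' @param seed Master seed.
#' @param ... Overrides for any listed default; unknown names are an error.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment_id = "exp1", n_participants = 28,
                            seed = 1L, ...) {
  cfg <- list(
    experiment_id = experiment_id, n_participants = n_participants,
    seed = seed,
    participant_sd = 0.1,
    blink_pre_ms = 100, blink_post_ms = 150,
    fwhm_gaze_ms = 35, fwhm_pupil_ms = 235,
    sg_order = 2, sg_frame_ms = 55,
    saccade_threshold = 30,
    baseline_window_s = 1.0, vel_window_s = c(0.3, 0.7),
    alpha = 0.05, q = 0.05, cluster_alpha = 0.01,
    n_perm = 10000, n_boot = 1000,
    n_required_kinematic = 10, n_required_learning = 3,
    stages = c("timeseries_stats", "adaptation", "setbreak",
               "changepoints", "subgroup"),
    params = participant_params()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full study pipeline on a synthetic cohort
#'
#' Simulates the cohort participant by participant, preprocesses and reduces
#' each participant to trial features and onset-locked pupil-velocity traces
#' (raw traces are discarded as soon as they are reduced, keeping memory
#' flat in cohort size), then runs the enabled analysis stages:
#'
#' * `timeseries_stats`: running paired t-tests (HB/BH corrected) and the
#'   cluster-mass permutation test on baseline-vs-perturbed pupil-velocity
#'   traces, plus the paired test of the baseline-pupil increase on the
#'   trial after the first perturbation.
#' * `adaptation`: two-state fit with bootstrap washout prediction and
#'   percent-change latencies for lateral error and learning index.
#' * `setbreak`: early/late contrasts after set breaks.
#' * `changepoints`: change-point response table and mixed-model trends.
#' * `subgroup`: recall median split, block-wise chi-squared tests, and the
#'   block x subgroup mixed models.
#'
#' @param config A [pipeline_config()].
#' @param out Optional directory; stage outputs are written there as CSV and
#'   JSON, stamped with the seed and a configuration hash.
#' @return A list of class `pupil_study` with `trials`, `locked`, `truth`,
#'   `reports`, `schedule`, `analyses`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sch <- make_schedule(config$experiment_id, channel_seed = config$seed)
  n <- config$n_participants
  prop_cw <- switch(config$experiment_id,
                    exp1 = 20 / 28, exp3 = 0.5, exp4 = 19 / 34, 1)
  n_cw <- if (attr(sch, "flip_direction")) max(1L, round(prop_cw * n)) else n
  directions <- rep(c("CW", "CCW"), c(n_cw, n - n_cw))[seq_len(n)]

  trials <- vector("list", n)
  locked <- vector("list", n)
  truth <- vector("list", n)
  reports <- vector("list", n)
  offs <- NULL
  for (p in seq_len(n)) {
    set.seed(as.integer(child_seed(config$seed, 1000 + p)))
    pp <- jitter_params(config$params, config$participant_sd)
    sim <- simulate_participant(sch, pp, directions[p],
                                seed = child_seed(config$seed, p))
    pf <- participant_features(sim, sch, p,
                               baseline_window_s = config$baseline_window_s,
                               vel_window_s = config$vel_window_s)
    flip <- directions[p] == "CCW"
    pf$trials <- dplyr::mutate(pf$trials,
      pve = if (flip) -.data$pve else .data$pve,
      learning_index = if (flip) -.data$learning_index
                       else .data$learning_index,
      sign_flipped = flip)
    trials[[p]] <- pf$trials
    locked[[p]] <- pf$locked
    offs <- pf$lock_offsets
    truth[[p]] <- tibble::tibble(participant = p, direction = directions[p],
                                 A_f = pp$two_state$A_f, A_s = pp$two_state$A_s,
                                 B_f = pp$two_state$B_f, B_s = pp$two_state$B_s,
                                 novelty_bump = pp$pupil$novelty_bump,
                                 surprise_gain = pp$pupil$surprise_gain)
    reports[[p]] <- tibble::tibble(participant = p,
                                   block = seq_along(sim$report),
                                   present = as.integer(sim$report))
  }
  study <- structure(list(
    trials = dplyr::bind_rows(trials),
    locked = list(per_participant = locked, offsets = offs),
    truth = dplyr::bind_rows(truth), reports = dplyr::bind_rows(reports),
    schedule = sch, config = config, analyses = list()
  ), class = "pupil_study")

  for (st in config$stages) {
    study$analyses[[st]] <- switch(st,
      timeseries_stats = stage_timeseries_stats(study),
      adaptation = stage_adaptation(study),
      setbreak = setbreak_contrast(study$trials, sch, config$experiment_id),
      changepoints = stage_changepoints(study),
      subgroup = stage_subgroup(study)
    )
  }
  if (!is.null(out)) write_study(study, out)
  study
}

# Per-subject mean onset-locked pupil-velocity traces over a trial set,
# excluding saccade-contaminated trials; frames at/after movement onset.
subject_mean_traces <- function(study, reach_set) {
  offs <- study$locked$offsets
  keep_f <- which(offs >= 0)
  tt <- study$trials
  mats <- purrr::imap(study$locked$per_participant, function(L, p) {
    pt <- tt[tt$participant == p, ]  # already arranged by reach_index
    good <- pt$reach_index[!pt$saccade_in_movement]
    rows <- match(intersect(reach_set, good), pt$reach_index)
    if (length(rows) == 0) return(rep(NA_real_, length(keep_f)))
    colMeans(L[rows, keep_f, drop = FALSE], na.rm = TRUE)
  })
  list(mat = do.call(rbind, mats), offsets = offs[keep_f])
}

stage_timeseries_stats <- function(study) {
  cfg <- study$config
  rt_rows <- reaching_trials(study$schedule)
  onset_trial <- which(rt_rows$B != 0)[1]
  base_set <- rt_rows$reach_index[rt_rows$block == 1 & !rt_rows$is_channel]
  pert_set <- head(rt_rows$reach_index[rt_rows$B != 0 & !rt_rows$is_channel], 5)

  base <- subject_mean_traces(study, base_set)
  pert <- subject_mean_traces(study, pert_set)
  run <- running_paired_ttests(pert$mat, base$mat, base$offsets,
                               alpha = cfg$alpha, q = cfg$q)
  clus <- cluster_mass_permutation(pert$mat - base$mat,
                                   cluster_alpha = cfg$cluster_alpha,
                                   alpha = cfg$alpha, n_perm = cfg$n_perm)

  tt <- study$trials
  # baseline increase on the trial after the first perturbation, relative to
  # the perturbation trial itself (the novelty bump at the block start makes
  # earlier trials an elevated reference)
  p1 <- dplyr::summarise(
    dplyr::group_by(tt, .data$participant),
    post = .data$baseline_pupil[.data$reach_index == onset_trial + 1],
    pre = .data$baseline_pupil[.data$reach_index == onset_trial],
    .groups = "drop"
  )
  bt <- t.test(p1$post, p1$pre, paired = TRUE)
  list(running = run, cluster = clus,
       baseline_p1 = list(statistic = unname(bt$statistic),
                          df = unname(bt$parameter), p.value = bt$p.value,
                          mean_increase = mean(p1$post - p1$pre)))
}

stage_adaptation <- function(study) {
  cfg <- study$config
  rt_rows <- reaching_trials(study$schedule)
  B_full <- attr(study$schedule, "B_full")
  nR <- nrow(rt_rows)
  # counterbalanced designs sign-flip participants into the CW convention,
  # so the group field is |B|; fixed switching schedules keep the sign
  f <- if (attr(study$schedule, "flip_direction")) {
    abs(rt_rows$B) / B_full
  } else {
    rt_rows$B / B_full
  }
  onset <- which(f != 0)[1]
  washout <- which(f == 0 & seq_len(nR) > onset)
  washout_start <- if (length(washout)) washout[1] else NA_integer_

  tt <- study$trials
  obs_mat <- matrix(NA_real_, nrow = length(unique(tt$participant)),
                    ncol = nR)
  for (p in unique(tt$participant)) {
    d <- tt[tt$participant == p, ]
    obs_mat[p, d$reach_index] <- d$learning_index / B_full
  }

  boot <- if (!is.na(washout_start)) {
    bootstrap_washout_prediction(obs_mat, f, rt_rows$is_channel,
                                 washout_start, n_boot = cfg$n_boot,
                                 seed = cfg$seed)
  } else {
    NULL
  }

  group_pve <- dplyr::summarise(
    dplyr::group_by(tt, .data$reach_index),
    pve = mean(.data$pve, na.rm = TRUE), .groups = "drop")
  li_series <- colMeans(obs_mat, na.rm = TRUE)

  lat <- list()
  if (!is.na(washout_start)) {
    learn_idx <- onset:(washout_start - 1)
    learn <- group_pve$pve[learn_idx]
    plateau_l <- mean(tail(learn, 25))
    lat$pve_learning <- percent_change_latency(
      to_percent_change(learn, learn[1], plateau_l),
      n_required = cfg$n_required_kinematic)
    wash <- group_pve$pve[washout_start:nR]
    plateau_w <- mean(tail(wash, 25))
    lat$pve_washout <- percent_change_latency(
      to_percent_change(wash, wash[1], plateau_w),
      n_required = cfg$n_required_kinematic)
    li_learn <- li_series[learn_idx]
    li_learn <- li_learn[!is.nan(li_learn)]
    lat$li_learning <- percent_change_latency(
      to_percent_change(li_learn, li_learn[1], mean(tail(li_learn, 5))),
      n_required = cfg$n_required_learning)
    li_wash <- li_series[washout_start:nR]
    li_wash <- li_wash[!is.nan(li_wash)]
    if (length(li_wash) >= cfg$n_required_learning) {
      lat$li_washout <- percent_change_latency(
        to_percent_change(li_wash, li_wash[1], mean(tail(li_wash, 5))),
        n_required = cfg$n_required_learning)
    }
  }
  list(bootstrap = boot, latency = lat, washout_start = washout_start)
}

stage_changepoints <- function(study) {
  cps <- attr(study$schedule, "change_points")
  if (length(cps) == 0) return(NULL)
  records <- changepoint_table(study$trials, study$schedule)
  fits <- if (length(cps) >= 3) {
    list(dilation = changepoint_lme(records, "dilation"),
         baseline = changepoint_lme(records, "baseline"))
  } else {
    NULL
  }
  list(records = records, fits = fits)
}

stage_subgroup <- function(study) {
  split <- tryCatch(recall_split(study$reports), error = function(e) NULL)
  if (is.null(split)) return(NULL)
  fits <- purrr::map(
    c(baseline_pupil = "baseline_pupil", dilation_velocity = "dilation_velocity",
      pve = "pve", learning_index = "learning_index"),
    function(resp) {
      tryCatch(subgroup_block_lme(study$trials, split, resp),
               error = function(e) NULL)
    })
  list(split = split, fits = fits)
}

# Serialize the machine-readable outputs of a run.
write_study <- function(study, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$trials, file.path(out, "trials.csv"))
  readr::write_csv(schedule_to_csv(study$schedule),
                   file.path(out, "schedule.csv"))
  readr::write_csv(study$truth, file.path(out, "truth.csv"))
  readr::write_csv(study$reports, file.path(out, "reports.csv"))
  jsonlite::write_json(study_summary(study), file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out)
}

# Key statistics of every stage, JSON-serializable.
study_summary <- function(study) {
  cfg <- study$config
  an <- study$analyses
  s <- list(
    experiment_id = cfg$experiment_id, n_participants = cfg$n_participants,
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "params")]),
    n_trials = nrow(study$trials)
  )
  if (!is.null(an$timeseries_stats)) {
    ts <- an$timeseries_stats
    s$timeseries_stats <- list(
      latency_ms = as.list(attr(ts$running, "latency_ms")),
      min_cluster_p = if (nrow(ts$cluster$clusters)) {
        min(ts$cluster$clusters$p)
      } else {
        NA
      },
      n_significant_clusters = sum(ts$cluster$clusters$significant),
      baseline_p1 = ts$baseline_p1
    )
  }
  if (!is.null(an$adaptation)) {
    ad <- an$adaptation
    s$adaptation <- list(
      point = if (!is.null(ad$bootstrap)) {
        ad$bootstrap$point[c("A_f", "A_s", "B_f", "B_s")]
      },
      below_band_run = if (!is.null(ad$bootstrap)) ad$bootstrap$below_band_run,
      latency = purrr::map(ad$latency, function(l) as.list(setNames(
        l$latency, paste0("pct", l$threshold))))
    )
  }
  if (!is.null(an$setbreak)) {
    s$setbreak <- purrr::transpose(an$setbreak)
    names(s$setbreak) <- an$setbreak$measure
  }
  if (!is.null(an$changepoints) && !is.null(an$changepoints$fits)) {
    s$changepoints <- purrr::map(an$changepoints$fits, function(f) {
      list(fixed = purrr::transpose(f$fixed), lrt = f$lrt,
           singular_fallback = f$singular_fallback)
    })
  }
  if (!is.null(an$subgroup)) {
    s$subgroup <- list(
      group_sizes = as.list(table(an$subgroup$split$scores$group)),
      per_block_chisq = purrr::transpose(an$subgroup$split$per_block)
    )
  }
  s
}

#' Render a plain-text report from a written pipeline run
#'
#' Reads only the stored outputs of [run_pipeline()] (no recomputation) and
#' formats the key tables; stages missing from the run directory are marked
#' absent.
#'
#' @param run_dir Directory written by `run_pipeline(..., out = )`.
#' @param file Output path (default `report.txt` inside `run_dir`).
#' @param figures Also write summary figures as PDF files?
#' @return The path of the written report, invisibly.
#' @export
make_report <- function(run_dir, file = file.path(run_dir, "report.txt"),
                        figures = FALSE) {
  sm_path <- file.path(run_dir, "summary.json")
  if (!file.exists(sm_path)) stop("no summary.json in ", run_dir)
  sm <- jsonlite::read_json(sm_path)
  trials <- readr::read_csv(file.path(run_dir, "trials.csv"),
                            show_col_types = FALSE)
  lines <- c(
    sprintf("Pupil-adaptation pipeline report (%s, n = %s, seed = %s)",
            sm$experiment_id, sm$n_participants, sm$seed),
    sprintf("config hash: %s", sm$config_hash),
    "",
    sprintf("Trials: %d rows, %d participants", nrow(trials),
            length(unique(trials$participant))),
    ""
  )
  fmt_stage <- function(name, body) {
    if (is.null(sm[[name]])) {
      c(sprintf("[%s] absent from this run", name), "")
    } else {
      c(sprintf("[%s]", name), body, "")
    }
  }
  lines <- c(lines, fmt_stage("timeseries_stats", if (!is.null(sm$timeseries_stats)) c(
    sprintf("  first significant frame (HB): %s ms",
            format(sm$timeseries_stats$latency_ms$hb %||% NA)),
    sprintf("  first significant frame (BH): %s ms",
            format(sm$timeseries_stats$latency_ms$bh %||% NA)),
    sprintf("  min cluster p: %s | significant clusters: %s",
            format(sm$timeseries_stats$min_cluster_p),
            format(sm$timeseries_stats$n_significant_clusters)),
    sprintf("  baseline increase on trial p+1: t = %.3f, p = %.3g",
            sm$timeseries_stats$baseline_p1$statistic,
            sm$timeseries_stats$baseline_p1$p.value))))
  lines <- c(lines, fmt_stage("adaptation", if (!is.null(sm$adaptation)) c(
    sprintf("  two-state point fit: A_f=%.3f A_s=%.3f B_f=%.3f B_s=%.3f",
            sm$adaptation$point$A_f, sm$adaptation$point$A_s,
            sm$adaptation$point$B_f, sm$adaptation$point$B_s),
    sprintf("  consecutive washout trials below the 95%% band: %s",
            format(sm$adaptation$below_band_run)))))
  lines <- c(lines, fmt_stage("setbreak", if (!is.null(sm$setbreak)) {
    vapply(names(sm$setbreak), function(ms) {
      x <- sm$setbreak[[ms]]
      sprintf("  %s: delta = %.4g, t = %.3f, p = %.3g",
              ms, x$delta, x$statistic, x$p.value)
    }, "")
  }))
  lines <- c(lines, fmt_stage("subgroup", if (!is.null(sm$subgroup)) c(
    sprintf("  group sizes: low = %s, high = %s",
            format(sm$subgroup$group_sizes$low),
            format(sm$subgroup$group_sizes$high)))))
  writeLines(lines, file)
  if (figures) {
    pdf_path <- file.path(run_dir, "learning_curve.pdf")
    ggplot2::ggsave(pdf_path, plot_learning_curve(trials),
                    width = 7, height = 4)
  }
  invisible(file)
}
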