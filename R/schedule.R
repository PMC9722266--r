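#' Build a perturbation schedule for one of the study designs
#'
#' Constructs the full per-trial plan of an experiment: block structure,
#' environment viscosity `B` per reaching trial (clockwise positive),
#' channel-trial and light-reflex-trial placement, and the derived
#' change-point trials.  Six designs are built in:
#'
#' * `"exp1"`: five blocks of 59 trials (44 in block 4; the first and last
#'   two trials of each block measure the pupillary light reflex, leaving
#'   55/55/55/40/55 reaching trials).  A curl field of `B = 0.15` is switched
#'   on at the 11th reaching trial of block 2 and off at the 11th reaching
#'   trial of block 4.
#' * `"exp2A"`, `"exp2B"`, `"exp2C"`: five blocks of 50 reaching trials
#'   (plus two light-reflex trials before and after each block) with
#'   `B = 0.12` and the switching CW/CCW trial sets of those designs.
#' * `"exp3"`: seven blocks of 50 reaching trials; the field is introduced at
#'   the 16th trial of block 2 and grows by 5% of full strength
#'   (`B = 0.12`) every 11 trials until full strength, then is removed at the
#'   11th trial of block 7.  A final block of 10 alternating light-reflex
#'   trials follows.
#' * `"exp4"`: as `"exp3"` but block 7 has 70 trials with channel trials
#'   repeated from its 21st to 70th trial instead of force removal.
#'
#' Channel trials are interleaved in 20% of reaching trials: one randomly
#' placed channel per 5-trial cycle (seeded; a minimum gap between successive
#' channels is enforced), except where a design pins them (all of trials
#' 171--250 for `"exp2C"`, trials 321--370 for `"exp4"`).
#'
#' On channel trials `B` records the unchanged *environment* viscosity (the
#' channel physically replaces the field for that trial); use `is_channel`
#' to identify them.
#'
#' @param experiment_id One of `"exp1"`, `"exp2A"`, `"exp2B"`, `"exp2C"`,
#'   `"exp3"`, `"exp4"`, or `"custom"`.
#' @param direction `"CW"` or `"CCW"`; flips the sign of `B` for the designs
#'   whose field direction was counterbalanced across participants
#'   (exp1/3/4).  Ignored for exp2, whose CW/CCW sets are fixed.
#' @param channel_seed Integer seed for the random channel placement stream
#'   (kept separate from all noise streams).
#' @param min_gap Minimum number of non-channel trials between successive
#'   channel trials (default 1, i.e. no consecutive channels).
#' @param cp_min_jump Fraction of full field strength that a between-trial
#'   jump in `B` must exceed to count as a change point (default 0.5, so the
#'   5% gradual increments of exp3/4 are not change points).
#' @param custom For `experiment_id = "custom"`: a list with elements
#'   `blocks` (integer vector of reaching-trial counts per block), `B_full`,
#'   and either `cw`/`ccw` (reaching-trial index sets) or `field` (a function
#'   mapping reaching index to `B`). Optional: `amplitude_m`, `channel`,
#'   `fixed_channel_trials`, `eye_distance_mm`.
#'
#' @return A tibble of class `pupil_schedule` with one row per trial:
#'   `trial_index`, `reach_index` (`NA` on light-reflex trials), `block`,
#'   `B`, `is_channel`, `is_light_reflex`, `lr_stimulus`, `is_change_point`.
#'   Attributes: `experiment_id`, `B_full`, `amplitude_m`, `channel`
#'   (stiffness/damping), `eye_distance_mm`, `change_points` (reach indices),
#'   `blocks` (tibble of start/end reach indices).
#' @examples
#' sch <- make_schedule("exp1")
#' table(sch$block[!sch$is_light_reflex])
#' @export
make_schedule <- function(experiment_id = c("exp1", "exp2A", "exp2B", "exp2C",
                                            "exp3", "exp4", "custom"),
                          direction = c("CW", "CCW"),
                          channel_seed = 1L, min_gap = 1L,
                          cp_min_jump = 0.5, custom = NULL) {
  experiment_id <- match.arg(experiment_id)
  direction <- match.arg(direction)
  des <- schedule_design(experiment_id, custom)

  n_reach <- sum(des$blocks)
  block_of <- rep(seq_along(des$blocks), des$blocks)
  B <- des$field(seq_len(n_reach))
  if (des$flip_direction && direction == "CCW") B <- -B

  is_channel <- place_channels(n_reach, des$fixed_channel_trials,
                               channel_seed, min_gap)

  # change points: abrupt jumps of the environment strictly inside a block
  jump <- abs(diff(B))
  inside <- block_of[-1] == block_of[-n_reach]
  cp <- which(jump > cp_min_jump * des$B_full & inside) + 1L

  blocks_tbl <- tibble::tibble(
    block = seq_along(des$blocks),
    start = cumsum(c(1L, des$blocks[-length(des$blocks)])),
    end = cumsum(des$blocks)
  )

  rows <- purrr::map(seq_along(des$blocks), function(b) {
    idx <- which(block_of == b)
    reach <- tibble::tibble(
      reach_index = idx, block = b, B = B[idx],
      is_channel = is_channel[idx], is_light_reflex = FALSE,
      lr_stimulus = NA_character_
    )
    lr <- tibble::tibble(
      reach_index = NA_integer_, block = b, B = 0,
      is_channel = FALSE, is_light_reflex = TRUE,
      lr_stimulus = c("dark", "bright")
    )
    dplyr::bind_rows(lr, reach, lr)
  })
  sched <- dplyr::bind_rows(rows)
  if (des$final_lr_block > 0) {
    sched <- dplyr::bind_rows(sched, tibble::tibble(
      reach_index = NA_integer_, block = length(des$blocks) + 1L, B = 0,
      is_channel = FALSE, is_light_reflex = TRUE,
      lr_stimulus = rep(c("dark", "bright"), length.out = des$final_lr_block)
    ))
  }
  sched <- dplyr::mutate(sched,
    trial_index = dplyr::row_number(),
    is_change_point = !is.na(.data$reach_index) & .data$reach_index %in% cp,
    .before = 1
  )
  structure(sched,
    class = c("pupil_schedule", class(sched)),
    experiment_id = experiment_id, B_full = des$B_full,
    amplitude_m = des$amplitude_m, channel = des$channel,
    eye_distance_mm = des$eye_distance_mm,
    change_points = cp, blocks = blocks_tbl,
    flip_direction = des$flip_direction, direction = direction
  )
}

# Internal design table: block sizes, field profile and apparatus constants.
schedule_design <- function(experiment_id, custom) {
  on_off <- function(sets) {
    function(i) {
      B <- numeric(length(i))
      B[i %in% sets$cw] <- sets$B_full
      B[i %in% sets$ccw] <- -sets$B_full
      B
    }
  }
  gradual_field <- function(B_full, onset, last_on) {
    # 5% steps every 11 trials from `onset` until full strength, held until
    # `last_on`, zero afterwards
    function(i) {
      lev <- pmin(ceiling((i - onset + 1L) / 11), 20)
      B <- ifelse(i >= onset & i <= last_on, lev * 0.05 * B_full, 0)
      pmax(B, 0)
    }
  }
  exp24_channel <- list(stiffness = 2500, damping = 25)
  switch(experiment_id,
    exp1 = list(
      blocks = c(55L, 55L, 55L, 40L, 55L), B_full = 0.15,
      field = function(i) ifelse(i >= 66 & i <= 175, 0.15, 0),
      amplitude_m = 0.12, channel = list(stiffness = 7000, damping = 30),
      eye_distance_mm = 160, fixed_channel_trials = integer(0),
      final_lr_block = 0L, flip_direction = TRUE
    ),
    exp2A = list(
      blocks = rep(50L, 5), B_full = 0.12,
      field = on_off(list(
        cw = c(61:89, 101:129, 151:159, 170:179, 190:209, 220:229),
        ccw = c(90:100, 130:150, 160:169, 180:189, 210:219, 230:239),
        B_full = 0.12
      )),
      amplitude_m = 0.10, channel = exp24_channel, eye_distance_mm = 350,
      fixed_channel_trials = integer(0), final_lr_block = 0L,
      flip_direction = FALSE
    ),
    exp2B = list(
      blocks = rep(50L, 5), B_full = 0.12,
      field = on_off(list(
        cw = c(70:79, 90:109, 120:129, 140:189, 201:229),
        ccw = c(61:69, 80:89, 110:119, 130:139, 190:200, 230:239),
        B_full = 0.12
      )),
      amplitude_m = 0.10, channel = exp24_channel, eye_distance_mm = 350,
      fixed_channel_trials = integer(0), final_lr_block = 0L,
      flip_direction = FALSE
    ),
    exp2C = list(
      blocks = rep(50L, 5), B_full = 0.12,
      field = on_off(list(cw = 61:159, ccw = 160:170, B_full = 0.12)),
      amplitude_m = 0.10, channel = exp24_channel, eye_distance_mm = 350,
      fixed_channel_trials = 171:250, final_lr_block = 0L,
      flip_direction = FALSE
    ),
    exp3 = list(
      blocks = rep(50L, 7), B_full = 0.12,
      field = gradual_field(0.12, 66L, 310L),
      amplitude_m = 0.10, channel = exp24_channel, eye_distance_mm = 440,
      fixed_channel_trials = integer(0), final_lr_block = 10L,
      flip_direction = TRUE
    ),
    exp4 = list(
      blocks = c(rep(50L, 6), 70L), B_full = 0.12,
      field = gradual_field(0.12, 66L, 370L),
      amplitude_m = 0.10, channel = exp24_channel, eye_distance_mm = 440,
      fixed_channel_trials = 321:370, final_lr_block = 10L,
      flip_direction = TRUE
    ),
    custom = validate_custom_design(custom)
  )
}

validate_custom_design <- function(custom) {
  if (is.null(custom)) stop("custom design requires a `custom` list")
  stopifnot(is.numeric(custom$blocks), all(custom$blocks >= 1),
            is.numeric(custom$B_full), custom$B_full > 0)
  if (!is.null(custom$cw) && !is.null(custom$ccw) &&
      length(intersect(custom$cw, custom$ccw)) > 0) {
    stop("custom design has overlapping CW and CCW trial sets")
  }
  field <- custom$field
  if (is.null(field)) {
    cw <- custom$cw %||% integer(0)
    ccw <- custom$ccw %||% integer(0)
    Bf <- custom$B_full
    field <- function(i) {
      B <- numeric(length(i))
      B[i %in% cw] <- Bf
      B[i %in% ccw] <- -Bf
      B
    }
  }
  list(
    blocks = as.integer(custom$blocks), B_full = custom$B_full, field = field,
    amplitude_m = custom$amplitude_m %||% 0.10,
    channel = custom$channel %||% list(stiffness = 2500, damping = 25),
    eye_distance_mm = custom$eye_distance_mm %||% 440,
    fixed_channel_trials = as.integer(custom$fixed_channel_trials %||% integer(0)),
    final_lr_block = 0L, flip_direction = TRUE
  )
}

# One channel per complete 5-trial cycle outside the pinned range, placed
# uniformly at random with a minimum gap to the previous channel.
place_channels <- function(n_reach, fixed, channel_seed, min_gap) {
  is_channel <- logical(n_reach)
  is_channel[fixed] <- TRUE
  free_max <- if (length(fixed)) min(fixed) - 1L else n_reach
  n_cycles <- free_max %/% 5L
  if (n_cycles > 0) {
    old <- .Random.seed_safe()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(channel_seed %% 2147483647))
    last <- -Inf
    for (cyc in seq_len(n_cycles)) {
      pos <- (5L * (cyc - 1L) + 1L):(5L * cyc)
      ok <- pos[pos - last > min_gap]
      pick <- if (length(ok)) sample(rep(ok, 2L), 1L) else max(pos)
      is_channel[pick] <- TRUE
      last <- pick
    }
  }
  is_channel
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Reaching-trial view of a schedule
#'
#' Drops the light-reflex rows of a schedule, leaving one row per reaching
#' trial with its cumulative `reach_index`, block, environment viscosity and
#' channel/change-point flags.
#'
#' @param schedule A `pupil_schedule` from [make_schedule()].
#' @return A tibble with one row per reaching trial.
#' @export
reaching_trials <- function(schedule) {
  out <- dplyr::filter(tibble::as_tibble(schedule), !.data$is_light_reflex)
  dplyr::select(out, -"lr_stimulus")
}
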