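#' Group learning curve from a trial table
#'
#' Cycle-averaged lateral error (PVE) and, where present, channel learning
#' index, with the mean environment viscosity overlaid for reference.
#'
#' @param trial_table Tibble from [build_trial_table()].
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(trial_table) {
  byc <- dplyr::summarise(
    dplyr::group_by(trial_table, .data$cycle),
    pve = mean(.data$pve, na.rm = TRUE),
    learning_index = mean(.data$learning_index, na.rm = TRUE),
    B = mean(abs(.data$B)), .groups = "drop"
  )
  long <- tidyr::pivot_longer(byc, c("pve", "learning_index"),
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(.data$cycle, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$B), colour = "grey70",
                       linetype = 2) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "cycle (5-trial bin)", y = NULL,
                  title = "Group learning curve") +
    ggplot2::theme_minimal()
}

#' Trial-by-trial pupil measures
#'
#' Group means of baseline pupil diameter and dilation velocity per reaching
#' trial, with perturbation trials highlighted.
#'
#' @param trial_table Tibble from [build_trial_table()].
#' @return A ggplot object.
#' @export
plot_pupil_course <- function(trial_table) {
  byt <- dplyr::summarise(
    dplyr::group_by(trial_table, .data$reach_index),
    baseline_pupil = mean(.data$baseline_pupil, na.rm = TRUE),
    dilation_velocity = mean(.data$dilation_velocity, na.rm = TRUE),
    perturbed = any(.data$B != 0), .groups = "drop"
  )
  long <- tidyr::pivot_longer(byt, c("baseline_pupil", "dilation_velocity"),
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(.data$reach_index, .data$value,
                                     colour = .data$perturbed)) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "reaching trial", y = NULL, colour = "field on") +
    ggplot2::theme_minimal()
}

#' @describeIn cluster_mass_permutation Plot the frame-wise t trace with the
#'   cluster-forming threshold and significant clusters shaded.
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @export
autoplot.cluster_result <- function(object, ...) {
  d <- tibble::tibble(frame = object$frames, t = object$t)
  cl <- object$clusters
  gg <- ggplot2::ggplot(d, ggplot2::aes(.data$frame, .data$t)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$threshold,
                        linetype = 3, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "paired t",
                  title = "Cluster-mass permutation test") +
    ggplot2::theme_minimal()
  if (nrow(cl) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = dplyr::filter(cl, .data$significant),
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "firebrick"
    )
  }
  gg
}

#' @describeIn bootstrap_washout_prediction Plot the bootstrap washout band
#'   against the actual group-average learning index.
#' @param object A `two_state_fit`.
#' @param ... Unused.
#' @export
autoplot.two_state_fit <- function(object, ...) {
  b <- object$band
  ggplot2::ggplot(b, ggplot2::aes(.data$trial)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$actual,
                                     colour = .data$below), na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "washout channel trial",
                  y = "normalized learning index",
                  colour = "below 95% band",
                  title = "Predicted vs actual washout") +
    ggplot2::theme_minimal()
}

#' Set-break contrast plot
#'
#' Per-participant early-minus-late deltas per measure, with the group mean.
#'
#' @param contrast Result of [setbreak_contrast()].
#' @return A ggplot object.
#' @export
plot_setbreak <- function(contrast) {
  pp <- attr(contrast, "per_participant")
  ggplot2::ggplot(pp, ggplot2::aes(.data$measure, .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, na.rm = TRUE) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "firebrick",
                          size = 3, na.rm = TRUE) +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = NULL, y = "early - late",
                  title = "Measures after set breaks") +
    ggplot2::theme_minimal()
}
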