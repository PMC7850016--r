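#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_step geom_ribbon
#'   geom_hline labs theme_minimal facet_wrap scale_colour_manual autoplot
#'   geom_errorbar position_dodge
NULL

#' Plot a staircase run trace
#'
#' SNR by trial, with reversals highlighted and the SRT (when the run is
#' valid) as a horizontal reference.
#'
#' @param object A `staircase_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.staircase_run <- function(object, ...) {
  tr <- object$trials
  p <- ggplot(tr, aes(x = .data$trial, y = .data$snr_db)) +
    geom_step(colour = "grey40") +
    geom_point(aes(colour = .data$correct, shape = .data$is_reversal), size = 2.5) +
    scale_colour_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f02"),
                        name = "correct") +
    labs(x = "trial", y = "SNR (dB)", shape = "reversal",
         title = if (object$valid) {
           sprintf("SRT = %.1f dB (last %d reversals)",
                   object$srt_db, object$params$srt_reversals)
         } else "discarded run (too few reversals)") +
    theme_minimal()
  if (object$valid) p <- p + geom_hline(yintercept = object$srt_db,
                                        linetype = "dashed", colour = "grey30")
  p
}

#' Plot a glimpse profile
#'
#' Target and combined-masker VU-style RMS tracks on a dB scale, with
#' glimpsed frames shaded.
#'
#' @param object A `glimpse_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.glimpse_profile <- function(object, ...) {
  fr <- tidyr::pivot_longer(object$frames, c("target_rms", "masker_rms"),
                            names_to = "signal", values_to = "rms")
  fr$level_db <- 20 * log10(fr$rms)
  ggplot(fr, aes(x = .data$time, y = .data$level_db, colour = .data$signal)) +
    geom_line() +
    geom_point(data = dplyr::filter(
                 dplyr::mutate(object$frames,
                               level_db = 20 * log10(.data$target_rms)),
                 .data$glimpse),
               aes(x = .data$time, y = .data$level_db),
               inherit.aes = FALSE, colour = "#2c7fb8", size = 1.6) +
    scale_colour_manual(values = c(target_rms = "#d7301f", masker_rms = "grey30"),
                        labels = c(target_rms = "target", masker_rms = "maskers"),
                        name = NULL) +
    labs(x = "time (s)", y = "level (dB re full scale)",
         title = sprintf("glimpse proportion %.2f, mean glimpsing SNR %s",
                         object$glimpse_proportion,
                         if (is.na(object$mean_glimpse_snr_db)) "undefined"
                         else sprintf("%.1f dB", object$mean_glimpse_snr_db))) +
    theme_minimal()
}

#' Plot mean SRTs by masker-talker count
#'
#' The canonical summary figure: mean SRT (with standard-error bars) as a
#' function of the number of masker talkers, for time-forward and
#' time-reversed maskers.
#'
#' @param conditions An `srt_experiment` or its conditions tibble.
#' @return A ggplot object.
#' @export
plot_srt_by_talkers <- function(conditions) {
  g <- talker_group_means(conditions)
  g$maskers <- ifelse(g$reversed, "time-reversed", "time-forward")
  ggplot(g, aes(x = .data$n_talkers, y = .data$mean_srt_db,
                colour = .data$maskers, group = .data$maskers)) +
    geom_line() + geom_point(size = 2.5) +
    geom_errorbar(aes(ymin = .data$mean_srt_db - .data$se_srt_db,
                      ymax = .data$mean_srt_db + .data$se_srt_db),
                  width = 0.08, na.rm = TRUE) +
    labs(x = "number of masker talkers", y = "mean SRT (dB SNR)",
         colour = NULL) +
    theme_minimal()
}
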