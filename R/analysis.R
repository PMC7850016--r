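#' Masking release due to masker intelligibility
#'
#' Difference between the SRT with time-forward (intelligible) maskers and
#' the SRT with time-reversed (unintelligible) maskers for the same
#' condition. Positive values mean reversal (removing masker intelligibility)
#' helped.
#'
#' @param srt_forward_db,srt_reversed_db SRTs in dB (vectorised).
#' @return Forward minus reversed SRT, in dB.
#' @export
#' @examples
#' mr_intelligibility(-14.1, -21.4)  # 7.3 dB
mr_intelligibility <- function(srt_forward_db, srt_reversed_db) {
  srt_forward_db - srt_reversed_db
}

#' Masking release due to target-masker sex differences
#'
#' Difference between the SRT with same-sex maskers and the SRT with
#' different-sex maskers within one reversal state (pairs TS-TD, TSS-TDD,
#' TSS-TSD). Positive values mean the sex cue helped.
#'
#' @param srt_same_sex_db,srt_diff_sex_db SRTs in dB (vectorised).
#' @return Same-sex minus different-sex SRT, in dB.
#' @export
mr_sex_cue <- function(srt_same_sex_db, srt_diff_sex_db) {
  srt_same_sex_db - srt_diff_sex_db
}

#' Multi-masker penalty
#'
#' Worsening of the SRT when the number of maskers is doubled (pairs TDD-TD,
#' TSS-TS, TSSDD-TSD), within one reversal state. Positive = penalty.
#'
#' @param srt_more_db,srt_fewer_db SRTs in dB (vectorised).
#' @return More-maskers minus fewer-maskers SRT, in dB.
#' @export
multi_masker_penalty <- function(srt_more_db, srt_fewer_db) {
  srt_more_db - srt_fewer_db
}

#' Convert SNR to target-to-masker ratio (TMR)
#'
#' SNR is the target level relative to the summed maskers; TMR is relative
#' to each individual masker. Summing `n` equal-RMS mutually incoherent
#' maskers raises the combined power by a factor `n`, so
#' `TMR = SNR + 10 log10(n)` — +3.01 dB per doubling of the masker count.
#'
#' @param snr_db SNR in dB (vectorised).
#' @param n_maskers Number of equal-level maskers (>= 1).
#' @return TMR in dB.
#' @export
#' @examples
#' snr_to_tmr(0, 2)  # 3.0103 dB
snr_to_tmr <- function(snr_db, n_maskers) {
  if (any(n_maskers < 1)) abort("`n_maskers` must be >= 1.")
  snr_db + 10 * log10(n_maskers)
}

#' Per-condition SRT means across listeners
#'
#' @param conditions The conditions tibble of an `srt_experiment` (or any
#'   tibble with `listener_id`, `label`, `reversed`, `srt_db`).
#' @return A tibble with per-(label, reversed) mean SRT, SE (NA for a single
#'   listener) and listener count.
#' @export
condition_summary <- function(conditions) {
  conditions <- tidy_if_experiment(conditions)
  dplyr::summarise(
    dplyr::group_by(conditions, .data$label, .data$reversed),
    mean_srt_db = mean(.data$srt_db),
    se_srt_db = if (dplyr::n() > 1) sd(.data$srt_db) / sqrt(dplyr::n()) else NA_real_,
    n_listeners = dplyr::n(),
    .groups = "drop"
  )
}

#' Mean SRTs grouped by masker-talker count
#'
#' Groups the six conditions as 1-talker (mean of TS, TD), 2-talker (mean of
#' TDD, TSD, TSS) and 4-talker (TSSDD), per reversal state: first averaged
#' within listener, then across listeners.
#'
#' @inheritParams condition_summary
#' @return Tibble with `n_talkers`, `reversed`, `mean_srt_db`, `se_srt_db`.
#' @export
talker_group_means <- function(conditions) {
  conditions <- tidy_if_experiment(conditions)
  per_listener <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(conditions, n_talkers = n_maskers(.data$label)),
      .data$listener_id, .data$reversed, .data$n_talkers),
    srt_db = mean(.data$srt_db), .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per_listener, .data$n_talkers, .data$reversed),
    mean_srt_db = mean(.data$srt_db),
    se_srt_db = if (dplyr::n() > 1) sd(.data$srt_db) / sqrt(dplyr::n()) else NA_real_,
    .groups = "drop")
}

tidy_if_experiment <- function(x) {
  if (inherits(x, "srt_experiment")) x$conditions else x
}

#' All masking-release and multi-masker-penalty contrasts
#'
#' Computes, per listener and then averaged across listeners, the three
#' contrast families: masking release due to masker intelligibility
#' (forward - reversed, per condition label), masking release due to sex
#' cues (TS-TD, TSS-TDD, TSS-TSD, per reversal state), and the multi-masker
#' penalty (TDD-TD, TSS-TS, TSSDD-TSD, per reversal state) in both SNR and
#' TMR accounting. For every doubling contrast the TMR value exceeds the SNR
#' value by exactly 10 log10(2) dB.
#'
#' @inheritParams condition_summary
#' @return A tibble with `family`, `name`, `reversed` (NA for the
#'   intelligibility family, which spans both states), `value_db`,
#'   `se_db`, `n_listeners`.
#' @export
srt_contrasts <- function(conditions) {
  conditions <- tidy_if_experiment(conditions)
  wide <- tidyr::pivot_wider(
    dplyr::select(conditions, "listener_id", "label", "reversed", "srt_db"),
    names_from = c("label", "reversed"), values_from = "srt_db")
  col <- function(lab, rev) wide[[paste(lab, rev, sep = "_")]]

  per_listener <- dplyr::bind_rows(
    # MR due to masker intelligibility: forward - reversed, per label
    purrr::map_dfr(condition_labels(), function(lab) {
      tibble::tibble(listener_id = wide$listener_id,
                     family = "mr_intelligibility",
                     name = paste0("MR_intelligibility_", lab),
                     reversed = NA,
                     value_db = mr_intelligibility(col(lab, FALSE), col(lab, TRUE)))
    }),
    # MR due to sex cues: same-sex minus different-sex, per reversal state
    purrr::map_dfr(list(c("TS", "TD"), c("TSS", "TDD"), c("TSS", "TSD")),
                   function(pair) {
      purrr::map_dfr(c(FALSE, TRUE), function(rev) {
        tibble::tibble(listener_id = wide$listener_id,
                       family = "mr_sex_cue",
                       name = sprintf("MR_sex_%s_vs_%s", pair[1], pair[2]),
                       reversed = rev,
                       value_db = mr_sex_cue(col(pair[1], rev), col(pair[2], rev)))
      })
    }),
    # multi-masker penalty, SNR and TMR accounting
    purrr::map_dfr(list(c("TDD", "TD"), c("TSS", "TS"), c("TSSDD", "TSD")),
                   function(pair) {
      purrr::map_dfr(c(FALSE, TRUE), function(rev) {
        snr_pen <- multi_masker_penalty(col(pair[1], rev), col(pair[2], rev))
        tmr_pen <- multi_masker_penalty(
          snr_to_tmr(col(pair[1], rev), n_maskers(pair[1])),
          snr_to_tmr(col(pair[2], rev), n_maskers(pair[2])))
        dplyr::bind_rows(
          tibble::tibble(listener_id = wide$listener_id,
                         family = "multi_masker_penalty_snr",
                         name = sprintf("MMP_%s_vs_%s", pair[1], pair[2]),
                         reversed = rev, value_db = snr_pen),
          tibble::tibble(listener_id = wide$listener_id,
                         family = "multi_masker_penalty_tmr",
                         name = sprintf("MMP_TMR_%s_vs_%s", pair[1], pair[2]),
                         reversed = rev, value_db = tmr_pen))
      })
    })
  )
  out <- dplyr::summarise(
    dplyr::group_by(per_listener, .data$family, .data$name, .data$reversed),
    se_db = if (dplyr::n() > 1) sd(.data$value_db) / sqrt(dplyr::n()) else NA_real_,
    value_db = mean(.data$value_db),
    n_listeners = dplyr::n(),
    .groups = "drop"
  )
  dplyr::relocate(out, "value_db", .before = "se_db")
}
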