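#' Glimpsing analysis parameters
#'
#' @param window Integration window in seconds (default 0.300 s, the standard
#'   volume-unit meter integration time).
#' @param hop Hop between successive windows in seconds (default 0.020 s).
#' @return A list of class `glimpse_params`.
#' @export
glimpse_params <- function(window = 0.300, hop = 0.020) {
  assert_scalar_number(window, "window", positive = TRUE)
  assert_scalar_number(hop, "hop", positive = TRUE)
  if (hop > window) abort("`hop` must not exceed `window`.")
  structure(list(window = window, hop = hop), class = "glimpse_params")
}

#' Sliding long-term RMS envelope
#'
#' VU-meter-like loudness track: the RMS amplitude over a long integration
#' window, advanced in small hops. Only full, left-aligned windows are used
#' (frame i covers samples `[i*H, i*H + W)`, 0-based), giving
#' `floor((L - W)/H) + 1` frames for a signal of length L.
#'
#' @param x Numeric waveform.
#' @param sample_rate Sampling rate in Hz.
#' @param params A [glimpse_params()].
#' @return A tibble with `time` (window start, seconds) and `rms`.
#' @export
sliding_rms <- function(x, sample_rate, params = glimpse_params()) {
  W <- round(params$window * sample_rate)
  H <- round(params$hop * sample_rate)
  L <- length(x)
  if (L < W) abort("signal is shorter than one integration window.")
  n_frames <- (L - W) %/% H + 1L
  starts <- (seq_len(n_frames) - 1L) * H
  cs <- c(0, cumsum(x^2))
  energy <- cs[starts + W + 1L] - cs[starts + 1L]
  tibble::tibble(time = starts / sample_rate,
                 rms = sqrt(pmax(energy, 0) / W))
}

#' Glimpse profile of a target against the combined maskers
#'
#' Computes the sliding-RMS loudness tracks of the target and of the combined
#' masker separately, marks a frame as a glimpse when the target RMS strictly
#' exceeds the combined-masker RMS (ties are not glimpses), and summarizes
#' the glimpse proportion and the mean glimpsing SNR — the average, in dB,
#' of the framewise target/masker level ratio over glimpsed frames only.
#' When no frame is glimpsed the mean glimpsing SNR is undefined (`NA`).
#'
#' @param target Numeric waveform (or a `sentence_audio`).
#' @param masker_sum Numeric waveform of the summed maskers, same length.
#' @param sample_rate Sampling rate in Hz (taken from `target` if it is a
#'   `sentence_audio`).
#' @param params A [glimpse_params()].
#' @return A `glimpse_profile`: list with `frames` (tibble: time, target_rms,
#'   masker_rms, snr_db, glimpse), `glimpse_proportion`,
#'   `mean_glimpse_snr_db` (NA when no glimpses) and `params`.
#' @export
glimpse_profile <- function(target, masker_sum, sample_rate = NULL,
                            params = glimpse_params()) {
  if (inherits(target, "sentence_audio")) {
    sample_rate <- sample_rate %||% target$sample_rate
    target <- target$samples
  }
  if (is.null(sample_rate)) abort("`sample_rate` must be supplied.")
  if (length(target) != length(masker_sum)) {
    abort("target and masker_sum must have equal length.")
  }
  t_rms <- sliding_rms(target, sample_rate, params)
  m_rms <- sliding_rms(masker_sum, sample_rate, params)
  frames <- tibble::tibble(
    time = t_rms$time,
    target_rms = t_rms$rms,
    masker_rms = m_rms$rms,
    snr_db = 20 * log10(t_rms$rms / m_rms$rms),
    glimpse = t_rms$rms > m_rms$rms
  )
  structure(
    list(frames = frames,
         glimpse_proportion = mean(frames$glimpse),
         mean_glimpse_snr_db = if (any(frames$glimpse)) {
           mean(frames$snr_db[frames$glimpse])
         } else NA_real_,
         params = params),
    class = "glimpse_profile"
  )
}

#' @export
print.glimpse_profile <- function(x, ...) {
  cat(sprintf("<glimpse_profile> %d frames, glimpse proportion %.3f, mean glimpsing SNR %s\n",
              nrow(x$frames), x$glimpse_proportion,
              if (is.na(x$mean_glimpse_snr_db)) "undefined"
              else sprintf("%.2f dB", x$mean_glimpse_snr_db)))
  invisible(x)
}

#' Framewise glimpse data of a profile
#'
#' @param x A `glimpse_profile`.
#' @param ... Unused.
#' @return The framewise tibble (time, target_rms, masker_rms, snr_db, glimpse).
#' @exportS3Method generics::tidy
tidy.glimpse_profile <- function(x, ...) x$frames

#' One-row summary of a glimpse profile
#'
#' @param x A `glimpse_profile`.
#' @param ... Unused.
#' @return Tibble with `n_frames`, `glimpse_proportion`, `mean_glimpse_snr_db`.
#' @exportS3Method generics::glance
glance.glimpse_profile <- function(x, ...) {
  tibble::tibble(n_frames = nrow(x$frames),
                 glimpse_proportion = x$glimpse_proportion,
                 mean_glimpse_snr_db = x$mean_glimpse_snr_db)
}

#' Glimpse profile of an assembled trial
#'
#' Applies [glimpse_profile()] to a trial's scaled target and combined-masker
#' components (both carry the same overall level gain, which cancels in the
#' framewise ratio).
#'
#' @param trial A `trial_stimulus`.
#' @param params A [glimpse_params()].
#' @return A `glimpse_profile`.
#' @export
glimpse_trial <- function(trial, params = glimpse_params()) {
  stopifnot(inherits(trial, "trial_stimulus"))
  glimpse_profile(trial$target_scaled, trial$masker_scaled,
                  trial$sample_rate, params)
}

#' Mean glimpsing SNR for a masker condition
#'
#' Builds `n_trials` fresh trials of the condition at the stated SNR
#' (default 0 dB) and returns the per-trial mean glimpsing SNR and glimpse
#' proportion. Randomness (word draws, per-run talker picks) comes from the
#' current RNG stream.
#'
#' @param corpus An `ssc_corpus`.
#' @param label Condition label.
#' @param reversed Time-reverse the masker words?
#' @param snr_db Trial SNR in dB.
#' @param n_trials Number of seeded trials to average over.
#' @param params A [glimpse_params()].
#' @return A tibble with one row per trial: `label`, `reversed`, `trial`,
#'   `glimpse_proportion`, `mean_glimpse_snr_db`.
#' @export
condition_glimpse_snr <- function(corpus, label, reversed = FALSE,
                                  snr_db = 0, n_trials = 100,
                                  params = glimpse_params()) {
  purrr::map_dfr(seq_len(n_trials), function(i) {
    cond <- condition(label, corpus, reversed = reversed)
    gp <- glimpse_trial(make_trial(corpus, cond, snr_db = snr_db), params)
    tibble::tibble(label = label, reversed = reversed, trial = i,
                   glimpse_proportion = gp$glimpse_proportion,
                   mean_glimpse_snr_db = gp$mean_glimpse_snr_db)
  })
}
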