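#' Simulated listener profile
#'
#' A logistic psychometric model of single-keyword identification in the
#' closed-set matrix task: chance performance is `guess` (1/10 for the
#' 10-alternative response grid), rising to `1 - lapse` with midpoint
#' `threshold_db` and spread `slope_db`.
#'
#' @param threshold_db Midpoint of the per-keyword psychometric function
#'   (dB SNR).
#' @param slope_db Spread parameter of the logistic (dB); smaller is steeper.
#' @param guess Per-keyword chance rate (default 0.1).
#' @param lapse Per-keyword lapse rate (default 0).
#' @return A list of class `listener_profile`.
#' @export
listener_profile <- function(threshold_db, slope_db = 2, guess = 0.1, lapse = 0) {
  assert_scalar_number(threshold_db, "threshold_db")
  assert_scalar_number(slope_db, "slope_db", positive = TRUE)
  stopifnot(guess >= 0, guess < 1, lapse >= 0, lapse < 1, guess + lapse < 1)
  structure(list(threshold_db = threshold_db, slope_db = slope_db,
                 guess = guess, lapse = lapse),
            class = "listener_profile")
}

#' Probability of identifying one keyword
#'
#' `guess + (1 - guess - lapse) * logistic((snr - threshold)/slope)`;
#' strictly increasing in SNR.
#'
#' @param snr_db SNR in dB (vectorised).
#' @param profile A [listener_profile()].
#' @return Probability in `[guess, 1 - lapse]`.
#' @export
p_keyword <- function(snr_db, profile) {
  profile$guess + (1 - profile$guess - profile$lapse) *
    plogis((snr_db - profile$threshold_db) / profile$slope_db)
}

#' Probability of identifying both keywords
#'
#' The staircase tracks the both-keywords-correct event. Keyword responses
#' are modeled as independent, so this is `p_keyword(snr)^2` (floor
#' `guess^2` = 0.01 with the default 10-alternative guess rate).
#'
#' @inheritParams p_keyword
#' @return Probability.
#' @export
p_both <- function(snr_db, profile) p_keyword(snr_db, profile)^2

#' SNR at a stated both-keywords-correct probability
#'
#' Closed-form inversion of [p_both()]: the analytic speech recognition
#' threshold (SRT) when `p = 0.5`, i.e. the ground truth an adaptive
#' 1-up/1-down staircase on the both-correct event should recover.
#'
#' @param profile A [listener_profile()].
#' @param p Target probability; must lie strictly between `guess^2` and
#'   `(1 - lapse)^2`.
#' @return SNR in dB.
#' @export
snr_at_p_both <- function(profile, p = 0.5) {
  assert_scalar_number(p, "p")
  lo <- profile$guess^2
  hi <- (1 - profile$lapse)^2
  if (p <= lo || p >= hi) {
    abort(sprintf("p = %g is outside the attainable range (%g, %g).", p, lo, hi))
  }
  pk <- sqrt(p)
  profile$threshold_db + profile$slope_db *
    qlogis((pk - profile$guess) / (1 - profile$guess - profile$lapse))
}

#' Simulate one trial response
#'
#' Bernoulli draw of the both-keywords-correct event at the presented SNR,
#' from the current RNG stream.
#'
#' @inheritParams p_keyword
#' @return Logical: was the trial scored correct?
#' @export
respond <- function(snr_db, profile) {
  runif(1) < p_both(snr_db, profile)
}

#' Listener thresholds linked to a condition's glimpsing SNR
#'
#' Demonstration device tying the simulated listeners to the stimulus
#' acoustics: the per-keyword threshold for a condition is
#' `theta0 - gain * meanGlimpseSNR(condition at 0 dB)`, averaged over seeded
#' trials, so conditions with more glimpsing opportunity (e.g. time-reversed
#' maskers) yield better (lower) thresholds. Illustrative, not fitted to
#' human data.
#'
#' @param corpus An `ssc_corpus`.
#' @param label Condition label.
#' @param reversed Masker reversal flag.
#' @param theta0 Baseline threshold (dB SNR).
#' @param gain Coupling gain (dB threshold change per dB of glimpsing SNR).
#' @param n_trials Trials averaged for the glimpsing estimate.
#' @param slope_db,guess,lapse Passed to [listener_profile()].
#' @param params A [glimpse_params()].
#' @return A [listener_profile()].
#' @export
glimpse_linked_profile <- function(corpus, label, reversed = FALSE,
                                   theta0 = -8, gain = 1, n_trials = 30,
                                   slope_db = 2, guess = 0.1, lapse = 0,
                                   params = glimpse_params()) {
  g <- condition_glimpse_snr(corpus, label, reversed = reversed,
                             snr_db = 0, n_trials = n_trials, params = params)
  mg <- mean(g$mean_glimpse_snr_db, na.rm = TRUE)
  if (is.nan(mg)) mg <- 0
  listener_profile(theta0 - gain * mg, slope_db = slope_db,
                   guess = guess, lapse = lapse)
}
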