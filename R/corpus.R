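#' Default talker roster
#'
#' One male target talker and four masker talkers (two male, two female),
#' identified by their mean fundamental frequency (F0). F0 is the primary
#' acoustic correlate of talker sex exploited by the sex-cue masking
#' conditions: the target male sits at 106 Hz, the masker males at 97 and
#' 128 Hz, and the masker females at 157 and 190 Hz.
#'
#' @return A tibble with columns `talker_id`, `sex` (`"m"`/`"f"`),
#'   `f0_hz` and `role` (`"target"`/`"masker"`).
#' @export
#' @examples
#' default_talkers()
default_talkers <- function() {
  tibble::tibble(
    talker_id = c("tgt", "m97", "m128", "f157", "f190"),
    sex       = c("m", "m", "m", "f", "f"),
    f0_hz     = c(106, 97, 128, 157, 190),
    role      = c("target", "masker", "masker", "masker", "masker")
  )
}

#' Corpus synthesis settings
#'
#' Collects the tunable parameters of the parametric word synthesizer.
#'
#' @param sample_rate Sampling rate in Hz (default 22050; speech bandwidth
#'   suffices and files stay small).
#' @param duration_range Range (seconds) from which each word's base duration
#'   is drawn uniformly; the base duration is shared across talkers for the
#'   same word, with per-talker jitter applied on top.
#' @param rms Long-term RMS amplitude every token is normalized to
#'   (linear full scale). The default 0.05 leaves headroom for summing one
#'   target and up to four maskers without clipping.
#' @param n_words Words per category (default 10, a closed 10-alternative set).
#' @param cue_word_index Index (1-based) of the fixed Name cue word every
#'   target sentence starts with.
#' @param f0_jitter Per-word relative F0 jitter around the talker mean
#'   (default 0.03, so the talker mean F0 remains meaningful).
#' @param talker_duration_jitter Relative per-talker duration jitter around
#'   the shared base duration (default 0.10).
#' @param max_harmonics,max_harmonic_hz Harmonic count cap: the synthesizer
#'   uses the first `min(max_harmonics, floor(max_harmonic_hz / f0))`
#'   harmonics of F0.
#' @param attack_frac,decay_floor,ramp_frac Amplitude envelope shape in
#'   normalized word time: raised-cosine attack over the first `attack_frac`
#'   of the word, then exponential decay towards `decay_floor` of the peak,
#'   with a raised-cosine offset ramp over the final `ramp_frac`. The fast
#'   attack / slow decay asymmetry emulates stressed monosyllables and is
#'   what makes per-word time reversal acoustically meaningful.
#' @return A list of class `corpus_config`.
#' @export
corpus_config <- function(sample_rate = 22050,
                          duration_range = c(0.3, 0.5),
                          rms = 0.05,
                          n_words = 10,
                          cue_word_index = 1,
                          f0_jitter = 0.03,
                          talker_duration_jitter = 0.10,
                          max_harmonics = 20,
                          max_harmonic_hz = 5000,
                          attack_frac = 0.04,
                          decay_floor = 0.3,
                          ramp_frac = 0.025) {
  assert_scalar_number(sample_rate, "sample_rate", positive = TRUE)
  assert_scalar_number(rms, "rms", positive = TRUE)
  stopifnot(length(duration_range) == 2L, duration_range[1] > 0,
            duration_range[2] >= duration_range[1],
            cue_word_index >= 1, cue_word_index <= n_words)
  structure(
    list(sample_rate = sample_rate, duration_range = duration_range, rms = rms,
         n_words = as.integer(n_words), cue_word_index = as.integer(cue_word_index),
         f0_jitter = f0_jitter, talker_duration_jitter = talker_duration_jitter,
         max_harmonics = max_harmonics, max_harmonic_hz = max_harmonic_hz,
         attack_frac = attack_frac, decay_floor = decay_floor, ramp_frac = ramp_frac),
    class = "corpus_config"
  )
}

# Amplitude envelope in normalized word time u in [0, 1].
word_envelope <- function(n, attack_frac, decay_floor, ramp_frac) {
  u <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  env <- ifelse(u < attack_frac, 0.5 - 0.5 * cos(pi * u / attack_frac), 1)
  env <- env * ifelse(u <= attack_frac, 1,
                      decay_floor^((u - attack_frac) / (1 - attack_frac)))
  env * ifelse(u > 1 - ramp_frac, 0.5 - 0.5 * cos(pi * (1 - u) / ramp_frac), 1)
}

# Render a waveform from stored harmonic parameters. Pure function of its
# arguments, so a token can be resynthesized at any duration with pitch
# (f0, harmonic amplitudes, phases) unchanged.
render_token_samples <- function(params, n_samples, sample_rate, rms_target) {
  t <- (seq_len(n_samples) - 1) / sample_rate
  k <- seq_along(params$amps)
  x <- sin(outer(t, 2 * pi * params$f0_hz * k) +
             matrix(params$phases, n_samples, length(k), byrow = TRUE)) %*% params$amps
  x <- as.numeric(x) *
    word_envelope(n_samples, params$attack_frac, params$decay_floor, params$ramp_frac)
  x * (rms_target / rms(x))
}

# Word-specific spectral envelope: three seeded formant-like resonances plus
# gentle spectral tilt, evaluated at the harmonic frequencies.
draw_spectral_amps <- function(f0_hz, spectral_seed, max_harmonics, max_harmonic_hz) {
  n_harm <- max(1L, min(max_harmonics, floor(max_harmonic_hz / f0_hz)))
  withr::with_seed(spectral_seed, {
    centers <- c(runif(1, 300, 900), runif(1, 1000, 2200), runif(1, 2300, 3400))
    widths  <- runif(3, 80, 250)
    gains   <- c(1, runif(1, 0.4, 0.8), runif(1, 0.15, 0.45))
  })
  freqs <- f0_hz * seq_len(n_harm)
  env <- colSums(gains * exp(-outer(centers, freqs, function(c, f) (f - c)^2) /
                               (2 * widths^2)))
  tilt <- (freqs / freqs[1])^-0.5
  env * tilt + 0.02
}

#' Synthesize one matrix word token
#'
#' Renders a voiced harmonic complex: the first K harmonics of the talker's
#' (jittered) F0, shaped by a word-specific formant-like spectral envelope and
#' an asymmetric attack/decay amplitude envelope, then RMS-normalized. The
#' result is a pure function of the arguments, so regenerating with the same
#' seed yields a bit-identical waveform.
#'
#' @param talker A one-row data frame or list with at least `talker_id` and
#'   `f0_hz` (see [default_talkers()]).
#' @param category One of `"name"`, `"verb"`, `"number"`, `"color"`, `"object"`.
#' @param word_index Word slot within the category, 1..`n_words`.
#' @param duration Word duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer seed controlling F0 jitter and harmonic phases.
#' @param rms_target RMS amplitude the token is normalized to.
#' @param spectral_seed Seed for the word's spectral envelope. Defaults to a
#'   value derived from `seed`; [build_corpus()] shares it across talkers so
#'   the "same word" by different talkers is spectrally related.
#' @param config A [corpus_config()] supplying envelope and harmonic settings.
#' @return A `word_token`: list with `samples`, `sample_rate`, `talker_id`,
#'   `sex`, `category`, `word_index`, `duration`, `rms` and the generative
#'   `params` needed for pitch-preserving resynthesis.
#' @export
#' @examples
#' tok <- synthesize_word(default_talkers()[1, ], "number", 3,
#'                        duration = 0.4, seed = 7)
#' length(tok$samples)  # 0.4 s x 22050 Hz = 8820
synthesize_word <- function(talker, category, word_index, duration,
                            sample_rate = 22050, seed = 1,
                            rms_target = 0.05, spectral_seed = NULL,
                            config = corpus_config(sample_rate = sample_rate,
                                                   rms = rms_target)) {
  assert_scalar_number(duration, "duration", positive = TRUE)
  assert_scalar_number(sample_rate, "sample_rate", positive = TRUE)
  category <- match.arg(category, MATRIX_CATEGORIES)
  stopifnot(word_index >= 1)
  if (is.null(spectral_seed)) {
    spectral_seed <- derive_seed(seed, "spectrum", category, word_index)
  }
  f0_mean <- talker$f0_hz
  amps <- draw_spectral_amps(f0_mean, spectral_seed,
                             config$max_harmonics, config$max_harmonic_hz)
  withr::with_seed(seed, {
    f0 <- f0_mean * (1 + runif(1, -config$f0_jitter, config$f0_jitter))
    phases <- runif(length(amps), 0, 2 * pi)
  })
  params <- list(f0_hz = f0, amps = amps, phases = phases,
                 attack_frac = config$attack_frac,
                 decay_floor = config$decay_floor,
                 ramp_frac = config$ramp_frac)
  n <- round(duration * sample_rate)
  samples <- render_token_samples(params, n, sample_rate, rms_target)
  structure(
    list(samples = samples, sample_rate = sample_rate,
         talker_id = talker$talker_id, sex = talker$sex %||% NA_character_,
         category = category, word_index = as.integer(word_index),
         duration = n / sample_rate, rms = rms_target, params = params),
    class = "word_token"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resynthesize a word token at a new duration, preserving pitch
#'
#' Re-renders the token from its stored harmonic parameters (F0, amplitudes,
#' phases, envelope shape) at a new length, then re-normalizes to the token's
#' RMS constant. Because the pitch parameters are untouched, this is a
#' pitch-preserving uniform time-scaling by construction.
#'
#' @param token A `word_token`.
#' @param n_samples New length in samples.
#' @return A `word_token` of the requested length.
#' @export
resynthesize_token <- function(token, n_samples) {
  stopifnot(inherits(token, "word_token"), n_samples >= 2)
  out <- token
  out$samples <- render_token_samples(token$params, n_samples,
                                      token$sample_rate, token$rms)
  out$duration <- n_samples / token$sample_rate
  out
}

#' Build the full synthetic matrix corpus
#'
#' Generates the complete token set: 5 talkers x 5 categories x `n_words`
#' words, all normalized to one long-term RMS amplitude. Word base durations
#' are drawn uniformly from `config$duration_range` per (category, word) and
#' shared across talkers with seeded per-talker jitter, so word durations vary
#' slightly across categories and talkers. Every per-token seed is derived
#' deterministically from `seed`, so any token is reproducible in isolation
#' and two builds with the same seed are bit-identical.
#'
#' @param config A [corpus_config()].
#' @param seed Integer master seed.
#' @param talkers Talker roster, default [default_talkers()].
#' @return An `ssc_corpus`: list with `talkers` (tibble), `tokens` (nested
#'   list `tokens[[talker_id]][[category]][[word_index]]`), `cue_word_index`,
#'   `sample_rate`, `rms`, `config`, `seed`.
#' @export
#' @examples
#' corpus <- build_corpus(corpus_config(sample_rate = 8000), seed = 1)
#' corpus_token(corpus, "tgt", "number", 3)$rms
build_corpus <- function(config = corpus_config(), seed = 1,
                         talkers = default_talkers()) {
  stopifnot(sum(talkers$role == "target") == 1L)
  n_words <- config$n_words
  base_durations <- lapply(MATRIX_CATEGORIES, function(cat) {
    vapply(seq_len(n_words), function(w) {
      withr::with_seed(derive_seed(seed, "dur", cat, w),
                       runif(1, config$duration_range[1], config$duration_range[2]))
    }, numeric(1))
  })
  names(base_durations) <- MATRIX_CATEGORIES

  tokens <- lapply(seq_len(nrow(talkers)), function(i) {
    talker <- as.list(talkers[i, ])
    per_cat <- lapply(MATRIX_CATEGORIES, function(cat) {
      lapply(seq_len(n_words), function(w) {
        tok_seed <- derive_seed(seed, talker$talker_id, cat, w)
        jit <- withr::with_seed(derive_seed(seed, "tdur", talker$talker_id, cat, w),
                                runif(1, -1, 1)) * config$talker_duration_jitter
        synthesize_word(talker, cat, w,
                        duration = base_durations[[cat]][w] * (1 + jit),
                        sample_rate = config$sample_rate, seed = tok_seed,
                        rms_target = config$rms,
                        spectral_seed = derive_seed(seed, "spectrum", cat, w),
                        config = config)
      })
    })
    names(per_cat) <- MATRIX_CATEGORIES
    per_cat
  })
  names(tokens) <- talkers$talker_id

  structure(
    list(talkers = talkers, tokens = tokens,
         cue_word_index = config$cue_word_index,
         sample_rate = config$sample_rate, rms = config$rms,
         config = config, seed = seed),
    class = "ssc_corpus"
  )
}

#' Retrieve one token from a corpus
#'
#' @param corpus An `ssc_corpus`.
#' @param talker_id,category,word_index Token key.
#' @return The `word_token`.
#' @export
corpus_token <- function(corpus, talker_id, category, word_index) {
  tok <- corpus$tokens[[talker_id]][[category]][[word_index]]
  if (is.null(tok)) {
    abort(sprintf("corpus has no token (%s, %s, %d)", talker_id, category, word_index))
  }
  tok
}

#' @export
print.ssc_corpus <- function(x, ...) {
  cat(sprintf("<ssc_corpus> %d talkers x %d categories x %d words @ %g Hz, RMS %g\n",
              nrow(x$talkers), length(MATRIX_CATEGORIES), x$config$n_words,
              x$sample_rate, x$rms))
  invisible(x)
}

#' Tidy per-token summary of a corpus
#'
#' @param x An `ssc_corpus`.
#' @param ... Unused.
#' @return A tibble with one row per token: talker, category, word index,
#'   duration, measured RMS and realized F0.
#' @exportS3Method generics::tidy
tidy.ssc_corpus <- function(x, ...) {
  purrr::map_dfr(x$talkers$talker_id, function(tk) {
    purrr::map_dfr(MATRIX_CATEGORIES, function(cat) {
      purrr::map_dfr(seq_len(x$config$n_words), function(w) {
        tok <- x$tokens[[tk]][[cat]][[w]]
        tibble::tibble(talker_id = tk, category = cat, word_index = w,
                       duration = tok$duration, rms = rms(tok$samples),
                       f0_hz = tok$params$f0_hz)
      })
    })
  })
}
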