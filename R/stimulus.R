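#' Draw a target sentence specification
#'
#' The Name slot is always the corpus cue word (the listener's cue to the
#' target talker); the Verb, Number, Color and Object slots are drawn
#' uniformly from the 10 words of each category. Uses the current RNG stream.
#'
#' @param corpus An `ssc_corpus`.
#' @return A `sentence_spec`: list with `talker_id`, `word_indices` (named by
#'   category, in fixed category order) and `reversed = FALSE`.
#' @export
draw_target_spec <- function(corpus) {
  target_id <- corpus$talkers$talker_id[corpus$talkers$role == "target"]
  idx <- c(corpus$cue_word_index,
           sample.int(corpus$config$n_words, length(MATRIX_CATEGORIES) - 1L,
                      replace = TRUE))
  names(idx) <- MATRIX_CATEGORIES
  new_sentence_spec(target_id, idx, reversed = FALSE)
}

new_sentence_spec <- function(talker_id, word_indices, reversed) {
  stopifnot(length(word_indices) == length(MATRIX_CATEGORIES))
  structure(list(talker_id = talker_id,
                 word_indices = word_indices,
                 reversed = isTRUE(reversed)),
            class = "sentence_spec")
}

#' Draw masker sentence specifications with word exclusion
#'
#' For every category, each masker's word is drawn uniformly from the words
#' not already used by the target or by a previously drawn masker in that
#' trial (sequential sampling without replacement), so target and masker
#' sentences never share a word within a category.
#'
#' @param corpus An `ssc_corpus`.
#' @param target_spec The trial's target `sentence_spec`.
#' @param masker_talkers Character vector of masker talker ids, one per
#'   masker sentence (length 1, 2 or 4).
#' @param reversed Should the masker words be individually time-reversed?
#' @return A list of `sentence_spec`, one per masker.
#' @export
draw_masker_specs <- function(corpus, target_spec, masker_talkers,
                              reversed = FALSE) {
  n_m <- length(masker_talkers)
  stopifnot(n_m %in% c(1L, 2L, 4L), n_m + 1L <= corpus$config$n_words)
  used <- lapply(MATRIX_CATEGORIES, function(cat) target_spec$word_indices[[cat]])
  names(used) <- MATRIX_CATEGORIES
  specs <- vector("list", n_m)
  for (j in seq_len(n_m)) {
    idx <- vapply(MATRIX_CATEGORIES, function(cat) {
      pool <- setdiff(seq_len(corpus$config$n_words), used[[cat]])
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
    for (cat in MATRIX_CATEGORIES) used[[cat]] <- c(used[[cat]], idx[[cat]])
    specs[[j]] <- new_sentence_spec(masker_talkers[j], idx, reversed = reversed)
  }
  specs
}

#' Assemble a sentence waveform from a specification
#'
#' Concatenates the five word tokens in fixed category order. If
#' `spec$reversed`, each word's samples are reversed in time individually
#' before concatenation — the word order is not reversed — yielding an
#' unintelligible but spectrally matched masker. Word boundaries are recorded
#' as 0-based half-open sample offsets that tile the waveform contiguously.
#'
#' @param corpus An `ssc_corpus`.
#' @param spec A `sentence_spec`.
#' @return A `sentence_audio`: list with `samples`, `sample_rate`,
#'   `boundaries` (tibble: category, word_index, start, end), `spec`,
#'   `tokens` (the word tokens, for resynthesis) and `total_duration`.
#' @export
assemble_sentence <- function(corpus, spec) {
  tokens <- lapply(MATRIX_CATEGORIES, function(cat) {
    corpus_token(corpus, spec$talker_id, cat, spec$word_indices[[cat]])
  })
  sentence_from_tokens(tokens, spec, corpus$sample_rate)
}

sentence_from_tokens <- function(tokens, spec, sample_rate) {
  pieces <- lapply(tokens, function(tok) {
    if (spec$reversed) rev(tok$samples) else tok$samples
  })
  lens <- vapply(pieces, length, integer(1))
  ends <- cumsum(lens)
  structure(
    list(samples = unlist(pieces, use.names = FALSE),
         sample_rate = sample_rate,
         boundaries = tibble::tibble(
           category = MATRIX_CATEGORIES,
           word_index = vapply(tokens, function(t) t$word_index, integer(1)),
           start = ends - lens, end = ends),
         spec = spec, tokens = tokens,
         total_duration = sum(lens) / sample_rate),
    class = "sentence_audio"
  )
}

#' @export
print.sentence_audio <- function(x, ...) {
  cat(sprintf("<sentence_audio> %s%s, %.3f s @ %g Hz, words [%s]\n",
              x$spec$talker_id, if (x$spec$reversed) " (reversed)" else "",
              x$total_duration, x$sample_rate,
              paste(x$boundaries$word_index, collapse = " ")))
  invisible(x)
}

#' Match a masker sentence's duration to the target's, preserving pitch
#'
#' Uniformly time-scales the whole sentence (every word scaled by the same
#' global ratio) by resynthesizing each parametric token at its scaled length;
#' because the harmonic parameters are untouched, pitch is preserved by
#' construction. Reversal, if any, is re-applied after resynthesis, mirroring
#' the reverse-then-stretch generation order. Rounding is distributed across
#' words so the output length matches the requested duration to the sample.
#'
#' @param sentence A `sentence_audio` built from parametric tokens.
#' @param target_duration Desired duration in seconds, or use `n_samples`.
#' @param n_samples Desired length in samples (overrides `target_duration`).
#' @return A `sentence_audio` of exactly the requested length.
#' @export
match_duration <- function(sentence, target_duration = NULL, n_samples = NULL) {
  stopifnot(inherits(sentence, "sentence_audio"))
  fs <- sentence$sample_rate
  if (is.null(n_samples)) {
    assert_scalar_number(target_duration, "target_duration", positive = TRUE)
    n_samples <- round(target_duration * fs)
  }
  cur_lens <- vapply(sentence$tokens, function(t) length(t$samples), integer(1))
  if (n_samples == sum(cur_lens)) return(sentence)
  if (is.null(sentence$tokens[[1]]$params)) {
    abort("sentence was not built from parametric tokens; cannot time-scale.")
  }
  ratio <- n_samples / sum(cur_lens)
  new_lens <- floor(cur_lens * ratio)
  # distribute the rounding remainder over the words with largest fractional part
  rem <- n_samples - sum(new_lens)
  frac <- cur_lens * ratio - new_lens
  bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
  new_lens[bump] <- new_lens[bump] + 1L
  tokens <- Map(resynthesize_token, sentence$tokens, new_lens)
  sentence_from_tokens(tokens, sentence$spec, fs)
}

#' Mix a trial at a commanded SNR and overall level
#'
#' Sums the (duration-matched, equal-RMS) masker sentences sample-wise,
#' scales the summed masker so that the long-term target-to-combined-masker
#' RMS ratio equals `snr_db`, then scales the whole mixture to `level_rms`
#' (the software stand-in for a fixed presentation level).
#'
#' @param target A `sentence_audio` (forward target sentence).
#' @param maskers List of `sentence_audio`, all the same length as the target.
#' @param snr_db Commanded SNR in dB (target vs summed maskers, long-term RMS).
#' @param level_rms Overall mixture RMS after level normalization.
#' @return A `trial_stimulus`: list with `mixture`, `target_scaled`,
#'   `masker_scaled` (components after all scaling), `snr_db`, `level_rms`,
#'   `keywords` (target Number and Color indices), scale factors, and the
#'   input objects.
#' @export
mix_trial <- function(target, maskers, snr_db, level_rms = 0.05) {
  stopifnot(inherits(target, "sentence_audio"), length(maskers) >= 1)
  assert_scalar_number(snr_db, "snr_db")
  assert_scalar_number(level_rms, "level_rms", positive = TRUE)
  n <- length(target$samples)
  for (m in maskers) {
    if (length(m$samples) != n) {
      abort("all maskers must be duration-matched to the target (equal length).")
    }
  }
  masker_sum <- Reduce(`+`, lapply(maskers, `[[`, "samples"))
  if (all(masker_sum == 0)) abort("degenerate input: masker sum has zero energy.")
  g_masker <- rms(target$samples) / (rms(masker_sum) * 10^(snr_db / 20))
  mixture0 <- target$samples + g_masker * masker_sum
  g_level <- level_rms / rms(mixture0)
  structure(
    list(mixture = g_level * mixture0,
         target_scaled = g_level * target$samples,
         masker_scaled = g_level * g_masker * masker_sum,
         snr_db = snr_db, level_rms = level_rms,
         masker_gain = g_masker, level_gain = g_level,
         keywords = c(number = target$spec$word_indices[["number"]],
                      color  = target$spec$word_indices[["color"]]),
         target = target, maskers = maskers,
         sample_rate = target$sample_rate),
    class = "trial_stimulus"
  )
}

#' @export
print.trial_stimulus <- function(x, ...) {
  cat(sprintf("<trial_stimulus> %d masker(s), SNR %+.1f dB, level RMS %g\n",
              length(x$maskers), x$snr_db, x$level_rms))
  invisible(x)
}

#' Resolve a masker condition label to concrete masker talkers
#'
#' The six conditions code the masker count and sex composition relative to
#' the male target: `TD` one female, `TS` one male, `TDD` two females, `TSS`
#' two males, `TSD` one male + one female, `TSSDD` two males + two females.
#' Where a sex slot has two candidate talkers but the condition uses only
#' one (TS, TD, TSD), the talker is drawn uniformly (from the current RNG
#' stream) and should be held fixed within a test run.
#'
#' @param label Condition label.
#' @param corpus An `ssc_corpus` (for the talker roster).
#' @param reversed Are the masker words time-reversed?
#' @return A `masker_condition`: list with `label`, `reversed`,
#'   `masker_talkers` (character vector of talker ids).
#' @export
condition <- function(label, corpus, reversed = FALSE) {
  if (!label %in% names(CONDITION_SEXES)) {
    abort(sprintf("unknown condition label '%s'", label))
  }
  sexes <- CONDITION_SEXES[[label]]
  maskers <- corpus$talkers[corpus$talkers$role == "masker", ]
  pick <- function(sex, k) {
    pool <- maskers$talker_id[maskers$sex == sex]
    if (k == length(pool)) pool else pool[sample.int(length(pool), k)]
  }
  ids <- character(0)
  for (s in c("m", "f")) {
    k <- sum(sexes == s)
    if (k > 0) ids <- c(ids, pick(s, k))
  }
  structure(list(label = label, reversed = isTRUE(reversed),
                 masker_talkers = ids),
            class = "masker_condition")
}

#' Build one complete trial stimulus for a condition
#'
#' Draws a fresh target spec and exclusion-respecting masker specs, assembles
#' the sentences, duration-matches the maskers to the target, and mixes at
#' the commanded SNR. Randomness comes from the current RNG stream.
#'
#' @param corpus An `ssc_corpus`.
#' @param cond A `masker_condition` (see [condition()]).
#' @param snr_db Commanded SNR in dB.
#' @param level_rms Overall mixture RMS.
#' @return A `trial_stimulus`.
#' @export
make_trial <- function(corpus, cond, snr_db = 0, level_rms = 0.05) {
  tspec <- draw_target_spec(corpus)
  mspecs <- draw_masker_specs(corpus, tspec, cond$masker_talkers,
                              reversed = cond$reversed)
  target <- assemble_sentence(corpus, tspec)
  maskers <- lapply(mspecs, function(sp) {
    match_duration(assemble_sentence(corpus, sp),
                   n_samples = length(target$samples))
  })
  mix_trial(target, maskers, snr_db, level_rms)
}
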