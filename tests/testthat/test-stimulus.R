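test_that("target specs fix the cue word and draw the rest uniformly", {
  corpus <- small_corpus()
  set.seed(11)
  draws <- replicate(10000, draw_target_spec(corpus)$word_indices[["number"]])
  names_drawn <- replicate(200, draw_target_spec(corpus)$word_indices[["name"]])
  expect_true(all(names_drawn == corpus$cue_word_index))
  # binomial bound: each index expected 1000 times, SD = sqrt(10000 * .1 * .9)
  counts <- tabulate(draws, nbins = 10)
  expect_true(all(abs(counts - 1000) < 4 * sqrt(10000 * 0.1 * 0.9)))
  set.seed(5); a <- draw_target_spec(corpus)
  set.seed(5); b <- draw_target_spec(corpus)
  expect_identical(a, b)
})

test_that("masker word selection excludes target and other maskers per category", {
  corpus <- small_corpus()
  set.seed(21)
  for (i in 1:200) {
    tspec <- draw_target_spec(corpus)
    mspecs <- draw_masker_specs(corpus, tspec,
                                c("m97", "m128", "f157", "f190"))
    for (cat in c("name", "verb", "number", "color", "object")) {
      idx <- c(tspec$word_indices[[cat]],
               vapply(mspecs, function(m) m$word_indices[[cat]], integer(1)))
      expect_equal(anyDuplicated(idx), 0L)
    }
    # the exclusion applies to the Name category too
    expect_true(all(vapply(mspecs, function(m) m$word_indices[["name"]],
                           integer(1)) != corpus$cue_word_index))
  }
})

test_that("sentence assembly records tiling boundaries; reversal is an involution", {
  corpus <- small_corpus()
  set.seed(3)
  spec <- draw_target_spec(corpus)
  fwd <- assemble_sentence(corpus, spec)
  b <- fwd$boundaries
  expect_equal(b$start[1], 0)
  expect_equal(b$end[5], length(fwd$samples))
  expect_equal(b$start[-1], b$end[-5])          # contiguous half-open tiling
  expect_equal(fwd$total_duration,
               sum(vapply(fwd$tokens, function(t) t$duration, numeric(1))))

  rspec <- spec; rspec$reversed <- TRUE
  rev1 <- assemble_sentence(corpus, rspec)
  expect_equal(rms(rev1$samples), rms(fwd$samples))   # multiset preserved
  # reversing each word again restores the forward waveform bit-exactly
  again <- unlist(lapply(seq_len(5), function(i) {
    seg <- rev1$samples[(b$start[i] + 1):b$end[i]]
    rev(seg)
  }))
  expect_identical(again, fwd$samples)
})

test_that("duration matching is exact, identity at ratio one, pitch-preserving", {
  corpus <- small_corpus()
  set.seed(9)
  spec <- draw_target_spec(corpus)
  s <- assemble_sentence(corpus, spec)
  expect_identical(match_duration(s, n_samples = length(s$samples)), s)

  n_target <- round(2.0 * 8000)
  m <- match_duration(s, target_duration = 2.0)
  expect_length(m$samples, n_target)
  expect_equal(m$boundaries$end[5], n_target)
  for (i in c(1, 3, 5)) {
    f_before <- estimate_f0(s$tokens[[i]]$samples, 8000)
    f_after <- estimate_f0(m$tokens[[i]]$samples, 8000)
    expect_lt(abs(f_before - f_after) / f_before, 0.01)
  }
})

test_that("mixing hits the commanded SNR and overall level exactly", {
  corpus <- small_corpus()
  set.seed(31)
  for (n_m in c(1L, 2L, 4L)) {
    talkers <- c("m97", "m128", "f157", "f190")[seq_len(n_m)]
    tspec <- draw_target_spec(corpus)
    target <- assemble_sentence(corpus, tspec)
    maskers <- lapply(draw_masker_specs(corpus, tspec, talkers), function(sp) {
      match_duration(assemble_sentence(corpus, sp),
                     n_samples = length(target$samples))
    })
    for (snr in c(-30, -10, 0, 10)) {
      tr <- mix_trial(target, maskers, snr_db = snr, level_rms = 0.05)
      measured <- 20 * log10(rms(tr$target_scaled) / rms(tr$masker_scaled))
      expect_lt(abs(measured - snr), 0.01)
      expect_equal(rms(tr$mixture), 0.05, tolerance = 1e-4)
      # linearity: mixture is the scaled sum of its components
      resid <- tr$mixture - (tr$target_scaled + tr$masker_scaled)
      expect_lt(max(abs(resid)), 1e-10)
    }
    # each masker contributes equal long-term RMS before SNR scaling
    m_rms <- vapply(maskers, function(m) rms(m$samples), numeric(1))
    expect_lt(diff(range(m_rms)) / mean(m_rms), 1e-3)
  }
  expect_equal(10^(10 / 20), 3.1623, tolerance = 1e-4)
})

test_that("condition labels resolve to the right masker compositions", {
  corpus <- small_corpus()
  set.seed(2)
  sex_of <- function(ids) {
    corpus$talkers$sex[match(ids, corpus$talkers$talker_id)]
  }
  expect_equal(sort(sex_of(condition("TSSDD", corpus)$masker_talkers)),
               c("f", "f", "m", "m"))
  expect_equal(sex_of(condition("TD", corpus)$masker_talkers), "f")
  expect_setequal(condition("TSS", corpus)$masker_talkers, c("m97", "m128"))
  expect_equal(sort(sex_of(condition("TSD", corpus)$masker_talkers)),
               c("f", "m"))
  expect_error(condition("TX", corpus), "unknown condition")
  # the free same-sex slot varies across draws
  picks <- replicate(50, condition("TS", corpus)$masker_talkers)
  expect_setequal(unique(picks), c("m97", "m128"))
})
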