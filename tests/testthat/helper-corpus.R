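# Shared fixtures, built once per test session. A reduced sample rate keeps
# unit tests fast; the synthesis code path is identical at any rate.

.fixture_env <- new.env(parent = emptyenv())

small_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    .fixture_env$corpus <- build_corpus(corpus_config(sample_rate = 8000),
                                        seed = 1)
  }
  .fixture_env$corpus
}

default_corpus <- function() {
  if (is.null(.fixture_env$default_corpus)) {
    .fixture_env$default_corpus <- build_corpus(corpus_config(), seed = 1)
  }
  .fixture_env$default_corpus
}

# Frequency (Hz) of the largest magnitude-spectrum bin of a waveform.
dominant_freq <- function(x, sample_rate) {
  n <- length(x)
  spec <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  (which.max(spec) - 1) * sample_rate / n
}

# Harmonic-comb F0 estimate: the grid F0 whose first harmonics collect the
# most spectral magnitude. Independent of the synthesizer's stored parameters.
estimate_f0 <- function(x, sample_rate, f0_grid = seq(70, 250, by = 0.25)) {
  n <- length(x)
  spec <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  bin_hz <- sample_rate / n
  score <- vapply(f0_grid, function(f0) {
    k <- 1:floor(min(10, (length(spec) - 1) * bin_hz / f0))
    sum(spec[pmin(round(k * f0 / bin_hz) + 1, length(spec))]) / length(k)
  }, numeric(1))
  f0_grid[which.max(score)]
}

# Peak of the normalized cross-correlation between two waveforms.
max_norm_xcorr <- function(a, b) {
  cc <- stats::convolve(a, rev(b), type = "open")
  max(abs(cc)) / sqrt(sum(a^2) * sum(b^2))
}
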