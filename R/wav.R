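# Minimal RIFF WAVE codec: linear PCM 16-bit and IEEE float32, mono or
# multichannel, which covers everything the stimulus pipeline produces.

#' Write a waveform to a WAV file
#'
#' @param samples Numeric vector (mono) of dimensionless amplitudes in
#'   \[-1, 1\].
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz.
#' @param format `"float32"` (default; lossless round trip for this
#'   pipeline) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  if (format == "float32") {
    fmt_code <- 3L; bits <- 32L
    data_size <- n * 4L
  } else {
    fmt_code <- 1L; bits <- 16L
    data_size <- n * 2L
  }
  block_align <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # channels
  writeBin(as.integer(round(sample_rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(sample_rate) * block_align), con, size = 4,
           endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else {
    q <- as.integer(round(pmin(pmax(samples, -1), 32767 / 32768) * 32768))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Supports mono linear PCM 16-bit and IEEE float32 RIFF files (the formats
#' [write_wav()] produces and the corpus directory layout accepts).
#'
#' @param path Path to a WAV file.
#' @return List with `samples` (numeric) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    abort(sprintf("'%s' is not a RIFF/WAVE file.", path))
  }
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, raw(), n = size)
      fmt <- list(
        code = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        sample_rate = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) abort("malformed WAV: data chunk before fmt chunk.")
      if (fmt$code == 3 && fmt$bits == 32) {
        samples <- readBin(con, numeric(), n = size %/% 4, size = 4,
                           endian = "little")
      } else if (fmt$code == 1 && fmt$bits == 16) {
        samples <- readBin(con, integer(), n = size %/% 2, size = 2,
                           signed = TRUE, endian = "little") / 32768
      } else {
        abort(sprintf("unsupported WAV format (code %d, %d bits).",
                      fmt$code, fmt$bits))
      }
      break
    } else {
      seek(con, size + size %% 2, origin = "current")
    }
  }
  if (is.null(samples)) abort("malformed WAV: no data chunk found.")
  if (fmt$channels != 1) {
    samples <- colMeans(matrix(samples, nrow = fmt$channels))
  }
  list(samples = samples, sample_rate = fmt$sample_rate)
}

#' Export a corpus as a directory of WAV files plus a JSON manifest
#'
#' Layout: `<dir>/<talker>/<category>_<index>.wav` (float32) and
#' `<dir>/manifest.json` (talkers, F0s, cue word index, RMS constant,
#' sample rate). Real recordings following the same layout can be imported
#' with [import_corpus()].
#'
#' @param corpus An `ssc_corpus`.
#' @param dir Output directory (created if needed).
#' @param format WAV sample format, see [write_wav()].
#' @return `dir`, invisibly.
#' @export
export_corpus <- function(corpus, dir, format = "float32") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tk in corpus$talkers$talker_id) {
    tdir <- file.path(dir, tk)
    dir.create(tdir, showWarnings = FALSE)
    for (cat in MATRIX_CATEGORIES) {
      for (w in seq_len(corpus$config$n_words)) {
        tok <- corpus$tokens[[tk]][[cat]][[w]]
        write_wav(tok$samples, file.path(tdir, sprintf("%s_%02d.wav", cat, w)),
                  corpus$sample_rate, format = format)
      }
    }
  }
  manifest <- list(
    talkers = corpus$talkers,
    cue_word_index = corpus$cue_word_index,
    n_words = corpus$config$n_words,
    rms = corpus$rms,
    sample_rate = corpus$sample_rate
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Import a corpus from a WAV directory with a JSON manifest
#'
#' Reads the layout written by [export_corpus()]. Imported tokens carry no
#' generative parameters, so [match_duration()] is unavailable for them
#' unless an external time-scaler is used; everything else (assembly,
#' reversal, mixing, glimpsing) works unchanged.
#'
#' @param dir Corpus directory.
#' @return An `ssc_corpus`.
#' @export
import_corpus <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  talkers <- tibble::as_tibble(manifest$talkers)
  tokens <- lapply(talkers$talker_id, function(tk) {
    per_cat <- lapply(MATRIX_CATEGORIES, function(cat) {
      lapply(seq_len(manifest$n_words), function(w) {
        wav <- read_wav(file.path(dir, tk, sprintf("%s_%02d.wav", cat, w)))
        structure(
          list(samples = wav$samples, sample_rate = wav$sample_rate,
               talker_id = tk, sex = talkers$sex[talkers$talker_id == tk],
               category = cat, word_index = w,
               duration = length(wav$samples) / wav$sample_rate,
               rms = manifest$rms, params = NULL),
          class = "word_token")
      })
    })
    names(per_cat) <- MATRIX_CATEGORIES
    per_cat
  })
  names(tokens) <- talkers$talker_id
  cfg <- corpus_config(sample_rate = manifest$sample_rate, rms = manifest$rms,
                       n_words = manifest$n_words,
                       cue_word_index = manifest$cue_word_index)
  structure(list(talkers = talkers, tokens = tokens,
                 cue_word_index = manifest$cue_word_index,
                 sample_rate = manifest$sample_rate, rms = manifest$rms,
                 config = cfg, seed = NA_integer_),
            class = "ssc_corpus")
}
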