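#' @importFrom rlang abort .data
#' @importFrom stats qlogis plogis runif rnorm sd
#' @importFrom utils head tail
NULL

# Categories of the matrix test, in fixed sentence order.
MATRIX_CATEGORIES <- c("name", "verb", "number", "color", "object")

# Condition label -> masker sex composition ("m" = same sex as the male
# target, "f" = different sex).
CONDITION_SEXES <- list(
  TD    = "f",
  TS    = "m",
  TDD   = c("f", "f"),
  TSS   = c("m", "m"),
  TSD   = c("m", "f"),
  TSSDD = c("m", "m", "f", "f")
)

#' Condition labels for the six target-masker sex-cue conditions
#'
#' @return Character vector `c("TD","TS","TDD","TSS","TSD","TSSDD")`.
#' @export
condition_labels <- function() names(CONDITION_SEXES)

#' Number of masker talkers in a condition
#'
#' @param label Condition label (vectorised).
#' @return Integer vector of masker counts (1, 2 or 4).
#' @export
n_maskers <- function(label) {
  stopifnot(all(label %in% names(CONDITION_SEXES)))
  vapply(label, function(l) length(CONDITION_SEXES[[l]]), integer(1), USE.NAMES = FALSE)
}

#' Long-term root-mean-square amplitude
#'
#' @param x Numeric waveform.
#' @return RMS amplitude (linear, dimensionless).
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Derive a reproducible integer seed from a master seed and string labels
#'
#' Stable DJB2-style fold over the UTF-8 bytes of the labels, reduced modulo
#' 2^31 - 1 so the result is a valid `set.seed()` argument on any platform.
#'
#' @param master_seed Integer master seed.
#' @param ... Further labels (coerced to character) that identify the item.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(c(as.character(master_seed), vapply(list(...), as.character, character(1))),
               collapse = "\x1f")
  bytes <- utf8ToInt(key)
  h <- 5381
  m <- 2147483647
  for (b in bytes) h <- (h * 33 + b) %% m
  as.integer(h)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  invisible(x)
}
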