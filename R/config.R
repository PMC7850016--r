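# Experiment configuration: YAML in, validated list out, lossless round trip.

config_defaults <- function() {
  list(
    corpus = list(sample_rate = 22050, duration_range = c(0.3, 0.5),
                  rms = 0.05, n_words = 10, cue_word_index = 1),
    staircase = list(initial_snr_db = 10, step_initial_db = 4,
                     step_final_db = 2, reversals_to_reduce = 2,
                     max_trials = 20, reversals_required = 6,
                     srt_reversals = 6, snr_bounds_db = c(-60, 40)),
    listeners = list(n_listeners = 10, theta0 = -8, gain = 1,
                     between_sd = 1, slope_db = 2, guess = 0.1, lapse = 0,
                     glimpse_trials = 30),
    conditions = list(labels = condition_labels(), reversed = c(FALSE, TRUE)),
    n_runs = 2,
    max_attempts = 10,
    master_seed = 1
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    if (!key %in% names(defaults)) {
      abort(sprintf("unknown configuration key '%s'",
                    paste(c(path, key), collapse = ".")))
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        abort(sprintf("configuration key '%s' must be a mapping.",
                      paste(c(path, key), collapse = ".")))
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML file describing the corpus, staircase, listener, and
#' condition settings, fills defaults for every omitted key, and rejects
#' unknown keys by name. An empty or missing-section file yields the full
#' default configuration (the standard protocol: initial SNR +10 dB, 4/2 dB
#' steps, 20 trials, last six reversals).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list of class `experiment_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(config_defaults(), user)
  structure(cfg, class = "experiment_config")
}

#' Write an experiment configuration to YAML
#'
#' @param config An `experiment_config` (or plain list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a results table to CSV
#'
#' @param table A data frame (e.g. the `conditions` tibble of an
#'   `srt_experiment`, or a contrast table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_results <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run the full simulation pipeline from a configuration
#'
#' Builds the corpus, derives glimpse-linked listener profiles, simulates
#' the experiment and returns results plus summaries. Fully reproducible
#' from `config$master_seed`.
#'
#' @param config An `experiment_config` from [load_config()].
#' @return List with `corpus`, `listeners`, `experiment` (an
#'   `srt_experiment`), `summary` (per-condition means) and `contrasts`.
#' @export
run_pipeline <- function(config = load_config()) {
  cc <- config$corpus
  corpus <- build_corpus(
    corpus_config(sample_rate = cc$sample_rate,
                  duration_range = cc$duration_range, rms = cc$rms,
                  n_words = cc$n_words, cue_word_index = cc$cue_word_index),
    seed = config$master_seed)
  lc <- config$listeners
  listeners <- glimpse_linked_listeners(
    corpus, n_listeners = lc$n_listeners, labels = config$conditions$labels,
    theta0 = lc$theta0, gain = lc$gain, n_trials = lc$glimpse_trials,
    between_sd = lc$between_sd, slope_db = lc$slope_db, guess = lc$guess,
    lapse = lc$lapse, seed = config$master_seed)
  listeners <- listeners[listeners$reversed %in% config$conditions$reversed, ]
  sc <- config$staircase
  params <- staircase_params(sc$initial_snr_db, sc$step_initial_db,
                             sc$step_final_db, sc$reversals_to_reduce,
                             sc$max_trials, sc$reversals_required,
                             sc$srt_reversals, sc$snr_bounds_db)
  experiment <- simulate_experiment(corpus, listeners, params,
                                    n_runs = config$n_runs,
                                    max_attempts = config$max_attempts,
                                    seed = config$master_seed)
  list(corpus = corpus, listeners = listeners, experiment = experiment,
       summary = condition_summary(experiment),
       contrasts = srt_contrasts(experiment))
}
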