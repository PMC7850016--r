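#' Adaptive staircase parameters
#'
#' The 1-up/1-down adaptive procedure on the both-keywords-correct event:
#' start at +10 dB SNR, step 4 dB until two reversals have occurred, then
#' 2 dB; a run lasts exactly `max_trials` trials; the SRT is the mean of the
#' last `srt_reversals` reversal SNRs, and a run with fewer than
#' `reversals_required` reversals within `max_trials` trials is discarded.
#'
#' @param initial_snr_db Starting SNR (default +10 dB).
#' @param step_initial_db Initial step size (default 4 dB).
#' @param step_final_db Step size after `reversals_to_reduce` reversals
#'   (default 2 dB).
#' @param reversals_to_reduce Reversal count that triggers the step-size
#'   reduction (default 2).
#' @param max_trials Trials per run (default 20).
#' @param reversals_required Minimum reversal count for a valid run (default 6).
#' @param srt_reversals Number of late reversals averaged into the SRT
#'   (default 6).
#' @param snr_bounds_db Clamp on the commanded SNR (default `c(-60, 40)`);
#'   clamped trials are flagged but a clamped run is not auto-discarded.
#' @return A list of class `staircase_params`.
#' @export
staircase_params <- function(initial_snr_db = 10,
                             step_initial_db = 4,
                             step_final_db = 2,
                             reversals_to_reduce = 2,
                             max_trials = 20,
                             reversals_required = 6,
                             srt_reversals = 6,
                             snr_bounds_db = c(-60, 40)) {
  stopifnot(step_final_db <= step_initial_db, step_final_db > 0,
            srt_reversals <= reversals_required, max_trials >= 1,
            length(snr_bounds_db) == 2L,
            snr_bounds_db[1] <= initial_snr_db,
            initial_snr_db <= snr_bounds_db[2])
  structure(list(initial_snr_db = initial_snr_db,
                 step_initial_db = step_initial_db,
                 step_final_db = step_final_db,
                 reversals_to_reduce = reversals_to_reduce,
                 max_trials = as.integer(max_trials),
                 reversals_required = as.integer(reversals_required),
                 srt_reversals = as.integer(srt_reversals),
                 snr_bounds_db = snr_bounds_db),
            class = "staircase_params")
}

#' Run one adaptive staircase
#'
#' One-up/one-down on the tracked (both keywords correct) event: a correct
#' response lowers the next SNR by the current step, an incorrect response
#' raises it. A reversal is logged at the trial whose commanded direction
#' differs from the previous commanded direction; the reversal SNR is the
#' SNR presented at that trial. The step drops to the final size for every
#' step commanded after the second reversal. The run always lasts
#' `max_trials` trials; validity and SRT follow the last-six-reversals rule.
#'
#' @param responder Function `f(snr_db) -> logical` giving the trial outcome.
#' @param params A [staircase_params()].
#' @return A `staircase_run`: list with `trials` (tibble: trial, snr_db,
#'   correct, direction, is_reversal, step_after_db, clamped),
#'   `reversal_snrs_db`, `n_reversals`, `valid`, `srt_db` (NA when invalid)
#'   and `params`.
#' @export
run_staircase <- function(responder, params = staircase_params()) {
  n <- params$max_trials
  snr <- numeric(n); correct <- logical(n); direction <- integer(n)
  is_rev <- logical(n); step_after <- numeric(n); clamped <- logical(n)
  cur <- params$initial_snr_db
  n_reversals <- 0L
  for (i in seq_len(n)) {
    snr[i] <- cur
    correct[i] <- isTRUE(responder(cur))
    direction[i] <- if (correct[i]) -1L else 1L
    if (i > 1L && direction[i] != direction[i - 1L]) {
      is_rev[i] <- TRUE
      n_reversals <- n_reversals + 1L
    }
    step <- if (n_reversals >= params$reversals_to_reduce) {
      params$step_final_db
    } else {
      params$step_initial_db
    }
    step_after[i] <- step
    nxt <- cur + direction[i] * step
    nxt_cl <- min(max(nxt, params$snr_bounds_db[1]), params$snr_bounds_db[2])
    clamped[i] <- nxt_cl != nxt
    cur <- nxt_cl
  }
  reversal_snrs <- snr[is_rev]
  valid <- n_reversals >= params$reversals_required
  structure(
    list(trials = tibble::tibble(trial = seq_len(n), snr_db = snr,
                                 correct = correct, direction = direction,
                                 is_reversal = is_rev,
                                 step_after_db = step_after, clamped = clamped),
         reversal_snrs_db = reversal_snrs,
         n_reversals = n_reversals,
         valid = valid,
         srt_db = if (valid) mean(tail(reversal_snrs, params$srt_reversals))
                  else NA_real_,
         params = params),
    class = "staircase_run"
  )
}

#' @export
print.staircase_run <- function(x, ...) {
  cat(sprintf("<staircase_run> %d trials, %d reversals, %s\n",
              nrow(x$trials), x$n_reversals,
              if (x$valid) sprintf("SRT %.2f dB", x$srt_db) else "discarded"))
  invisible(x)
}

#' Trial-by-trial trace of a staircase run
#'
#' @param x A `staircase_run`.
#' @param ... Unused.
#' @return The per-trial tibble.
#' @exportS3Method generics::tidy
tidy.staircase_run <- function(x, ...) x$trials

#' One-row summary of a staircase run
#'
#' @param x A `staircase_run`.
#' @param ... Unused.
#' @return Tibble with `n_trials`, `n_reversals`, `valid`, `srt_db`.
#' @exportS3Method generics::glance
glance.staircase_run <- function(x, ...) {
  tibble::tibble(n_trials = nrow(x$trials), n_reversals = x$n_reversals,
                 valid = x$valid, srt_db = x$srt_db)
}

#' Measure an SRT from repeated staircase runs
#'
#' Repeats [run_staircase()] until `n_runs` valid runs are collected
#' (discarding invalid ones, as the procedure prescribes) or `max_attempts`
#' runs have been executed, then averages the per-run SRTs.
#'
#' @param responder_factory Function of no arguments returning a fresh
#'   responder `f(snr_db) -> logical` for each run (a fresh run of trials
#'   with fresh stimuli).
#' @param params A [staircase_params()].
#' @param n_runs Valid runs required (default 2, as in a 2-3 run protocol).
#' @param max_attempts Maximum total runs before giving up.
#' @return An `srt_condition`: list with `runs` (list of `staircase_run`),
#'   `run_srts_db`, `srt_db` (mean across valid runs), `n_discarded`.
#' @export
measure_srt <- function(responder_factory, params = staircase_params(),
                        n_runs = 2, max_attempts = 10) {
  stopifnot(n_runs >= 1)
  runs <- list(); srts <- numeric(0); discarded <- 0L; attempts <- 0L
  while (length(srts) < n_runs && attempts < max_attempts) {
    attempts <- attempts + 1L
    run <- run_staircase(responder_factory(), params)
    runs[[attempts]] <- run
    if (run$valid) srts <- c(srts, run$srt_db) else discarded <- discarded + 1L
  }
  if (length(srts) < n_runs) {
    abort(sprintf(
      "staircase failed to converge: %d valid run(s) in %d attempts (need %d).",
      length(srts), attempts, n_runs))
  }
  structure(list(runs = runs, run_srts_db = srts, srt_db = mean(srts),
                 n_discarded = discarded),
            class = "srt_condition")
}

#' @export
print.srt_condition <- function(x, ...) {
  cat(sprintf("<srt_condition> SRT %.2f dB over %d run(s), %d discarded\n",
              x$srt_db, length(x$run_srts_db), x$n_discarded))
  invisible(x)
}

#' Simulate a full speech-on-speech masking experiment
#'
#' For every listener and every condition (6 sex-cue labels x forward /
#' time-reversed maskers, randomized in order per listener), measures an SRT
#' with the adaptive staircase. Each trial draws a fresh target sentence and
#' fresh exclusion-respecting masker sentences; for conditions with a free
#' same-sex talker slot the masker talker is drawn once per run. Responses
#' come from each listener's psychometric profile for that condition.
#'
#' @param corpus An `ssc_corpus`.
#' @param listeners A tibble with one row per listener x condition x reversal
#'   state: columns `listener_id`, `label`, `reversed`, `threshold_db`, and
#'   optionally `slope_db`, `guess`, `lapse` (see [glimpse_linked_listeners()]).
#' @param params A [staircase_params()].
#' @param n_runs Valid runs per condition (default 2).
#' @param max_attempts Maximum runs attempted per condition.
#' @param seed Master seed; the whole experiment is reproducible from it.
#' @return An `srt_experiment`: list of tibbles `trials`, `runs`,
#'   `conditions` (one SRT per listener x condition x reversal state).
#' @export
simulate_experiment <- function(corpus, listeners, params = staircase_params(),
                                n_runs = 2, max_attempts = 10, seed = 1) {
  need <- c("listener_id", "label", "reversed", "threshold_db")
  if (!all(need %in% names(listeners))) {
    abort(sprintf("`listeners` must have columns: %s", paste(need, collapse = ", ")))
  }
  listeners <- dplyr::mutate(
    listeners,
    slope_db = if ("slope_db" %in% names(listeners)) .data$slope_db else 2,
    guess    = if ("guess" %in% names(listeners)) .data$guess else 0.1,
    lapse    = if ("lapse" %in% names(listeners)) .data$lapse else 0
  )
  trials_out <- list(); runs_out <- list(); cond_out <- list()
  for (lid in unique(listeners$listener_id)) {
    rows <- listeners[listeners$listener_id == lid, ]
    order_seed <- derive_seed(seed, "order", lid)
    rows <- rows[withr::with_seed(order_seed, sample.int(nrow(rows))), ]
    for (r in seq_len(nrow(rows))) {
      row <- rows[r, ]
      profile <- listener_profile(row$threshold_db, row$slope_db,
                                  row$guess, row$lapse)
      cond_seed <- derive_seed(seed, "cond", lid, row$label, row$reversed)
      res <- withr::with_seed(cond_seed, {
        factory <- function() {
          cond <- condition(row$label, corpus, reversed = row$reversed)
          function(snr_db) {
            tspec <- draw_target_spec(corpus)
            draw_masker_specs(corpus, tspec, cond$masker_talkers,
                              reversed = row$reversed)
            respond(snr_db, profile)
          }
        }
        measure_srt(factory, params, n_runs = n_runs,
                    max_attempts = max_attempts)
      })
      key <- tibble::tibble(listener_id = lid, label = row$label,
                            reversed = row$reversed)
      cond_out[[length(cond_out) + 1L]] <- dplyr::mutate(
        key, srt_db = res$srt_db, n_runs = length(res$run_srts_db),
        n_discarded = res$n_discarded, threshold_db = row$threshold_db)
      for (k in seq_along(res$runs)) {
        rn <- res$runs[[k]]
        runs_out[[length(runs_out) + 1L]] <- dplyr::mutate(
          key, run = k, valid = rn$valid,
          n_reversals = rn$n_reversals, srt_db = rn$srt_db)
        trials_out[[length(trials_out) + 1L]] <- dplyr::bind_cols(
          key[rep(1, nrow(rn$trials)), ],
          dplyr::mutate(rn$trials, run = k, .before = 1))
      }
    }
  }
  structure(list(trials = dplyr::bind_rows(trials_out),
                 runs = dplyr::bind_rows(runs_out),
                 conditions = dplyr::bind_rows(cond_out)),
            class = "srt_experiment")
}

#' @export
print.srt_experiment <- function(x, ...) {
  cat(sprintf("<srt_experiment> %d listener(s), %d condition SRTs, %d runs, %d trials\n",
              length(unique(x$conditions$listener_id)), nrow(x$conditions),
              nrow(x$runs), nrow(x$trials)))
  invisible(x)
}

#' Per-condition SRT table of a simulated experiment
#'
#' @param x An `srt_experiment`.
#' @param ... Unused.
#' @return The conditions tibble (one SRT per listener x condition x
#'   reversal state).
#' @exportS3Method generics::tidy
tidy.srt_experiment <- function(x, ...) x$conditions

#' One-row summary of a simulated experiment
#'
#' @param x An `srt_experiment`.
#' @param ... Unused.
#' @return Tibble with listener, condition, run and trial counts.
#' @exportS3Method generics::glance
glance.srt_experiment <- function(x, ...) {
  tibble::tibble(n_listeners = length(unique(x$conditions$listener_id)),
                 n_conditions = nrow(x$conditions),
                 n_runs = nrow(x$runs), n_trials = nrow(x$trials),
                 n_discarded = sum(x$conditions$n_discarded))
}

#' Build glimpse-linked listener profiles for an experiment
#'
#' Convenience wrapper producing the `listeners` tibble for
#' [simulate_experiment()]: condition thresholds follow
#' [glimpse_linked_profile()] (shared across listeners), plus seeded
#' between-listener jitter.
#'
#' @param corpus An `ssc_corpus`.
#' @param n_listeners Number of simulated listeners.
#' @param labels Condition labels (default all six).
#' @param theta0,gain,n_trials Passed to [glimpse_linked_profile()].
#' @param between_sd SD (dB) of Gaussian between-listener threshold jitter.
#' @param slope_db,guess,lapse Psychometric settings shared by all listeners.
#' @param seed Seed for the glimpsing estimates and the jitter.
#' @return A tibble suitable for `simulate_experiment(listeners = ...)`.
#' @export
glimpse_linked_listeners <- function(corpus, n_listeners = 10,
                                     labels = condition_labels(),
                                     theta0 = -8, gain = 1, n_trials = 30,
                                     between_sd = 1, slope_db = 2,
                                     guess = 0.1, lapse = 0, seed = 1) {
  base <- purrr::map_dfr(labels, function(lab) {
    purrr::map_dfr(c(FALSE, TRUE), function(rev) {
      prof <- withr::with_seed(
        derive_seed(seed, "glimpse", lab, rev),
        glimpse_linked_profile(corpus, lab, reversed = rev, theta0 = theta0,
                               gain = gain, n_trials = n_trials,
                               slope_db = slope_db, guess = guess,
                               lapse = lapse))
      tibble::tibble(label = lab, reversed = rev,
                     base_threshold_db = prof$threshold_db)
    })
  })
  purrr::map_dfr(seq_len(n_listeners), function(i) {
    jit <- withr::with_seed(derive_seed(seed, "listener", i),
                            rnorm(1, 0, between_sd))
    dplyr::mutate(base, listener_id = sprintf("L%02d", i),
                  threshold_db = .data$base_threshold_db + jit,
                  slope_db = slope_db, guess = guess, lapse = lapse,
                  .keep = "unused")
  })
}
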