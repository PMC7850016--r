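# Independent hand-coded staircase simulator, kept deliberately different in
# structure from the implementation: recomputes the trace via explicit state.
oracle_staircase <- function(correct_at, params = staircase_params()) {
  snrs <- c(); revs <- c(); dir_prev <- NULL; n_rev <- 0
  cur <- params$initial_snr_db
  for (i in seq_len(params$max_trials)) {
    snrs <- c(snrs, cur)
    dir_now <- if (correct_at(cur)) -1 else +1
    if (!is.null(dir_prev) && dir_now != dir_prev) {
      n_rev <- n_rev + 1
      revs <- c(revs, cur)
    }
    dir_prev <- dir_now
    step <- if (n_rev >= params$reversals_to_reduce) params$step_final_db
            else params$step_initial_db
    cur <- min(max(cur + dir_now * step, params$snr_bounds_db[1]),
               params$snr_bounds_db[2])
  }
  list(snrs = snrs, revs = revs, valid = n_rev >= params$reversals_required,
       srt = if (n_rev >= params$reversals_required) {
         mean(tail(revs, params$srt_reversals))
       } else NA_real_)
}

test_that("the deterministic threshold-at-zero responder reproduces the hand trace", {
  run <- run_staircase(function(s) s >= 0)
  expect_equal(run$trials$snr_db,
               c(10, 6, 2, -2, 2, 0, -2, 0, -2, 0, -2, 0, -2, 0, -2, 0, -2, 0, -2, 0))
  expect_equal(head(run$reversal_snrs_db, 4), c(-2, 2, -2, 0))
  expect_equal(tail(run$reversal_snrs_db, 6), c(-2, 0, -2, 0, -2, 0))
  expect_true(run$valid)
  expect_equal(run$srt_db, -1.0)
})

test_that("run_staircase agrees with the independent oracle on threshold responders", {
  for (theta in c(-13, -6, -1, 3, 8)) {
    responder <- local({
      th <- theta
      function(s) s >= th
    })
    run <- run_staircase(responder)
    orc <- oracle_staircase(responder)
    expect_equal(run$trials$snr_db, orc$snrs)
    expect_equal(run$reversal_snrs_db, orc$revs)
    expect_equal(run$valid, orc$valid)
    expect_equal(run$srt_db, orc$srt)
  }
  # stochastic responders replayed from a recorded outcome sequence
  set.seed(42)
  for (i in 1:20) {
    outcomes <- runif(20) < 0.5
    mk <- function() {
      k <- 0
      function(s) { k <<- k + 1; outcomes[k] }
    }
    run <- run_staircase(mk())
    orc <- oracle_staircase(mk())
    expect_equal(run$trials$snr_db, orc$snrs)
    expect_equal(run$reversal_snrs_db, orc$revs)
    expect_equal(run$valid, orc$valid)
    expect_equal(run$n_reversals, sum(run$trials$is_reversal))
  }
})

test_that("degenerate responders yield monotone invalid runs, not errors", {
  up <- run_staircase(function(s) TRUE)
  expect_equal(up$n_reversals, 0L)
  expect_false(up$valid)
  expect_true(is.na(up$srt_db))
  expect_true(all(diff(up$trials$snr_db) <= 0))   # monotone down to the clamp
  down <- run_staircase(function(s) FALSE)
  expect_equal(down$n_reversals, 0L)
  expect_false(down$valid)
})

test_that("SNR clamping at the bounds is applied and flagged", {
  params <- staircase_params(snr_bounds_db = c(-4, 12))
  run <- run_staircase(function(s) TRUE, params)
  expect_true(all(run$trials$snr_db >= -4))
  expect_true(any(run$trials$clamped))
  expect_false(run$valid)    # clamped runs are reported, not auto-discarded
})

test_that("measure_srt collects valid runs, discards invalid ones, or errors", {
  res <- measure_srt(function() function(s) s >= 0, n_runs = 2)
  expect_equal(res$run_srts_db, c(-1, -1))
  expect_equal(res$srt_db, -1)
  expect_equal(res$n_discarded, 0L)
  expect_error(
    measure_srt(function() function(s) TRUE, n_runs = 2, max_attempts = 4),
    "failed to converge")
  # stochastic listener: per-run SRTs retained, mean reported
  prof <- listener_profile(-8, 2, guess = 0.1)
  set.seed(7)
  res2 <- measure_srt(function() function(s) respond(s, prof), n_runs = 3)
  expect_length(res2$run_srts_db, 3)
  expect_equal(res2$srt_db, mean(res2$run_srts_db))
})

test_that("staircase runs are reproducible under a fixed seed", {
  prof <- listener_profile(-5, 1.5, guess = 0.1)
  set.seed(123); a <- run_staircase(function(s) respond(s, prof))
  set.seed(123); b <- run_staircase(function(s) respond(s, prof))
  expect_identical(a$trials, b$trials)
})

test_that("simulate_experiment covers the design, randomizes order, reproduces", {
  corpus <- small_corpus()
  listeners <- tibble::tibble(
    listener_id = rep(c("L01", "L02"), each = 12),
    label = rep(rep(condition_labels(), each = 2), 2),
    reversed = rep(c(FALSE, TRUE), 12),
    threshold_db = -8
  )
  exp1 <- simulate_experiment(corpus, listeners, seed = 5)
  expect_equal(nrow(exp1$conditions), 24L)     # 2 listeners x 6 labels x 2 states
  expect_equal(nrow(dplyr::distinct(exp1$conditions, label, reversed)), 12L)
  expect_true(all(table(exp1$conditions$listener_id) == 12L))
  # per-listener condition order differs under one master seed
  ord <- function(lid) {
    d <- exp1$trials[exp1$trials$listener_id == lid, ]
    unique(paste(d$label, d$reversed))
  }
  expect_false(identical(ord("L01"), ord("L02")))
  exp2 <- simulate_experiment(corpus, listeners, seed = 5)
  expect_identical(exp1$conditions, exp2$conditions)
  expect_identical(exp1$trials, exp2$trials)
  # valid runs only contribute SRTs; bookkeeping is consistent
  expect_true(all(exp1$runs$n_reversals[exp1$runs$valid] >= 6))
  expect_equal(nrow(exp1$trials), nrow(exp1$runs) * 20L)
})

test_that("the staircase recovers the analytic both-keyword 50% point", {
  # 1-up/1-down tracks the 50% point of the tracked (both-correct) function,
  # not the per-keyword function
  prof <- listener_profile(-10, 2, guess = 0.1)
  truth_both <- snr_at_p_both(prof, 0.5)
  theta_keyword <- prof$threshold_db
  srts <- vapply(1:150, function(i) {
    set.seed(derive_seed(31, i))
    run <- run_staircase(function(s) respond(s, prof))
    if (run$valid) run$srt_db else NA_real_
  }, numeric(1))
  m <- mean(srts, na.rm = TRUE)
  expect_lt(abs(m - truth_both), 0.5)
  expect_gt(abs(m - theta_keyword), 0.5)
})
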