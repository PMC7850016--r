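test_that("contrast arithmetic reproduces the published values from their operands", {
  # masking release due to masker intelligibility (forward - reversed)
  expect_equal(mr_intelligibility(-14.1, -21.4), 7.3)
  expect_equal(mr_intelligibility(-3.5, -9.0), 5.5)
  expect_equal(mr_intelligibility(-5, -5), 0)
  # sex-cue masking release (same-sex - different-sex)
  expect_equal(mr_sex_cue(0, 0), 0)
  # multi-masker penalty is antisymmetric under operand swap
  expect_equal(multi_masker_penalty(-2, -9), -multi_masker_penalty(-9, -2))
  expect_equal(mr_sex_cue(-2, -9), -mr_sex_cue(-9, -2))
  expect_equal(mr_intelligibility(-2, -9), -mr_intelligibility(-9, -2))
})

test_that("SNR to TMR conversion adds 10 log10(n) for equal-level maskers", {
  expect_equal(snr_to_tmr(-7.2, 1), -7.2)              # single masker: TMR == SNR
  expect_equal(snr_to_tmr(0, 2), 3.0103, tolerance = 1e-4)
  expect_equal(snr_to_tmr(-10, 4), -3.979, tolerance = 1e-3)
  expect_error(snr_to_tmr(0, 0), "n_maskers")
})

random_conditions_table <- function(seed, n_listeners = 4) {
  withr::with_seed(seed, {
    tidyr::expand_grid(listener_id = sprintf("L%02d", seq_len(n_listeners)),
                       label = condition_labels(),
                       reversed = c(FALSE, TRUE)) |>
      dplyr::mutate(srt_db = round(runif(dplyr::n(), -25, 0), 1))
  })
}

test_that("every doubling contrast gains exactly 10 log10(2) in TMR accounting", {
  for (seed in c(1, 2, 3)) {
    tab <- random_conditions_table(seed)
    cc <- srt_contrasts(tab)
    snr_pen <- cc[cc$family == "multi_masker_penalty_snr", ]
    tmr_pen <- cc[cc$family == "multi_masker_penalty_tmr", ]
    key <- function(d) paste(sub("MMP_(TMR_)?", "", d$name), d$reversed)
    m <- match(key(snr_pen), key(tmr_pen))
    expect_equal(tmr_pen$value_db[m] - snr_pen$value_db,
                 rep(10 * log10(2), nrow(snr_pen)), tolerance = 1e-12)
  }
})

test_that("intelligibility-MR differences equal sex-cue-MR differences across states", {
  # MR_int(TSS) - MR_int(TDD) == MR_sex(TSS-TDD, fwd) - MR_sex(TSS-TDD, rev):
  # a pure arithmetic regrouping that must hold on any table
  for (seed in 4:6) {
    tab <- random_conditions_table(seed)
    cc <- srt_contrasts(tab)
    v <- function(nm, rev = NA) {
      rows <- cc$name == nm & (is.na(rev) | cc$reversed %in% rev)
      cc$value_db[rows]
    }
    lhs <- v("MR_intelligibility_TSS") - v("MR_intelligibility_TDD")
    rhs <- v("MR_sex_TSS_vs_TDD", FALSE) - v("MR_sex_TSS_vs_TDD", TRUE)
    expect_equal(lhs, rhs, tolerance = 1e-12)
    lhs2 <- v("MR_intelligibility_TS") - v("MR_intelligibility_TD")
    rhs2 <- v("MR_sex_TS_vs_TD", FALSE) - v("MR_sex_TS_vs_TD", TRUE)
    expect_equal(lhs2, rhs2, tolerance = 1e-12)
  }
})

test_that("summaries group conditions by talker count as published", {
  tab <- random_conditions_table(9, n_listeners = 3)
  g <- talker_group_means(tab)
  expect_setequal(g$n_talkers, c(1, 2, 4))
  manual_2 <- tab |>
    dplyr::filter(label %in% c("TDD", "TSD", "TSS"), !reversed) |>
    dplyr::group_by(listener_id) |>
    dplyr::summarise(srt = mean(srt_db)) |>
    dplyr::pull(srt) |> mean()
  expect_equal(g$mean_srt_db[g$n_talkers == 2 & !g$reversed], manual_2)
  cs <- condition_summary(tab)
  expect_equal(nrow(cs), 12L)
  expect_true(all(!is.na(cs$se_srt_db)))
  # single listener: SE is flagged as NA, never fabricated
  one <- condition_summary(tab[tab$listener_id == "L01", ])
  expect_true(all(is.na(one$se_srt_db)))
})

test_that("mean 1-to-2-masker penalty equals the mean of its two doubling pairs", {
  # fixed single-table input; the mean of (TDD - TD) and (TSS - TS) per state
  tab <- tibble::tibble(
    listener_id = "mean",
    label = rep(condition_labels(), 2),
    reversed = rep(c(FALSE, TRUE), each = 6),
    srt_db = c(-16, -12.2, -9.5, -2.0, -5.3, -3.5,
               -21.5, -21.3, -15.4, -13.0, -14.2, -9.0)
  )
  cc <- srt_contrasts(tab)
  fwd <- cc$value_db[cc$name %in% c("MMP_TDD_vs_TD", "MMP_TSS_vs_TS") & !cc$reversed]
  rev <- cc$value_db[cc$name %in% c("MMP_TDD_vs_TD", "MMP_TSS_vs_TS") & cc$reversed]
  expect_equal(mean(fwd), mean(c(-9.5 - -16, -2.0 - -12.2)))
  expect_equal(mean(rev), mean(c(-15.4 - -21.5, -13.0 - -21.3)))
})
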