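test_that("the long table has one row per participant-eye-sector-encounter", {
  fx <- generate_cohort(cohort_config(zero_noise = TRUE))
  sel <- select_better_scans(fx$scans)
  long <- build_long_table(sel, fx$encounters)
  # 38 participants x 2 eyes x 9 sectors x 3 pregnancy epochs; supplementary
  # peripartum encounters are excluded
  expect_equal(nrow(long), 38 * 2 * 9 * 3)

  one <- dplyr::filter(sel, participant_id == "C01")
  long1 <- build_long_table(one, fx$encounters)
  expect_equal(nrow(long1), 2 * 9 * 3)
})

test_that("a scan equal to baseline yields zero change in all nine rows", {
  s <- make_eye_series(280, list(`12` = 280, `30` = 276, `38` = 276))
  long <- build_long_table(s$scans, s$encounters)
  expect_equal(long$change_from_baseline[long$epoch == "early"], rep(0, 9))
  expect_equal(long$change_from_baseline[long$epoch == "mid"], rep(-4, 9))
})

test_that("participants without a baseline are dropped with a warning", {
  fx <- generate_cohort(small_config())
  sel <- select_better_scans(fx$scans)
  sel <- dplyr::filter(sel, !(participant_id == "C01" & grepl("base", encounter_id)))
  expect_warning(long <- build_long_table(sel, fx$encounters), "C01")
  expect_false("C01" %in% long$participant_id)
  expect_equal(attr(long, "dropped_participants"), "C01")
})

test_that("a noise-free cohort with a planted uniform early change is recovered exactly", {
  eff <- list(
    control = c(early = 3.94, mid = 3.94, delivery = 3.94),
    denovo_hdp = c(early = 3.94, mid = 3.94, delivery = 3.94),
    chtn_lot = c(early = 3.94, mid = 3.94, delivery = 3.94),
    chtn_nolot = c(early = 3.94, mid = 3.94, delivery = 3.94)
  )
  cfg <- cohort_config(zero_noise = TRUE, effects_um = eff,
                       n_denovo = 4, n_chtn_lot = 0, n_chtn_nolot = 0,
                       ring_weights = c(center = 1, inner = 1, outer = 1),
                       inner_floor_um = 0,
                       lot_delta_onset_um = 0, lot_delta_delivery_um = 0,
                       hypo_counts = c(denovo_hdp = 0, chtn_lot = 0, chtn_nolot = 0),
                       late_thinner_count = 0)
  fx <- generate_cohort(cfg)
  long <- build_long_table(select_better_scans(fx$scans), fx$encounters,
                           dplyr::select(fx$truth, participant_id, group))
  expect_warning(fit <- fit_interval_model(long), "boundary|degenerate|estimated")
  est <- tidy(fit)
  expect_true(fit$degenerate)
  expect_lt(max(abs(est$mean[est$epoch == "early"] - (-3.94))), 1e-6)
})

test_that("a cohort generated with zero effects estimates zero change", {
  eff <- list(
    control = c(early = 0, mid = 0, delivery = 0),
    denovo_hdp = c(early = 0, mid = 0, delivery = 0),
    chtn_lot = c(early = 0, mid = 0, delivery = 0),
    chtn_nolot = c(early = 0, mid = 0, delivery = 0)
  )
  cfg <- small_config(seed = 5, effects_um = eff,
                      lot_delta_onset_um = 0, lot_delta_delivery_um = 0,
                      hypo_extra_thinning_um = 0)
  fx <- generate_cohort(cfg)
  long <- build_long_table(select_better_scans(fx$scans), fx$encounters)
  fit <- fit_interval_model(long)
  est <- tidy(fit)
  expect_true(all(abs(est$mean) < 2 * est$se))
})

test_that("estimates are invariant to row order and eye relabeling", {
  fx <- generate_cohort(small_config(seed = 31))
  long <- build_long_table(select_better_scans(fx$scans), fx$encounters,
                           dplyr::select(fx$truth, participant_id, group))
  fit <- fit_interval_model(long)
  set.seed(1)
  shuffled <- long[sample(nrow(long)), ]
  fit_shuf <- fit_interval_model(shuffled)
  expect_equal(tidy(fit)$mean, tidy(fit_shuf)$mean, tolerance = 1e-6)

  swapped <- dplyr::mutate(long, eye = ifelse(eye == "OD", "OS_eye", "OD"))
  fit_swap <- fit_interval_model(swapped)
  expect_equal(tidy(fit)$mean, tidy(fit_swap)$mean, tolerance = 1e-6)
})

test_that("with no serial correlation and single-sector data the fit matches a balanced GLS oracle", {
  # balanced two-level design: GLS fixed effects reduce to the cell means
  set.seed(88)
  d <- tidyr::expand_grid(
    participant_id = c("P1", "P2", "P3"),
    eye = c("OD", "OS_eye"),
    epoch = c("early", "mid")
  ) |>
    dplyr::mutate(
      sector = "C",
      encounter_time = ifelse(epoch == "early", 12, 30),
      change_from_baseline = round(
        -4 + 2 * (epoch == "mid") +
          rep(rnorm(3, 0, 1.5), each = 4) + # participant effects
          rep(rnorm(6, 0, 0.8), each = 2) + # eye effects
          rnorm(12, 0, 0.5), 2
      )
    )
  fit <- fit_interval_model(d, correlation = "none")
  oracle <- tapply(d$change_from_baseline, d$epoch, mean)
  est <- tidy(fit)
  expect_equal(est$mean[est$epoch == "early"], unname(oracle["early"]),
               tolerance = 1e-6)
  expect_equal(est$mean[est$epoch == "mid"], unname(oracle["mid"]),
               tolerance = 1e-6)
})

test_that("model validation rejects unusable inputs", {
  fx <- generate_cohort(small_config())
  long <- build_long_table(select_better_scans(fx$scans), fx$encounters)
  expect_error(fit_interval_model(long, by_group = TRUE), "group")
  tiny <- dplyr::filter(
    build_long_table(select_better_scans(fx$scans), fx$encounters,
                     dplyr::select(fx$truth, participant_id, group)),
    participant_id %in% c("C01", "D01", "D02")
  )
  expect_error(fit_interval_model(tiny, by_group = TRUE), "fewer than 2")
  bad <- dplyr::mutate(long, change_from_baseline =
                         ifelse(dplyr::row_number() == 1, NaN, change_from_baseline))
  expect_error(fit_interval_model(bad), "non-finite")
})

test_that("tidy, glance and autoplot expose the fit", {
  fx <- generate_cohort(small_config(seed = 3))
  long <- build_long_table(select_better_scans(fx$scans), fx$encounters,
                           dplyr::select(fx$truth, participant_id, group))
  fit <- fit_interval_model(long, by_group = TRUE)
  est <- tidy(fit)
  expect_true(all(est$ci_lo <= est$mean & est$mean <= est$ci_hi))
  expect_true(all(fit$varcomp$sd >= 0))
  expect_true(fit$phi >= 0 && fit$phi < 1)
  expect_s3_class(tidy(fit, "contrasts"), "tbl_df")
  expect_equal(nrow(glance(fit)), 1)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
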