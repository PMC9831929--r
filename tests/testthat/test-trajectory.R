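test_that("a control-pattern eye shows early thinning and no loss of thinning", {
  s <- make_eye_series(280, list(`12` = 276, `28` = 276, `38` = 276))
  tr <- classify_eye(s$scans, s$encounters)
  expect_true(tr$early_thinning)
  expect_equal(tr$early_thinning_ga, 12)
  expect_false(tr$lot)
  expect_false(tr$overt_thickening)
  expect_equal(nrow(tr$sudden_events[[1]]), 0)
})

test_that("a sequential +4 um rebound in 3 contiguous sectors is loss of thinning", {
  rebound <- flat_map(276)
  rebound[c("IS", "IN", "II")] <- 280
  s <- make_eye_series(280, list(`12` = 276, `30` = rebound, `38` = rebound))
  tr <- classify_eye(s$scans, s$encounters)
  expect_true(tr$early_thinning)
  expect_true(tr$lot)
  expect_equal(tr$lot_ga, 30)
})

test_that("an eye with no change never fires", {
  s <- make_eye_series(280, list(`12` = 280, `30` = 280, `38` = 280))
  tr <- classify_eye(s$scans, s$encounters)
  expect_false(tr$early_thinning)
  expect_false(tr$lot)
  expect_true(is.na(tr$lot_ga))
})

test_that("classify_eye validates its inputs", {
  s <- make_eye_series(280, list(`12` = 276, `30` = 276))
  no_base <- dplyr::filter(s$scans, !grepl("base", encounter_id))
  expect_error(classify_eye(no_base, s$encounters), "baseline")
  enc_na <- dplyr::mutate(s$encounters,
                          gestational_age = ifelse(epoch == "early", NA, gestational_age))
  expect_error(classify_eye(s$scans, enc_na), "time-ordered")
})

test_that("sudden confluent thinning after established thinning plus a MAP drop is hypoperfusion", {
  # thinning established at 12 wk, sudden confluent drop at delivery with
  # MAP falling 101 -> 80
  s <- make_eye_series(
    280, list(`12` = 276, `30` = 276, `38` = 264),
    sbp = c(112, 129, 104, 112), dbp = c(70, 87, 68, 70)
  )
  tr <- classify_eye(s$scans, s$encounters)
  expect_equal(nrow(tr$sudden_events[[1]]), 1)
  expect_equal(tr$sudden_events[[1]]$ga, 38)
  expect_true(detect_hypoperfusion(tr, s$encounters))
  expect_false(detect_hypoperfusion(tr, s$encounters, drop_threshold = 25))

  # same thinning but MAP unchanged: no hypoperfusion
  s2 <- make_eye_series(280, list(`12` = 276, `30` = 276, `38` = 264))
  tr2 <- classify_eye(s2$scans, s2$encounters)
  expect_false(detect_hypoperfusion(tr2, s2$encounters))

  # MAP drop without any thinning event: no hypoperfusion
  s3 <- make_eye_series(
    280, list(`12` = 276, `30` = 276, `38` = 276),
    sbp = c(112, 129, 104, 112), dbp = c(70, 87, 68, 70)
  )
  tr3 <- classify_eye(s3$scans, s3$encounters)
  expect_false(detect_hypoperfusion(tr3, s3$encounters))
})

eye_row <- function(pid = "P1", eye = "OD", early = TRUE, lot = FALSE,
                    hypo = FALSE, thick = FALSE, lot_ga = NA_real_) {
  tibble::tibble(
    participant_id = pid, eye = eye,
    early_thinning = early, early_thinning_ga = ifelse(early, 12, NA_real_),
    lot = lot, lot_ga = ifelse(lot, lot_ga, NA_real_),
    lot_encounter_id = ifelse(lot, paste0(pid, "_ga", lot_ga), NA_character_),
    overt_thickening = thick,
    sudden_events = list(tibble::tibble(encounter_id = character(0),
                                        ga = numeric(0), magnitude = numeric(0))),
    hypoperfusion = hypo
  )
}

test_that("participant aggregation follows the both-eyes-normal rule", {
  od <- eye_row(lot = TRUE, lot_ga = 30)
  os <- eye_row(eye = "OS_eye")
  p <- classify_participant(od, os)
  expect_equal(p$label, "loss_of_thinning")
  expect_true(p$single_eye_lot)
  expect_false(p$no_injury)
  expect_equal(p$lot_ga, 30)

  both_ok <- classify_participant(eye_row(), eye_row(eye = "OS_eye"))
  expect_equal(both_ok$label, "maintained_thinning")
  expect_true(both_ok$no_injury)

  p3 <- classify_participant(
    eye_row(lot = TRUE, lot_ga = 30, hypo = TRUE),
    eye_row(eye = "OS_eye", lot = TRUE, lot_ga = 34)
  )
  expect_equal(p3$label, "loss_of_thinning")
  expect_false(p3$single_eye_lot)
  expect_true(p3$hypoperfusion)

  none <- classify_participant(eye_row(early = FALSE),
                               eye_row(eye = "OS_eye", early = FALSE))
  expect_equal(none$label, "no_early_thinning")

  expect_error(classify_participant(eye_row(), eye_row(pid = "P2", eye = "OS_eye")),
               "mismatch")
})

test_that("eye order never changes the participant label", {
  od <- eye_row(lot = TRUE, lot_ga = 30, hypo = TRUE)
  os <- eye_row(eye = "OS_eye", thick = TRUE)
  a <- classify_participant(od, os)
  b <- classify_participant(
    dplyr::mutate(os, eye = "OD"),
    dplyr::mutate(od, eye = "OS_eye")
  )
  expect_equal(a$label, b$label)
  expect_equal(a$single_eye_lot, b$single_eye_lot)
  expect_equal(a$hypoperfusion, b$hypoperfusion)
  expect_equal(a$no_injury, b$no_injury)
})

test_that("classification recovers every planted label when signals dominate noise", {
  cfg <- small_config(seed = 21, cor_um = 0.8, sd_visit = 0.1,
                      sd_change_sector = 0.1)
  fx <- generate_cohort(cfg)
  parts <- fx$scans |>
    select_better_scans() |>
    classify_eyes(fx$encounters) |>
    classify_participants()
  joined <- dplyr::inner_join(parts, fx$truth, by = "participant_id")
  expect_equal(joined$label, joined$planted_label)
  expect_equal(joined$single_eye_lot.x, joined$single_eye_lot.y)
  expect_equal(joined$hypoperfusion.x, joined$hypoperfusion.y)
})

test_that("participant labels are exhaustive and mutually exclusive on the fixture", {
  fx <- default_fixture()
  parts <- fx$scans |>
    select_better_scans() |>
    classify_eyes(fx$encounters) |>
    classify_participants()
  expect_equal(nrow(parts), nrow(fx$truth))
  expect_true(all(parts$label %in%
                    c("maintained_thinning", "loss_of_thinning", "no_early_thinning")))
  expect_true(all(!parts$single_eye_lot | parts$label == "loss_of_thinning"))
  expect_true(all(!parts$no_injury | parts$label != "loss_of_thinning"))
})
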