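#' Classify the longitudinal scan sequence of one eye
#'
#' Applies the interval change rule along an eye's scan sequence and derives
#' its trajectory labels:
#'
#' * **early thinning** -- the rule fires in the thinning direction for
#'   (non-pregnant baseline -> a pregnancy scan); checked scan by scan in
#'   gestational order, `early_thinning_ga` records the first firing (which
#'   may fall after the early epoch for late responders).
#' * **loss of thinning (LOT)** -- the rule fires in the thickening
#'   direction on a sequential within-pregnancy pair (previous pregnancy
#'   scan -> current); the non-pregnant baseline plays no part, so LOT is
#'   detectable without a baseline image. `lot_ga` is the gestational age of
#'   the first firing scan.
#' * **sudden thinning events** -- sequential pairs firing in the thinning
#'   direction after LOT or after established thinning (candidate
#'   hypoperfusion events; see [detect_hypoperfusion()]).
#' * **overt thickening** -- a pregnancy scan thicker than the non-pregnant
#'   baseline by the rule.
#'
#' Every scan is evaluated, so multiple encounters within one epoch are all
#' considered and the first firing sets the timing.
#'
#' @param scans Selected (better-of-two) wide scan records of a single
#'   participant eye, including the baseline scan.
#' @param encounters Encounter table covering those scans.
#' @param params Decision rule, default [rule_params()].
#' @param edges Contiguity convention.
#' @return A one-row tibble: `participant_id`, `eye`, `early_thinning`,
#'   `early_thinning_ga`, `lot`, `lot_ga`, `lot_encounter_id`,
#'   `overt_thickening`, and a list-column `sudden_events`
#'   (tibble: `encounter_id`, `ga`, `magnitude`).
#' @export
classify_eye <- function(scans, encounters, params = rule_params(),
                         edges = etdrs_adjacency()) {
  stopifnot(nrow(scans) >= 2)
  if (dplyr::n_distinct(scans$participant_id) != 1 ||
      dplyr::n_distinct(scans$eye) != 1) {
    stop("classify_eye expects scans of a single participant eye")
  }
  pid <- scans$participant_id[1]
  eye <- scans$eye[1]
  scans <- dplyr::inner_join(
    scans, dplyr::select(encounters, "participant_id", "encounter_id",
                         "epoch", "gestational_age"),
    by = c("participant_id", "encounter_id")
  )
  baseline <- dplyr::filter(scans, .data$epoch == "nonpregnant_baseline")
  if (nrow(baseline) == 0) {
    stop("missing non-pregnant baseline scan for participant ", pid, " eye ", eye)
  }
  preg <- dplyr::filter(scans, .data$epoch != "nonpregnant_baseline")
  if (nrow(preg) == 0) {
    stop("no pregnancy scan for participant ", pid, " eye ", eye)
  }
  if (any(is.na(preg$gestational_age))) {
    stop("pregnancy scan without gestational age; scans cannot be time-ordered")
  }
  preg <- dplyr::arrange(preg, .data$gestational_age, .data$encounter_id)

  n <- nrow(preg)
  base_map <- baseline[1, ]
  vs_base <- purrr::map(seq_len(n), function(i) {
    apply_rule(interval_change(base_map, preg[i, ]), params, edges)
  })
  thin_base <- purrr::map_lgl(vs_base, "fires_thinning")
  thick_base <- purrr::map_lgl(vs_base, "fires_thickening")

  seq_rules <- purrr::map(seq_len(n)[-1], function(i) {
    apply_rule(interval_change(preg[i - 1, ], preg[i, ]), params, edges)
  })
  seq_thick <- c(FALSE, purrr::map_lgl(seq_rules, "fires_thickening"))
  seq_thin <- c(FALSE, purrr::map_lgl(seq_rules, "fires_thinning"))

  early_thinning <- any(thin_base)
  early_idx <- which(thin_base)[1]
  lot_idx <- which(seq_thick)[1]

  # thinning established strictly before scan i (early thinning or LOT seen
  # at an earlier scan) makes a sequential thinning firing a "sudden" event
  established_before <- vapply(seq_len(n), function(i) {
    (early_thinning && !is.na(early_idx) && early_idx < i) ||
      (!is.na(lot_idx) && lot_idx < i)
  }, logical(1))
  sudden_idx <- which(seq_thin & established_before)
  sudden_events <- tibble::tibble(
    encounter_id = preg$encounter_id[sudden_idx],
    ga = preg$gestational_age[sudden_idx],
    magnitude = purrr::map_dbl(sudden_idx, function(i) {
      d <- seq_rules[[i - 1]]$diffs[[1]]
      mean(d[d <= -params$tau])
    })
  )

  tibble::tibble(
    participant_id = pid,
    eye = eye,
    early_thinning = early_thinning,
    early_thinning_ga = if (early_thinning) preg$gestational_age[early_idx] else NA_real_,
    lot = !is.na(lot_idx),
    lot_ga = if (!is.na(lot_idx)) preg$gestational_age[lot_idx] else NA_real_,
    lot_encounter_id = if (!is.na(lot_idx)) preg$encounter_id[lot_idx] else NA_character_,
    overt_thickening = any(thick_base),
    sudden_events = list(sudden_events)
  )
}

#' Flag hypoperfusion injury for one eye trajectory
#'
#' A hypoperfusion event is a sudden confluent thinning concomitant with a
#' significant drop in systemic blood pressure: the eye is flagged when any
#' sudden thinning event coincides with a MAP decrease of at least
#' `drop_threshold` mmHg relative to the immediately preceding encounter of
#' the same participant. Events whose encounter (or its predecessor) lacks a
#' blood pressure are skipped with a warning.
#'
#' @param eye_trajectory One-row tibble from [classify_eye()].
#' @param encounters Encounter table for the participant.
#' @param drop_threshold MAP drop defining a significant fall, mmHg
#'   (default 15).
#' @return Logical flag.
#' @export
detect_hypoperfusion <- function(eye_trajectory, encounters, drop_threshold = 15) {
  stopifnot(nrow(eye_trajectory) == 1, drop_threshold > 0)
  events <- eye_trajectory$sudden_events[[1]]
  if (nrow(events) == 0) {
    return(FALSE)
  }
  enc <- encounters |>
    dplyr::filter(.data$participant_id == eye_trajectory$participant_id,
                  .data$epoch != "nonpregnant_baseline") |>
    dplyr::arrange(.data$gestational_age, .data$encounter_id) |>
    dplyr::mutate(map = mean_arterial_pressure(.data$sbp, .data$dbp))
  drops <- vapply(events$encounter_id, function(id) {
    i <- match(id, enc$encounter_id)
    if (is.na(i) || i == 1 || !is.finite(enc$map[i]) || !is.finite(enc$map[i - 1])) {
      warning("sudden thinning event at encounter ", id,
              " skipped: blood pressure not resolvable")
      return(NA_real_)
    }
    enc$map[i - 1] - enc$map[i]
  }, numeric(1))
  any(drops >= drop_threshold, na.rm = TRUE)
}

#' Classify every eye of a cohort
#'
#' Applies [classify_eye()] and [detect_hypoperfusion()] to each
#' (participant, eye) group of a selected scan table.
#'
#' @param scans Selected (one scan per eye-encounter) wide scan table.
#' @param encounters Encounter table.
#' @inheritParams classify_eye
#' @param drop_threshold Passed to [detect_hypoperfusion()].
#' @return Tibble with one row per eye, the columns of [classify_eye()] plus
#'   `hypoperfusion`.
#' @export
classify_eyes <- function(scans, encounters, params = rule_params(),
                          edges = etdrs_adjacency(), drop_threshold = 15) {
  scans |>
    dplyr::group_by(.data$participant_id, .data$eye) |>
    dplyr::group_split() |>
    purrr::map(function(s) {
      tr <- classify_eye(s, encounters, params, edges)
      tr$hypoperfusion <- detect_hypoperfusion(tr, encounters, drop_threshold)
      tr
    }) |>
    dplyr::bind_rows()
}

#' Aggregate two eye trajectories to a participant label
#'
#' The two eyes are treated as independent observations, but both must be
#' normal for a participant to count as free of microvascular injury.
#' The primary label is:
#'
#' * `loss_of_thinning` when either eye shows LOT;
#' * otherwise `no_early_thinning` when neither eye ever shows early
#'   thinning;
#' * otherwise `maintained_thinning`.
#'
#' `single_eye_lot` marks LOT confined to exactly one eye; `hypoperfusion`
#' is true when either eye is flagged; `no_injury` requires both eyes free
#' of LOT, hypoperfusion and overt thickening. The label set is exhaustive
#' and mutually exclusive, and eye order is immaterial.
#'
#' @param od,os One-row eye trajectory tibbles (with `hypoperfusion` column)
#'   for the right and left eye of the same participant.
#' @return One-row tibble: `participant_id`, `label`, `single_eye_lot`,
#'   `hypoperfusion`, `no_injury`, `lot_ga`, `lot_encounter_id`,
#'   `early_thinning_ga`.
#' @export
classify_participant <- function(od, os) {
  stopifnot(nrow(od) == 1, nrow(os) == 1)
  if (od$participant_id != os$participant_id) {
    stop("participant mismatch: ", od$participant_id, " vs ", os$participant_id)
  }
  eyes <- dplyr::bind_rows(od, os)
  n_lot <- sum(eyes$lot)
  label <- if (n_lot > 0) {
    "loss_of_thinning"
  } else if (!any(eyes$early_thinning)) {
    "no_early_thinning"
  } else {
    "maintained_thinning"
  }
  lot_ga <- if (n_lot > 0) min(eyes$lot_ga, na.rm = TRUE) else NA_real_
  lot_enc <- if (n_lot > 0) {
    eyes$lot_encounter_id[eyes$lot][which.min(eyes$lot_ga[eyes$lot])]
  } else {
    NA_character_
  }
  tibble::tibble(
    participant_id = od$participant_id,
    label = label,
    single_eye_lot = n_lot == 1,
    hypoperfusion = any(eyes$hypoperfusion),
    no_injury = !any(eyes$lot) && !any(eyes$hypoperfusion) &&
      !any(eyes$overt_thickening),
    lot_ga = lot_ga,
    lot_encounter_id = lot_enc,
    early_thinning_ga = if (any(eyes$early_thinning)) {
      min(eyes$early_thinning_ga, na.rm = TRUE)
    } else {
      NA_real_
    }
  )
}

#' @rdname classify_participant
#' @param eyes Eye trajectory table from [classify_eyes()]; each participant
#'   must contribute both eyes.
#' @return `classify_participants()`: one row per participant.
#' @export
classify_participants <- function(eyes) {
  eyes |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_split() |>
    purrr::map(function(e) {
      if (nrow(e) != 2) {
        stop("participant ", e$participant_id[1], " has ", nrow(e),
             " eye trajectories; both eyes are required")
      }
      classify_participant(e[e$eye == "OD", ], e[e$eye == "OS_eye", ])
    }) |>
    dplyr::bind_rows()
}
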