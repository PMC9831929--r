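scan_columns <- function() {
  c(
    "participant_id", "eye", "encounter_id", "replicate", "signal_strength",
    etdrs_sectors()
  )
}

encounter_columns <- function() {
  c("participant_id", "encounter_id", "epoch", "gestational_age", "sbp", "dbp")
}

epoch_levels <- function() {
  c("early", "mid", "delivery", "nonpregnant_baseline")
}

check_scan_table <- function(scans, check_values = TRUE) {
  missing <- setdiff(scan_columns(), names(scans))
  if (length(missing) > 0) {
    stop("scan table is missing column(s): ", paste(missing, collapse = ", "))
  }
  key <- paste(scans$participant_id, scans$eye, scans$encounter_id, scans$replicate)
  if (anyDuplicated(key)) {
    stop(
      "duplicate (participant, eye, encounter, replicate) key(s), e.g.: ",
      key[duplicated(key)][1]
    )
  }
  if (!all(scans$eye %in% c("OD", "OS_eye"))) {
    stop("eye must be 'OD' or 'OS_eye'")
  }
  if (check_values && nrow(scans) > 0) {
    vals <- as.matrix(scans[, etdrs_sectors()])
    if (!is.numeric(vals) || any(!is.finite(vals))) {
      stop("non-numeric or non-finite sector thickness value")
    }
    ss <- scans$signal_strength
    if (any(!is.finite(ss) | ss < 0 | ss > 10)) {
      stop("signal_strength must lie in [0, 10]")
    }
  }
  invisible(scans)
}

check_encounter_table <- function(encounters) {
  missing <- setdiff(encounter_columns(), names(encounters))
  if (length(missing) > 0) {
    stop("encounter table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!all(encounters$epoch %in% epoch_levels())) {
    stop("unknown epoch label(s)")
  }
  nb <- encounters |>
    dplyr::filter(.data$epoch == "nonpregnant_baseline") |>
    dplyr::count(.data$participant_id)
  if (any(nb$n > 1)) {
    stop("more than one non-pregnant baseline encounter for participant ",
         nb$participant_id[nb$n > 1][1])
  }
  early_ga <- encounters$gestational_age[encounters$epoch == "early"]
  if (any(!is.na(early_ga) & early_ga >= 20)) {
    stop("early-epoch encounter with gestational age >= 20 weeks")
  }
  ok_bp <- with(encounters, is.finite(sbp) & is.finite(dbp) &
                  dbp >= 40 & dbp < sbp & sbp <= 300)
  if (!all(ok_bp)) {
    stop("blood pressure outside 40 <= dbp < sbp <= 300 mmHg")
  }
  invisible(encounters)
}

#' Read and write scan tables
#'
#' The on-disk format is a UTF-8 comma-separated file with dot decimals and
#' the fixed header
#' `participant_id,eye,encounter_id,replicate,signal_strength,C,IS,IN,II,IT,OS,ON,OI,OT`.
#' Sector thicknesses are micrometres stored to 0.01 um; writing then reading
#' a table is the identity at that precision. Malformed rows (non-numeric
#' sectors, missing columns, duplicate replicate keys) raise an error naming
#' the offending column or line.
#'
#' @param path File path.
#' @return `read_scans()`: a wide tibble of scan records.
#' @export
read_scans <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      eye = readr::col_character(),
      encounter_id = readr::col_character(),
      replicate = readr::col_integer(),
      signal_strength = readr::col_double(),
      .default = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop(
      "malformed scan file at line ", probs$row[1] + 1, ": expected ",
      probs$expected[1], ", got '", probs$actual[1], "'"
    )
  }
  check_scan_table(out)
  dplyr::mutate(out, dplyr::across(dplyr::all_of(etdrs_sectors()), ~ round(.x, 2)))
}

#' @rdname read_scans
#' @param scans Wide scan tibble.
#' @return `write_scans()`: the input, invisibly.
#' @export
write_scans <- function(scans, path) {
  check_scan_table(scans)
  out <- scans |>
    dplyr::select(dplyr::all_of(scan_columns())) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(etdrs_sectors()), ~ round(.x, 2)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(scans)
}

#' Read and write encounter tables
#'
#' Comma-separated with header
#' `participant_id,encounter_id,epoch,gestational_age,sbp,dbp`;
#' `gestational_age` is in weeks and empty for the non-pregnant baseline,
#' pressures are mmHg. Each participant has exactly one
#' `nonpregnant_baseline` encounter.
#'
#' @param path File path.
#' @return `read_encounters()`: a tibble of encounters.
#' @export
read_encounters <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      encounter_id = readr::col_character(),
      epoch = readr::col_character(),
      gestational_age = readr::col_double(),
      sbp = readr::col_double(),
      dbp = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop("malformed encounter file at line ", probs$row[1] + 1)
  }
  check_encounter_table(out)
  out
}

#' @rdname read_encounters
#' @param encounters Encounter tibble.
#' @return `write_encounters()`: the input, invisibly.
#' @export
write_encounters <- function(encounters, path) {
  check_encounter_table(encounters)
  readr::write_csv(
    dplyr::select(encounters, dplyr::all_of(encounter_columns())),
    path, progress = FALSE
  )
  invisible(encounters)
}

#' Select the better of the two replicate scans
#'
#' At every encounter two scans are taken per eye; the one with the higher
#' instrument signal strength is prospectively selected for analysis, with
#' ties resolved in favour of replicate 1. `select_better_scan()` operates on
#' a single pair of records; `select_better_scans()` applies the selection to
#' every (participant, eye, encounter) group of a scan table.
#'
#' @param r1,r2 One-row scan tibbles for replicates of the same
#'   participant/eye/encounter.
#' @return The selected one-row tibble.
#' @export
#' @examples
#' scans <- default_fixture()$scans
#' nrow(select_better_scans(scans)) # one record per eye-encounter
select_better_scan <- function(r1, r2) {
  stopifnot(nrow(r1) == 1, nrow(r2) == 1)
  same <- r1$participant_id == r2$participant_id &&
    r1$eye == r2$eye && r1$encounter_id == r2$encounter_id
  if (!same) {
    stop("replicate metadata mismatch: scans are not from the same eye-encounter")
  }
  if (r2$signal_strength > r1$signal_strength) r2 else r1
}

#' @rdname select_better_scan
#' @param scans Wide scan tibble with both replicates.
#' @export
select_better_scans <- function(scans) {
  check_scan_table(scans)
  scans |>
    dplyr::group_by(.data$participant_id, .data$eye, .data$encounter_id) |>
    dplyr::arrange(dplyr::desc(.data$signal_strength), .data$replicate,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Run the full analysis pipeline
#'
#' Chains the package end to end: better-of-two scan selection, empirical
#' null calibration from the replicate pairs, eye and participant trajectory
#' classification, the hierarchical interval model (pooled and by group,
#' when group labels are supplied), and MAP summaries anchored to retinal
#' events. With no inputs a default synthetic cohort is generated.
#'
#' @param scans,encounters Input tables; both `NULL` to simulate.
#' @param groups Optional tibble `participant_id`, `group` (required for the
#'   by-group interval model and group-restricted MAP summaries; supplied
#'   automatically in simulate mode from the generator ground truth).
#' @param params Decision rule, default [rule_params()].
#' @param config Generator configuration for simulate mode, default
#'   [cohort_config()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as CSV alongside a `report.txt`.
#' @return A list of class `macula_report`: `calibration`, `eye_trajectories`,
#'   `participants`, `interval_fit_pooled`, `interval_fit_by_group`,
#'   `map_summaries`, `dropped` (log of excluded records).
#' @export
run_pipeline <- function(scans = NULL, encounters = NULL, groups = NULL,
                         params = rule_params(), config = cohort_config(),
                         out_dir = NULL) {
  if (is.null(scans) != is.null(encounters)) {
    stop("supply both scans and encounters, or neither (simulate mode)")
  }
  if (is.null(scans)) {
    cohort <- generate_cohort(config)
    scans <- cohort$scans
    encounters <- cohort$encounters
    groups <- dplyr::select(cohort$truth, "participant_id", "group")
  }
  check_scan_table(scans)
  check_encounter_table(encounters)

  pairs <- replicate_pairs(scans)
  if (length(pairs) == 0) {
    stop("change_rule stage failed: no same-encounter replicate pairs for calibration")
  }
  calibration <- calibrate_null(pairs, params = params)

  selected <- select_better_scans(scans)

  # participants lacking a baseline scan are dropped, with a log entry
  has_baseline <- selected |>
    dplyr::inner_join(encounters, by = c("participant_id", "encounter_id")) |>
    dplyr::filter(.data$epoch == "nonpregnant_baseline") |>
    dplyr::distinct(.data$participant_id)
  dropped <- selected |>
    dplyr::anti_join(has_baseline, by = "participant_id") |>
    dplyr::distinct(.data$participant_id) |>
    dplyr::mutate(reason = "no non-pregnant baseline scan")
  if (nrow(dropped) > 0) {
    warning(nrow(dropped), " participant(s) dropped: no baseline scan")
    selected <- dplyr::semi_join(selected, has_baseline, by = "participant_id")
  }

  eyes <- classify_eyes(selected, encounters, params = params)
  participants <- classify_participants(eyes)

  long <- build_long_table(selected, encounters, groups = groups)
  fit_pooled <- fit_interval_model(long, by_group = FALSE)
  fit_groups <- if (!is.null(groups)) fit_interval_model(long, by_group = TRUE) else NULL

  denovo <- if (!is.null(groups)) {
    groups$participant_id[groups$group == "denovo_hdp"]
  } else {
    participants$participant_id[participants$label == "loss_of_thinning"]
  }
  map_summaries <- dplyr::bind_rows(
    map_at_anchor(encounters, participants, "enrollment", participant_ids = denovo),
    tryCatch(
      map_at_anchor(encounters, participants, "lot", participant_ids = denovo),
      error = function(e) NULL
    ),
    map_at_anchor(encounters, participants, "delivery", participant_ids = denovo),
    tryCatch(
      map_rise(encounters, participants, "lot", "delivery", participant_ids = denovo),
      error = function(e) NULL
    )
  )

  report <- structure(
    list(
      calibration = calibration,
      eye_trajectories = eyes,
      participants = participants,
      interval_fit_pooled = fit_pooled,
      interval_fit_by_group = fit_groups,
      map_summaries = map_summaries,
      dropped = dropped
    ),
    class = "macula_report"
  )
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
  }
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(report$calibration), file.path(out_dir, "calibration.csv"))
  readr::write_csv(
    dplyr::select(
      report$participants, "participant_id", "label", "single_eye_lot",
      "hypoperfusion", "lot_ga", "early_thinning_ga"
    ),
    file.path(out_dir, "participants.csv")
  )
  readr::write_csv(tidy(report$interval_fit_pooled), file.path(out_dir, "interval_estimates_pooled.csv"))
  if (!is.null(report$interval_fit_by_group)) {
    readr::write_csv(tidy(report$interval_fit_by_group), file.path(out_dir, "interval_estimates_by_group.csv"))
  }
  readr::write_csv(report$map_summaries, file.path(out_dir, "map_summaries.csv"))
  con <- file(file.path(out_dir, "report.txt"), "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  invisible(report)
}

#' @export
print.macula_report <- function(x, ...) {
  cat("Macular thickness pipeline report\n")
  cat("=================================\n\n")
  print(x$calibration)
  cat("\nParticipant classification:\n")
  print(dplyr::count(x$participants, .data$label, .data$single_eye_lot,
                     .data$hypoperfusion))
  if (nrow(x$dropped) > 0) {
    cat("\nDropped participants:\n")
    print(x$dropped)
  }
  cat("\nInterval estimates (pooled):\n")
  print(tidy(x$interval_fit_pooled), n = 20)
  cat("\nMAP summaries:\n")
  print(x$map_summaries)
  invisible(x)
}
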