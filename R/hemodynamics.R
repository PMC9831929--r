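#' Mean arterial pressure
#'
#' Standard one-third pulse pressure formula,
#' MAP = dbp + (sbp - dbp) / 3, reported to 0.1 mmHg. Vectorised.
#' Integer rounding (e.g. 116.7 presented as 117) is left to presentation.
#'
#' @param sbp,dbp Systolic and diastolic pressures, mmHg; must satisfy
#'   40 <= dbp < sbp <= 300 (equal pressures are tolerated as a degenerate
#'   zero-pulse-pressure input and return that value).
#' @return MAP in mmHg, rounded to 0.1.
#' @export
#' @examples
#' mean_arterial_pressure(112, 70) # 84.0
#' mean_arterial_pressure(150, 100) # 116.7, presents as 117
mean_arterial_pressure <- function(sbp, dbp) {
  stopifnot(length(sbp) == length(dbp))
  bad <- !is.finite(sbp) | !is.finite(dbp) | dbp < 40 | dbp > sbp | sbp > 300
  if (any(bad)) {
    stop("invalid blood pressure: need 40 <= dbp <= sbp <= 300 mmHg")
  }
  round(dbp + (sbp - dbp) / 3, 1)
}

# per-participant MAP at a named anchor encounter; anchors:
#   enrollment - first encounter in time (lowest gestational age)
#   delivery   - first delivery-epoch encounter
#   lot        - the encounter at which LOT first fired (participants whose
#                LOT is first seen at the delivery encounter are excluded:
#                their true MAP at loss of thinning is not estimable)
anchor_maps <- function(encounters, trajectories, anchor,
                        participant_ids = NULL) {
  check_encounter_table(encounters)
  enc <- encounters |>
    dplyr::filter(.data$epoch != "nonpregnant_baseline") |>
    dplyr::mutate(map = mean_arterial_pressure(.data$sbp, .data$dbp))
  if (!is.null(participant_ids)) {
    enc <- dplyr::filter(enc, .data$participant_id %in% participant_ids)
  }
  if (anchor == "enrollment") {
    out <- enc |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::arrange(.data$gestational_age, .data$encounter_id, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  } else if (anchor == "delivery") {
    out <- enc |>
      dplyr::filter(.data$epoch == "delivery") |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::arrange(.data$gestational_age, .data$encounter_id, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  } else if (anchor == "lot") {
    if (is.null(trajectories)) {
      stop("the lot anchor requires participant trajectories")
    }
    lot <- trajectories |>
      dplyr::filter(.data$label == "loss_of_thinning", !is.na(.data$lot_encounter_id))
    first_delivery <- enc |>
      dplyr::filter(.data$epoch == "delivery") |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::arrange(.data$gestational_age, .data$encounter_id, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::select("participant_id", delivery_encounter = "encounter_id")
    lot <- lot |>
      dplyr::left_join(first_delivery, by = "participant_id") |>
      dplyr::filter(is.na(.data$delivery_encounter) |
                      .data$lot_encounter_id != .data$delivery_encounter)
    out <- enc |>
      dplyr::inner_join(
        dplyr::select(lot, "participant_id", encounter_id = "lot_encounter_id"),
        by = c("participant_id", "encounter_id")
      )
  } else {
    stop("unknown anchor '", anchor, "'")
  }
  dplyr::select(out, "participant_id", "encounter_id", "map")
}

t_ci <- function(x) {
  n <- length(x)
  m <- mean(x)
  if (n < 2) {
    return(c(mean = m, lo = NA_real_, hi = NA_real_, n = n))
  }
  half <- stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half, n = n)
}

#' Cohort MAP summary at an anchor encounter
#'
#' Mean and Student-t 95% confidence interval of per-participant mean
#' arterial pressure at a cohort anchor: `enrollment` (first encounter),
#' `lot` (the encounter where loss of thinning first fired; participants
#' whose LOT was first seen at delivery are excluded because their true
#' MAP at loss of thinning cannot be reliably estimated) or `delivery`
#' (first delivery-epoch encounter). A single-participant summary has a
#' degenerate (NA) interval, flagged in the `degenerate` column.
#'
#' @param encounters Encounter table.
#' @param trajectories Participant trajectory table from
#'   [classify_participants()] (needed for the `lot` anchor; may be `NULL`
#'   otherwise).
#' @param anchor `"enrollment"`, `"lot"` or `"delivery"`.
#' @param participant_ids Optional restriction (e.g. one HDP subgroup).
#' @return One-row tibble: `summary`, `anchor`, `n`, `mean`, `ci_lo`,
#'   `ci_hi`, `degenerate`.
#' @export
map_at_anchor <- function(encounters, trajectories = NULL,
                          anchor = c("enrollment", "lot", "delivery"),
                          participant_ids = NULL) {
  anchor <- match.arg(anchor)
  maps <- anchor_maps(encounters, trajectories, anchor, participant_ids)
  if (nrow(maps) == 0) {
    stop("no participant resolvable at anchor '", anchor, "'")
  }
  ci <- t_ci(maps$map)
  tibble::tibble(
    summary = "map",
    anchor = anchor,
    n = as.integer(ci[["n"]]),
    mean = ci[["mean"]],
    ci_lo = ci[["lo"]],
    ci_hi = ci[["hi"]],
    degenerate = ci[["n"]] < 2
  )
}

#' Within-participant MAP rise between two anchors
#'
#' Pairs each participant's MAP at `from_anchor` and `to_anchor` and
#' summarises the within-participant differences (to minus from) with a
#' Student-t 95% CI. The paired rise is the authoritative quantity; it
#' equals the difference of the two anchor means only when the anchored
#' participant sets coincide.
#'
#' @inheritParams map_at_anchor
#' @param from_anchor,to_anchor Anchor names as in [map_at_anchor()].
#' @return One-row tibble as [map_at_anchor()], `anchor` being
#'   `"<from>-><to>"`.
#' @export
map_rise <- function(encounters, trajectories = NULL,
                     from_anchor = "lot", to_anchor = "delivery",
                     participant_ids = NULL) {
  from <- anchor_maps(encounters, trajectories, from_anchor, participant_ids)
  to <- anchor_maps(encounters, trajectories, to_anchor, participant_ids)
  paired <- dplyr::inner_join(
    dplyr::select(from, "participant_id", from_map = "map"),
    dplyr::select(to, "participant_id", to_map = "map"),
    by = "participant_id"
  )
  if (nrow(paired) == 0) {
    stop("no participant resolvable at both anchors")
  }
  ci <- t_ci(paired$to_map - paired$from_map)
  tibble::tibble(
    summary = "map_rise",
    anchor = paste0(from_anchor, "->", to_anchor),
    n = as.integer(ci[["n"]]),
    mean = ci[["mean"]],
    ci_lo = ci[["lo"]],
    ci_hi = ci[["hi"]],
    degenerate = ci[["n"]] < 2
  )
}
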