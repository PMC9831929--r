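#' Parameters of the interval change decision rule
#'
#' The decision rule fires when a directionally identical interval
#' difference of at least `tau` micrometres appears in `k` or more contiguous
#' ETDRS sectors of a single eye. The defaults (tau = 4 um, k = 3) set tau to
#' twice the instrument's test-retest coefficient of repeatability (2 um).
#'
#' @param tau Change threshold in um, > 0. Default 4.
#' @param k Minimum contiguous sector count, integer in 1..9. Default 3.
#' @return A list of class `rule_params`.
#' @export
#' @examples
#' rule_params()
rule_params <- function(tau = 4, k = 3) {
  stopifnot(is.numeric(tau), length(tau) == 1, is.finite(tau), tau > 0)
  stopifnot(is.numeric(k), length(k) == 1, k == as.integer(k), k >= 1, k <= 9)
  structure(list(tau = tau, k = as.integer(k)), class = "rule_params")
}

#' @export
print.rule_params <- function(x, ...) {
  cat(sprintf(
    "Change rule: |difference| >= %g um in >= %d contiguous ETDRS sectors\n",
    x$tau, x$k
  ))
  invisible(x)
}

#' Per-sector interval change between two scans of one eye
#'
#' Computes followup minus reference thickness for each sector; negative
#' values are thinning. Inputs can be named numeric vectors over the nine
#' sectors or one-row wide scan tibbles (as read by [read_scans()]); values
#' are stored to 0.01 um. When both inputs carry an `eye` column/field the
#' lateralities must match.
#'
#' @param reference,followup Complete sector maps (named vectors or one-row
#'   tibbles with columns `C`..`OT`).
#' @return Named numeric vector of differences, um, canonical sector order.
#' @export
#' @examples
#' a <- stats::setNames(rep(280, 9), etdrs_sectors())
#' b <- stats::setNames(rep(276, 9), etdrs_sectors())
#' interval_change(a, b)
interval_change <- function(reference, followup) {
  eye_of <- function(x) {
    if (is.data.frame(x) && "eye" %in% names(x)) x$eye else NA_character_
  }
  e1 <- eye_of(reference)
  e2 <- eye_of(followup)
  if (!is.na(e1) && !is.na(e2) && e1 != e2) {
    stop("laterality mismatch: reference is ", e1, ", followup is ", e2)
  }
  ref <- round(complete_sector_vector(reference), 2)
  fol <- round(complete_sector_vector(followup), 2)
  round(fol - ref, 2)
}

#' Apply the contiguity decision rule to interval differences
#'
#' Evaluates both directions independently: the rule fires for thickening
#' (thinning) when the largest connected component of sectors with
#' difference >= +tau (<= -tau) has size >= k. Both directions may fire on
#' the same pair.
#'
#' @param diffs Named numeric vector of per-sector differences, um.
#' @param params A [rule_params()] object.
#' @param edges Contiguity convention, by default [etdrs_adjacency()].
#' @return A one-row tibble with columns `fires_thickening`, `fires_thinning`,
#'   `max_pos_component`, `max_neg_component` and a list-column `diffs`
#'   holding the (rounded) difference vector.
#' @export
#' @examples
#' d <- stats::setNames(rep(-5, 9), etdrs_sectors())
#' apply_rule(d)
apply_rule <- function(diffs, params = rule_params(), edges = etdrs_adjacency()) {
  stopifnot(inherits(params, "rule_params"))
  diffs <- round(complete_sector_vector(diffs), 2)
  pos <- largest_directional_component(diffs, params$tau, "+", edges)
  neg <- largest_directional_component(diffs, params$tau, "-", edges)
  tibble::tibble(
    fires_thickening = pos >= params$k,
    fires_thinning = neg >= params$k,
    max_pos_component = as.integer(pos),
    max_neg_component = as.integer(neg),
    diffs = list(diffs)
  )
}

#' Empirical-null calibration of the decision rule
#'
#' Estimates, for every weaker rule (tau', k') on a grid, the frequency with
#' which the rule fires in either direction across a null set of paired
#' same-encounter scans of the same eye. The grid defaults enumerate all
#' combinations of lesser levels of change dominated by the default rule:
#' tau' in 1..4 um by k' in 1..9 sectors. Because the firing event is
#' monotone, the frequency surface is non-increasing in both tau' and k'.
#'
#' @param null_pairs A list of pairs; each element is a list or unnamed pair
#'   `list(reference, followup)` of complete sector maps, or a two-row wide
#'   scan tibble. Conveniently produced by [replicate_pairs()].
#' @param tau_grid Numeric vector of thresholds, um. Default `1:4`.
#' @param k_grid Integer vector of contiguity counts. Default `1:9`.
#' @param params The rule whose firing frequency is reported as `p_at_rule`
#'   (its tau and k are added to the grids if absent).
#' @param edges Contiguity convention.
#' @return A list of class `null_calibration` with elements `n_pairs`,
#'   `freq` (tibble: `tau`, `k`, `n_pairs`, `freq`) and `p_at_rule`.
#' @export
calibrate_null <- function(null_pairs, tau_grid = 1:4, k_grid = 1:9,
                           params = rule_params(), edges = etdrs_adjacency()) {
  if (length(null_pairs) == 0) {
    stop("empty null pair list")
  }
  stopifnot(all(tau_grid > 0), all(k_grid >= 1 & k_grid <= 9))
  tau_grid <- sort(unique(c(tau_grid, params$tau)))
  k_grid <- sort(unique(as.integer(c(k_grid, params$k))))

  diff_list <- lapply(null_pairs, function(p) {
    if (is.data.frame(p)) {
      stopifnot(nrow(p) == 2)
      interval_change(p[1, ], p[2, ])
    } else {
      stopifnot(length(p) == 2)
      interval_change(p[[1]], p[[2]])
    }
  })
  # per pair: largest component size in each direction at each tau'.
  # Component sizes depend only on the marked sector subset, so they are
  # precomputed for all 2^9 subsets and looked up by bitmask.
  lookup <- component_size_lookup(edges)
  D <- do.call(rbind, diff_list) # pairs x 9, canonical sector order
  bit <- 2^(0:8)
  size_mat <- vapply(tau_grid, function(t) {
    pos <- as.integer((D >= t) %*% bit) + 1L
    neg <- as.integer((D <= -t) %*% bit) + 1L
    pmax(lookup[pos], lookup[neg])
  }, integer(length(diff_list)))
  size_mat <- matrix(size_mat, nrow = length(diff_list)) # pairs x tau_grid
  freq <- tidyr::expand_grid(tau = tau_grid, k = k_grid) |>
    dplyr::mutate(
      n_pairs = length(diff_list),
      freq = purrr::map2_dbl(.data$tau, .data$k, function(t, kk) {
        mean(size_mat[, match(t, tau_grid)] >= kk)
      })
    )
  p_at_rule <- freq$freq[freq$tau == params$tau & freq$k == params$k]
  structure(
    list(n_pairs = length(diff_list), freq = freq, p_at_rule = p_at_rule),
    class = "null_calibration"
  )
}

#' @export
print.null_calibration <- function(x, ...) {
  cat(sprintf(
    "Empirical null calibration over %d same-encounter scan pairs\n",
    x$n_pairs
  ))
  cat(sprintf("Firing frequency at the configured rule: %.4f\n", x$p_at_rule))
  invisible(x)
}

#' @rdname calibrate_null
#' @param x A `null_calibration` object.
#' @param ... Unused.
#' @return `tidy()`: the frequency grid as a tibble.
#' @export
tidy.null_calibration <- function(x, ...) {
  x$freq
}

# size of the largest connected component for every subset of the nine
# sectors, indexed by bitmask + 1 (canonical sector order)
component_size_lookup <- function(edges) {
  sectors <- etdrs_sectors()
  vapply(0:511, function(mask) {
    marked <- sectors[bitwAnd(mask, 2^(0:8)) > 0]
    comps <- sector_components(marked, edges)
    if (length(comps) == 0) 0L else max(lengths(comps))
  }, integer(1))
}

#' Extract same-encounter replicate scan pairs from a scan table
#'
#' Pairs the two replicate scans of each (participant, eye, encounter); these
#' same-encounter pairs are the empirical null for [calibrate_null()].
#' Encounters with fewer than two replicates are skipped.
#'
#' @param scans Wide scan tibble (see [read_scans()]).
#' @return A list of two-row tibbles.
#' @export
replicate_pairs <- function(scans) {
  check_scan_table(scans)
  scans |>
    dplyr::group_by(.data$participant_id, .data$eye, .data$encounter_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::arrange(.data$replicate, .by_group = TRUE) |>
    dplyr::group_split() |>
    purrr::map(~ .x[1:2, ])
}
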