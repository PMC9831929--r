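# Independent oracles and small builders used across the test files.
# Everything here is deliberately written straight-line, without reusing the
# package's graph-search or calibration code paths.

sector_names <- c("C", "IS", "IN", "II", "IT", "OS", "ON", "OI", "OT")

# a flat sector map as a named vector
flat_map <- function(value = 280) {
  stats::setNames(rep(value, 9), sector_names)
}

# brute-force connected components: repeated neighbour expansion over the raw
# edge list (no igraph)
oracle_components <- function(marked, edges = etdrs_adjacency()) {
  marked <- as.character(marked)
  comps <- list()
  remaining <- marked
  while (length(remaining) > 0) {
    comp <- remaining[1]
    repeat {
      grow <- unique(c(
        edges$to[edges$from %in% comp], edges$from[edges$to %in% comp]
      ))
      grow <- intersect(grow, remaining)
      new <- union(comp, grow)
      if (setequal(new, comp)) break
      comp <- new
    }
    comps[[length(comps) + 1]] <- sort(comp)
    remaining <- setdiff(remaining, comp)
  }
  comps[order(-lengths(comps))]
}

# all connected subsets of the nine sectors with at least `min_size` members,
# found by exhaustive enumeration of the 2^9 subsets
oracle_connected_subsets <- function(min_size, edges = etdrs_adjacency()) {
  out <- list()
  for (mask in 1:511) {
    s <- sector_names[bitwAnd(mask, 2^(0:8)) > 0]
    if (length(s) < min_size) next
    if (length(oracle_components(s, edges)) == 1) {
      out[[length(out) + 1]] <- s
    }
  }
  out
}

# straight-line null-calibration frequency: a pair fires at (tau, k) iff some
# connected subset of >= k sectors is wholly above +tau or wholly below -tau
oracle_null_frequency <- function(diff_mat, tau, k, edges = etdrs_adjacency()) {
  subsets <- oracle_connected_subsets(k, edges)
  D <- round(diff_mat[, sector_names, drop = FALSE], 2)
  above <- D >= tau
  below <- D <= -tau
  fired <- rep(FALSE, nrow(D))
  for (s in subsets) {
    fired <- fired |
      rowSums(above[, s, drop = FALSE]) == length(s) |
      rowSums(below[, s, drop = FALSE]) == length(s)
  }
  mean(fired)
}

# one-row wide scan tibble
make_scan <- function(values, participant_id = "P1", eye = "OD",
                      encounter_id = "E1", replicate = 1L,
                      signal_strength = 9) {
  vals <- if (length(values) == 1) flat_map(values) else values
  dplyr::bind_cols(
    tibble::tibble(
      participant_id = participant_id, eye = eye,
      encounter_id = encounter_id, replicate = replicate,
      signal_strength = signal_strength
    ),
    tibble::as_tibble(as.list(vals))
  )
}

# a minimal encounter row
make_encounter <- function(participant_id, encounter_id, epoch,
                           gestational_age = NA_real_, sbp = 112, dbp = 70) {
  tibble::tibble(
    participant_id = participant_id, encounter_id = encounter_id,
    epoch = epoch, gestational_age = gestational_age, sbp = sbp, dbp = dbp
  )
}

# a one-eye longitudinal series: baseline plus pregnancy scans given as a
# named list ga -> sector map (values or full vectors)
make_eye_series <- function(baseline, preg, participant_id = "P1", eye = "OD",
                            sbp = NULL, dbp = NULL) {
  gas <- as.numeric(names(preg))
  n <- length(gas)
  if (is.null(sbp)) sbp <- rep(112, n + 1)
  if (is.null(dbp)) dbp <- rep(70, n + 1)
  scans <- dplyr::bind_rows(c(
    list(make_scan(baseline, participant_id, eye, paste0(participant_id, "_base"))),
    unname(purrr::imap(preg, function(v, ga) {
      make_scan(v, participant_id, eye, paste0(participant_id, "_ga", ga))
    }))
  ))
  encounters <- dplyr::bind_rows(
    make_encounter(participant_id, paste0(participant_id, "_base"),
                   "nonpregnant_baseline", sbp = sbp[n + 1], dbp = dbp[n + 1]),
    purrr::map2_dfr(gas, seq_len(n), function(ga, i) {
      epoch <- if (ga < 20) "early" else if (ga < 36) "mid" else "delivery"
      make_encounter(participant_id, paste0(participant_id, "_ga", ga),
                     epoch, gestational_age = ga, sbp = sbp[i], dbp = dbp[i])
    })
  )
  list(scans = scans, encounters = encounters)
}

# small fast generator configuration for pipeline-level tests
small_config <- function(seed = 7, ...) {
  cohort_config(n_control = 4, n_denovo = 4, n_chtn_lot = 4, n_chtn_nolot = 4,
                seed = seed, ...)
}
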