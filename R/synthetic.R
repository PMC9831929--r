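#' Configuration of the synthetic cohort generator
#'
#' All parameters of [generate_cohort()], defaulting to the statistical
#' structure of the emulated study: 11 non-hypertensive controls and 27 HDP
#' participants (12 de novo HDP, 8 HDP on chronic hypertension with loss of
#' thinning, 7 without), four encounter epochs (non-pregnant baseline and
#' visits at 12, 30 and 38 weeks), two replicate scans per eye per
#' encounter with test-retest noise anchored to a 2 um coefficient of
#' repeatability, group-specific thinning trajectories, patchy contiguous
#' loss-of-thinning plants, hypoperfusion events with a concomitant MAP
#' drop, and group MAP anchor trajectories.
#'
#' Thinning effects are positive magnitudes in um (applied with negative
#' sign); they are the realized group-by-epoch mean changes, so the
#' generator compensates the base trajectory for planted loss-of-thinning
#' mass and the group means match the configured truths exactly when all
#' noise is off.
#'
#' @param n_control,n_denovo,n_chtn_lot,n_chtn_nolot Group sizes.
#' @param effects_um Named list of per-group length-3 vectors (early, mid,
#'   delivery thinning magnitudes, um).
#' @param baseline_um Named vector of the nine baseline sector means, um.
#' @param ring_weights Relative thinning depth of center/inner/outer rings
#'   (mean 1 over the nine sectors).
#' @param inner_floor_um Minimum planted inner-ring depth at the
#'   early-thinning epoch, um (keeps the planted signal comfortably above
#'   the 4 um decision threshold).
#' @param cor_um Test-retest coefficient of repeatability, um; the
#'   per-scan replicate noise SD is `cor_um / (1.96 * sqrt(2))`.
#' @param sd_baseline_participant,sd_baseline_eye,sd_baseline_sector
#'   Between-participant / eye / sector SDs of absolute baseline thickness,
#'   um (cancel in change-from-baseline).
#' @param participant_effect_range,eye_effect_range Half-width of the
#'   uniform multiplicative response-intensity factors at participant and
#'   eye level.
#' @param sd_change_participant,sd_change_eye SDs of the persistent additive
#'   participant- and eye-level change offsets, um (truncated at 2 SD so
#'   planted rule firings remain noise-robust).
#' @param sd_change_sector SD of the persistent per-sector change offset, um.
#' @param sd_visit,serial_range_weeks SD and continuous-time AR(1) range of
#'   the per-visit biological noise, um and weeks.
#' @param lot_delta_onset_um,lot_delta_delivery_um Planted contiguous
#'   effacement at loss-of-thinning onset and (grown) at delivery, um;
#'   effaced sector sets are contiguous subsets of 3--5 sectors cycled over
#'   LOT participants.
#' @param lot_delivery_frac Fraction of chronic-hypertension LOT
#'   participants whose loss of thinning first appears at delivery.
#' @param single_eye_frac Fraction of LOT participants (per group) with
#'   single-eye loss of thinning.
#' @param hypo_counts Named counts of hypoperfusion participants per group.
#' @param hypo_map_drop,hypo_extra_thinning_um MAP drop (mmHg) and
#'   confluent extra thinning (um) planted at the peripartum hypoperfusion
#'   event encounter.
#' @param late_thinner_count Number of HDP participants (taken from the
#'   chtn_nolot group) whose early thinning first fires between 20 and 32
#'   weeks rather than before 20 weeks.
#' @param visit_ga,baseline_time_weeks Gestational ages (weeks) of the
#'   early/mid/delivery visits and the position of the non-pregnant
#'   baseline on the common time axis used for serial correlation.
#' @param visit_jitter_sd Per-participant visit-time jitter SD (weeks,
#'   truncated at +-2); 0 gives the fixed fixture schedule.
#' @param map_anchors Named list of per-group MAP means (mmHg) at
#'   (baseline, enrollment, mid, delivery).
#' @param denovo_rise_mean,denovo_rise_sd Within-participant MAP rise from
#'   the mid (loss-of-thinning) visit to delivery in the de novo group.
#' @param sd_map_participant,sd_map_visit Between-participant and per-visit
#'   MAP SDs, mmHg.
#' @param seed Integer seed making the whole cohort reproducible.
#' @param zero_noise Convenience switch setting every noise source
#'   (replicate, visit, sector offset, multipliers, jitter, MAP jitter) to
#'   zero.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_control = 11, n_denovo = 12, n_chtn_lot = 8, n_chtn_nolot = 7,
    effects_um = list(
      control = c(early = 3.92, mid = 3.08, delivery = 5.16),
      denovo_hdp = c(early = 4.35, mid = 2.99, delivery = 3.45),
      chtn_lot = c(early = 3.39, mid = 2.85, delivery = 1.06),
      chtn_nolot = c(early = 3.91, mid = 3.80, delivery = 4.46)
    ),
    baseline_um = c(
      C = 250, IS = 285, IN = 288, II = 282, IT = 280,
      OS = 270, ON = 285, OI = 265, OT = 260
    ),
    ring_weights = c(center = 1, inner = 1, outer = 1),
    inner_floor_um = 6,
    cor_um = 2,
    sd_baseline_participant = 12, sd_baseline_eye = 4, sd_baseline_sector = 3,
    participant_effect_range = 0.2, eye_effect_range = 0.1,
    sd_change_participant = 0.7, sd_change_eye = 0.35,
    sd_change_sector = 0.3,
    sd_visit = 0.45, serial_range_weeks = 10,
    lot_delta_onset_um = 10, lot_delta_delivery_um = 12,
    lot_delivery_frac = 0.375,
    single_eye_frac = 0.35,
    hypo_counts = c(denovo_hdp = 2, chtn_lot = 2, chtn_nolot = 1),
    hypo_map_drop = 21, hypo_extra_thinning_um = 12,
    late_thinner_count = 1,
    visit_ga = c(early = 12, mid = 30, delivery = 38),
    baseline_time_weeks = 69,
    visit_jitter_sd = 1,
    map_anchors = list(
      control = c(baseline = 84, enrollment = 84, mid = 86, delivery = 88),
      denovo_hdp = c(baseline = 84, enrollment = 84, mid = 82, delivery = NA),
      chtn_lot = c(baseline = 92, enrollment = 87, mid = 98, delivery = 102),
      chtn_nolot = c(baseline = 92, enrollment = 89, mid = 100, delivery = 117)
    ),
    denovo_rise_mean = 19, denovo_rise_sd = 3.5,
    sd_map_participant = 8, sd_map_visit = 2.5,
    seed = 20210617,
    zero_noise = FALSE) {
  cfg <- as.list(environment())
  if (zero_noise) {
    cfg$sd_baseline_participant <- 0
    cfg$sd_baseline_eye <- 0
    cfg$sd_baseline_sector <- 0
    cfg$participant_effect_range <- 0
    cfg$eye_effect_range <- 0
    cfg$sd_change_participant <- 0
    cfg$sd_change_eye <- 0
    cfg$sd_change_sector <- 0
    cfg$sd_visit <- 0
    cfg$visit_jitter_sd <- 0
    cfg$sd_map_participant <- 0
    cfg$sd_map_visit <- 0
    cfg$denovo_rise_sd <- 0
    cfg$cor_um <- 0
  }
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  problems <- character(0)
  note <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  sizes <- c(cfg$n_control, cfg$n_denovo, cfg$n_chtn_lot, cfg$n_chtn_nolot)
  note(all(sizes >= 0 & sizes == round(sizes)), "group sizes must be non-negative integers")
  note(setequal(names(cfg$effects_um), c("control", "denovo_hdp", "chtn_lot", "chtn_nolot")) &&
         all(vapply(cfg$effects_um, length, 1L) == 3) &&
         all(unlist(cfg$effects_um) >= 0),
       "effects_um must give non-negative early/mid/delivery magnitudes for all four groups")
  note(setequal(names(cfg$baseline_um), etdrs_sectors()) &&
         all(cfg$baseline_um > 100 & cfg$baseline_um < 600),
       "baseline_um must cover the nine sectors with values in (100, 600) um")
  note(abs(cfg$ring_weights[["center"]] + 4 * cfg$ring_weights[["inner"]] +
             4 * cfg$ring_weights[["outer"]] - 9) < 1e-8,
       "ring_weights must average 1 over the nine sectors")
  sds <- c(cfg$cor_um, cfg$sd_baseline_participant, cfg$sd_baseline_eye,
           cfg$sd_baseline_sector, cfg$sd_change_participant,
           cfg$sd_change_eye, cfg$sd_change_sector, cfg$sd_visit,
           cfg$sd_map_participant, cfg$sd_map_visit, cfg$denovo_rise_sd,
           cfg$visit_jitter_sd)
  note(all(sds >= 0), "all noise SDs must be >= 0")
  note(cfg$participant_effect_range >= 0 && cfg$participant_effect_range < 1 &&
         cfg$eye_effect_range >= 0 && cfg$eye_effect_range < 1,
       "effect ranges must lie in [0, 1)")
  note(cfg$lot_delivery_frac >= 0 && cfg$lot_delivery_frac <= 1 &&
         cfg$single_eye_frac >= 0 && cfg$single_eye_frac <= 1,
       "fractions must lie in [0, 1]")
  note(cfg$visit_ga[["early"]] < 20, "the early visit must fall before 20 weeks")
  note(all(diff(cfg$visit_ga[c("early", "mid", "delivery")]) > 0),
       "visit schedule must be increasing")
  note(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
       "seed must be a single integer")
  if (length(problems) > 0) {
    stop("invalid cohort configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  invisible(cfg)
}

# contiguous effacement templates cycled over LOT participants; single-eye
# plants use inner-ring sets (the deepest-thinned sectors, so the planted
# sequential rebound is largest where only one eye can fire the rule)
lot_sector_templates <- function(single_eye) {
  if (single_eye) {
    list(
      c("IS", "IN", "II"), c("IN", "II", "IT"), c("IS", "IN", "II", "IT")
    )
  } else {
    list(
      c("IS", "IN", "II"), c("IT", "OT", "OS"),
      c("ON", "OI", "II"), c("II", "IT", "OI", "OT")
    )
  }
}

sector_weights <- function(cfg) {
  w <- c(cfg$ring_weights[["center"]],
         rep(cfg$ring_weights[["inner"]], 4),
         rep(cfg$ring_weights[["outer"]], 4))
  names(w) <- etdrs_sectors()
  w
}

# normal draw truncated at +-2 SD: persistent offsets stay bounded so planted
# rule firings are never washed out by a tail draw
rtrunc2 <- function(n, sd) {
  if (sd == 0) return(rep(0, n))
  pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd)
}

# structural allocation of the cohort: groups, LOT laterality/onset/sectors,
# hypoperfusion flags, the late early-thinner; deterministic given sizes
allocate_participants <- function(cfg) {
  groups <- c(
    rep("control", cfg$n_control),
    rep("denovo_hdp", cfg$n_denovo),
    rep("chtn_lot", cfg$n_chtn_lot),
    rep("chtn_nolot", cfg$n_chtn_nolot)
  )
  prefix <- c(control = "C", denovo_hdp = "D", chtn_lot = "L", chtn_nolot = "N")
  ids <- unlist(lapply(split(groups, factor(groups, unique(groups))), function(g) {
    sprintf("%s%02d", prefix[[g[1]]], seq_along(g))
  }), use.names = FALSE)
  truth <- tibble::tibble(participant_id = ids, group = groups)

  truth$lot <- truth$group %in% c("denovo_hdp", "chtn_lot")
  # chronic-hypertension LOT first seen at delivery for a fixed fraction
  n_del <- round(cfg$lot_delivery_frac * cfg$n_chtn_lot)
  chtn_idx <- which(truth$group == "chtn_lot")
  truth$lot_onset <- ifelse(truth$lot, "mid", NA)
  if (n_del > 0) {
    truth$lot_onset[utils::tail(chtn_idx, n_del)] <- "delivery"
  }
  # single-eye LOT among mid-onset participants of each LOT group
  truth$lot_eyes <- ifelse(truth$lot, "both", NA)
  for (g in c("denovo_hdp", "chtn_lot")) {
    idx <- which(truth$group == g & truth$lot & truth$lot_onset == "mid")
    n_single <- round(cfg$single_eye_frac * sum(truth$group == g & truth$lot))
    truth$lot_eyes[utils::head(idx, n_single)] <- "OD"
  }
  # contiguous effaced sector sets, cycled over templates
  lot_idx <- which(truth$lot)
  truth$lot_sectors <- vector("list", nrow(truth))
  j_single <- 0
  j_both <- 0
  for (idx in lot_idx) {
    single <- truth$lot_eyes[idx] != "both"
    pool <- lot_sector_templates(single)
    jj <- if (single) (j_single <- j_single + 1) else (j_both <- j_both + 1)
    truth$lot_sectors[[idx]] <- pool[[(jj - 1) %% length(pool) + 1]]
  }
  # hypoperfusion: bilateral LOT participants first, then non-LOT groups
  truth$hypoperfusion <- FALSE
  for (g in names(cfg$hypo_counts)) {
    n_h <- cfg$hypo_counts[[g]]
    if (n_h == 0) next
    cand <- which(truth$group == g &
                    (!truth$lot | (truth$lot_eyes == "both" &
                                     truth$lot_onset == "mid")))
    truth$hypoperfusion[utils::head(cand, n_h)] <- TRUE
  }
  # the late early-thinner: chtn_nolot participants without hypoperfusion
  truth$late_thinner <- FALSE
  if (cfg$late_thinner_count > 0) {
    cand <- which(truth$group == "chtn_nolot" & !truth$hypoperfusion)
    truth$late_thinner[utils::tail(cand, cfg$late_thinner_count)] <- TRUE
  }
  truth
}

#' Generate a synthetic macular-thickness cohort
#'
#' Simulates the full observable record of a repeated-measures pregnancy
#' cohort: per participant one non-pregnant baseline plus three pregnancy
#' encounters (a supplementary peripartum encounter for hypoperfusion
#' participants), two replicate scans per eye per encounter with Gaussian
#' test-retest noise of SD `cor_um / (1.96 sqrt(2))`, group-specific
#' ring-weighted thinning trajectories, planted contiguous loss-of-thinning
#' effacement growing from onset to delivery, planted hypoperfusion events
#' with a concomitant MAP drop, and per-encounter blood pressures hitting
#' the configured MAP anchors. Output is bit-reproducible for a given
#' configuration (the seed is part of the configuration).
#'
#' @param config A [cohort_config()].
#' @return A list with elements `scans` (wide replicate-level scan tibble),
#'   `encounters`, `truth` (per-participant ground truth: group, planted
#'   label, LOT onset/laterality/sectors, hypoperfusion, late-thinner flag,
#'   MAP anchor truths) and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_control = 2, n_denovo = 2,
#'                                         n_chtn_lot = 2, n_chtn_nolot = 2))
#' dplyr::count(cohort$truth, group)
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  cfg <- config

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  truth <- allocate_participants(cfg)
  n <- nrow(truth)
  w <- sector_weights(cfg)
  sectors <- etdrs_sectors()
  epochs <- c("early", "mid", "delivery")

  # response-intensity multipliers and the late-thinner early-scale, with
  # exact within-group compensation of the late thinner's shallow start
  truth$mult_p <- stats::runif(n, 1 - cfg$participant_effect_range,
                               1 + cfg$participant_effect_range)
  truth$early_scale <- 1
  for (g in unique(truth$group)) {
    idx <- which(truth$group == g)
    late <- which(truth$group == g & truth$late_thinner)
    if (length(late) > 0) {
      truth$early_scale[late] <- 0.25
      rest <- setdiff(idx, late)
      truth$early_scale[rest] <-
        (length(idx) - 0.25 * length(late)) / length(rest)
    }
  }

  # per-participant visit times
  jitter <- function(k) {
    if (cfg$visit_jitter_sd == 0) {
      rep(0, k)
    } else {
      pmin(pmax(stats::rnorm(k, 0, cfg$visit_jitter_sd), -2), 2)
    }
  }
  times <- purrr::map(seq_len(n), function(i) {
    ga <- cfg$visit_ga + jitter(3)
    c(baseline = unname(cfg$baseline_time_weeks),
      early = unname(ga[["early"]]), mid = unname(ga[["mid"]]),
      delivery = unname(ga[["delivery"]]))
  })

  # planted LOT effacement delta per participant/epoch (um, positive)
  lot_delta <- function(i, epoch) {
    if (!truth$lot[i]) return(0)
    onset <- truth$lot_onset[i]
    if (onset == "mid") {
      if (epoch == "mid") return(cfg$lot_delta_onset_um)
      if (epoch == "delivery") return(cfg$lot_delta_delivery_um)
    }
    if (onset == "delivery" && epoch == "delivery") {
      return(cfg$lot_delta_onset_um)
    }
    0
  }

  # group-level plant mass per epoch (um contribution to the group mean),
  # from the realized allocation: subtracted uniformly so the realized
  # group-by-epoch mean equals the configured truth
  groups_u <- unique(truth$group)
  plant_mean <- sapply(epochs, function(ep) {
    vapply(groups_u, function(g) {
      idx <- which(truth$group == g)
      tot <- sum(vapply(idx, function(i) {
        n_eyes <- if (is.na(truth$lot_eyes[i])) 0 else if (truth$lot_eyes[i] == "both") 2 else 1
        lot_delta(i, ep) * length(truth$lot_sectors[[i]]) * n_eyes
      }, numeric(1)))
      tot / (length(idx) * 2 * 9)
    }, numeric(1))
  })
  plant_mean <- matrix(plant_mean, nrow = length(groups_u),
                       dimnames = list(groups_u, epochs))

  scan_rows <- vector("list", n)
  enc_rows <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- truth$participant_id[i]
    g <- truth$group[i]
    eff <- cfg$effects_um[[g]]
    tms <- times[[i]]
    has_supp <- truth$hypoperfusion[i]
    visit_names <- c("baseline", "early", "mid", "delivery",
                     if (has_supp) "supp")
    visit_t <- c(tms, if (has_supp) unname(tms[["delivery"]]) + 0.5)
    names(visit_t) <- visit_names
    nv <- length(visit_t)

    # serially correlated per-visit biological noise, per eye and sector
    if (cfg$sd_visit > 0) {
      S <- cfg$sd_visit^2 *
        exp(-abs(outer(visit_t, visit_t, "-")) / cfg$serial_range_weeks)
      L <- chol(S)
      eps <- array(t(L) %*% matrix(stats::rnorm(nv * 18), nv, 18),
                   dim = c(nv, 2, 9))
    } else {
      eps <- array(0, dim = c(nv, 2, 9))
    }

    b_p <- stats::rnorm(1, 0, cfg$sd_baseline_participant)
    bc_p <- rtrunc2(1, cfg$sd_change_participant)
    mult_p <- truth$mult_p[i]

    eye_rows <- list()
    for (ei in 1:2) {
      eye <- c("OD", "OS_eye")[ei]
      b_e <- stats::rnorm(1, 0, cfg$sd_baseline_eye)
      b_s <- stats::rnorm(9, 0, cfg$sd_baseline_sector)
      mult_e <- stats::runif(1, 1 - cfg$eye_effect_range, 1 + cfg$eye_effect_range)
      bc <- bc_p + rtrunc2(1, cfg$sd_change_eye) # persistent, less thinning if > 0
      change_offset <- stats::rnorm(9, 0, cfg$sd_change_sector)
      base_true <- cfg$baseline_um[sectors] + b_p + b_e + b_s

      lot_here <- truth$lot[i] &&
        (truth$lot_eyes[i] == "both" || truth$lot_eyes[i] == eye)
      hypo_here <- truth$hypoperfusion[i] # bilateral events

      # eye-mean thinning magnitude at an epoch (um, positive = thinning)
      floor_ep <- if (truth$late_thinner[i]) "mid" else "early"
      ep_rank <- c(early = 1, mid = 2, delivery = 3)
      M_at <- function(ep) {
        scale <- if (ep == "early") truth$early_scale[i] else 1
        eff[[ep]] * mult_p * mult_e * scale - bc
      }
      # persistent mean-zero inner-ring deepening profile guaranteeing the
      # planted detection signal at the first thinning epoch; present from
      # that epoch on, so sequential diffs stay spatially uniform
      inner <- c("IS", "IN", "II", "IT")
      gdef <- max(0, cfg$inner_floor_um - M_at(floor_ep) * w[["IS"]])
      profile <- stats::setNames(rep(4 * gdef / 5, 9), sectors)
      profile[inner] <- -gdef

      change_at <- function(ep) {
        pat <- -M_at(ep) * w
        if (ep_rank[[ep]] >= ep_rank[[floor_ep]]) {
          pat <- pat + profile
        }
        pat <- pat + change_offset - plant_mean[g, ep]
        if (lot_here) {
          delta <- lot_delta(i, ep)
          pat[truth$lot_sectors[[i]]] <- pat[truth$lot_sectors[[i]]] + delta
        }
        pat
      }

      truth_by_visit <- list(baseline = base_true)
      for (ep in epochs) {
        truth_by_visit[[ep]] <- base_true + change_at(ep)
      }
      if (has_supp) {
        extra <- if (hypo_here) cfg$hypo_extra_thinning_um else 0
        truth_by_visit[["supp"]] <- truth_by_visit[["delivery"]] - extra
      }

      rep_sd <- cfg$cor_um / (1.96 * sqrt(2))
      vals <- matrix(NA_real_, nrow = 2 * nv, ncol = 9,
                     dimnames = list(NULL, sectors))
      for (vi in seq_len(nv)) {
        tv <- unname(truth_by_visit[[visit_names[vi]]]) + eps[vi, ei, ]
        for (r in 1:2) {
          vals[2 * (vi - 1) + r, ] <-
            tv + if (rep_sd > 0) stats::rnorm(9, 0, rep_sd) else 0
        }
      }
      eye_rows[[ei]] <- dplyr::bind_cols(
        tibble::tibble(
          participant_id = pid, eye = eye,
          encounter_id = paste0(pid, "_", rep(visit_names, each = 2)),
          replicate = rep(1:2, nv),
          signal_strength = sample(6:10, 2 * nv, replace = TRUE)
        ),
        tibble::as_tibble(vals)
      )
    }
    scan_rows[[i]] <- dplyr::bind_rows(eye_rows)

    # MAP series; the participant shift is truncated at 2 SD so planted
    # normotension/hypertension at the anchors stays true by construction
    u <- rtrunc2(1, cfg$sd_map_participant)
    anchors <- cfg$map_anchors[[g]]
    vn <- function() stats::rnorm(1, 0, cfg$sd_map_visit)
    map_base <- anchors[["baseline"]] + u + vn()
    map_enr <- anchors[["enrollment"]] + u + vn()
    map_mid <- anchors[["mid"]] + u + vn()
    map_del <- if (g == "denovo_hdp") {
      map_mid + cfg$denovo_rise_mean +
        if (cfg$denovo_rise_sd > 0) stats::rnorm(1, 0, cfg$denovo_rise_sd) else 0
    } else {
      anchors[["delivery"]] + u + vn()
    }
    maps <- c(baseline = map_base, early = map_enr, mid = map_mid,
              delivery = map_del,
              if (has_supp) c(supp = map_del - cfg$hypo_map_drop))
    bp <- map_to_bp(maps)
    enc_rows[[i]] <- tibble::tibble(
      participant_id = pid,
      encounter_id = paste0(pid, "_", visit_names),
      epoch = dplyr::case_when(
        visit_names == "baseline" ~ "nonpregnant_baseline",
        visit_names == "supp" ~ "delivery",
        TRUE ~ visit_names
      ),
      gestational_age = ifelse(visit_names == "baseline", NA_real_,
                               visit_t[visit_names]),
      sbp = bp$sbp[visit_names], dbp = bp$dbp[visit_names]
    )
  }

  scans <- dplyr::bind_rows(scan_rows)
  encounters <- dplyr::bind_rows(enc_rows)
  check_scan_table(scans)
  check_encounter_table(encounters)

  truth$planted_label <- ifelse(truth$lot, "loss_of_thinning", "maintained_thinning")
  truth$single_eye_lot <- truth$lot & truth$lot_eyes == "OD"
  truth$lot_onset_ga <- purrr::map2_dbl(seq_len(n), truth$lot_onset, function(i, on) {
    if (is.na(on)) NA_real_ else unname(times[[i]][[on]])
  })
  truth$map_rise_truth <- ifelse(truth$group == "denovo_hdp", cfg$denovo_rise_mean, NA)

  list(scans = scans, encounters = encounters, truth = truth, config = cfg)
}

# integer office blood pressure hitting a target MAP, with a pulse pressure
# widening with pressure (112/70 at MAP 84, 150/100 at MAP 117)
map_to_bp <- function(map) {
  pp <- pmax(42 + 0.24 * (map - 84), 25)
  dbp <- round(map - pp / 3)
  sbp <- round(dbp + pp)
  dbp <- pmax(dbp, 40)
  sbp <- pmax(sbp, dbp + 5)
  list(sbp = sbp, dbp = dbp)
}

#' The default deterministic acceptance fixture
#'
#' [generate_cohort()] under the shipped default configuration with a fixed
#' visit schedule (no jitter) and the given seed. The planted composition is
#' 11 controls and 27 HDP participants of whom 20 lose the early thinning
#' response (12 de novo, 8 on chronic hypertension, 3 of those first at
#' delivery), 7 with single-eye loss of thinning, 5 with a hypoperfusion
#' event (4 with antecedent loss of thinning), 26 whose early thinning is
#' detectable before 20 weeks and exactly one whose thinning first fires
#' between 20 and 32 weeks. Planted signals sit well above the 4 um
#' decision threshold so the classification counts are reproduced exactly
#' at the default seed.
#'
#' @param seed Integer seed (default 20210617).
#' @return As [generate_cohort()].
#' @export
#' @examples
#' fx <- default_fixture()
#' dplyr::count(fx$truth, group, planted_label)
default_fixture <- function(seed = 20210617) {
  generate_cohort(cohort_config(seed = seed, visit_jitter_sd = 0))
}
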