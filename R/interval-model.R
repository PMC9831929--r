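#' Build the change-from-baseline long table
#'
#' Converts selected (better-of-two) scans into the long format consumed by
#' [fit_interval_model()]: one row per (participant, eye, sector, pregnancy
#' encounter) with the change from that participant/eye/sector's
#' non-pregnant value. Baseline rows are excluded (they define zero). One
#' encounter per epoch enters the table -- the first in gestational time --
#' so supplementary event follow-ups within an epoch do not enter interval
#' estimation. Participants without a baseline scan are dropped with a
#' warning and logged in the `dropped_participants` attribute.
#'
#' @param scans Selected wide scan table (one scan per eye-encounter).
#' @param encounters Encounter table.
#' @param groups Optional tibble `participant_id`, `group` with levels among
#'   `control`, `denovo_hdp`, `chtn_lot`, `chtn_nolot`.
#' @return Long tibble: `participant_id`, `eye`, `sector`, `epoch`,
#'   `encounter_time` (weeks), `change_from_baseline` (um), and `group` when
#'   supplied.
#' @export
build_long_table <- function(scans, encounters, groups = NULL) {
  check_scan_table(scans)
  check_encounter_table(encounters)
  with_epoch <- scans |>
    dplyr::inner_join(
      dplyr::select(encounters, "participant_id", "encounter_id", "epoch",
                    "gestational_age"),
      by = c("participant_id", "encounter_id")
    )
  baseline <- with_epoch |>
    dplyr::filter(.data$epoch == "nonpregnant_baseline") |>
    dplyr::select("participant_id", "eye", dplyr::all_of(etdrs_sectors())) |>
    tidyr::pivot_longer(dplyr::all_of(etdrs_sectors()),
                        names_to = "sector", values_to = "baseline_um")

  no_baseline <- setdiff(
    unique(with_epoch$participant_id),
    unique(baseline$participant_id)
  )
  if (length(no_baseline) > 0) {
    warning(length(no_baseline), " participant(s) dropped from the long table",
            " (no baseline scan): ", paste(no_baseline, collapse = ", "))
  }

  long <- with_epoch |>
    dplyr::filter(.data$epoch != "nonpregnant_baseline") |>
    dplyr::group_by(.data$participant_id, .data$eye, .data$epoch) |>
    dplyr::arrange(.data$gestational_age, .data$encounter_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    tidyr::pivot_longer(dplyr::all_of(etdrs_sectors()),
                        names_to = "sector", values_to = "thickness_um") |>
    dplyr::inner_join(baseline, by = c("participant_id", "eye", "sector")) |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      eye = .data$eye,
      sector = .data$sector,
      epoch = factor(.data$epoch, levels = c("early", "mid", "delivery")),
      encounter_time = .data$gestational_age,
      change_from_baseline = .data$thickness_um - .data$baseline_um
    )
  if (!is.null(groups)) {
    long <- dplyr::inner_join(long, groups, by = "participant_id")
  }
  attr(long, "dropped_participants") <- no_baseline
  long
}

#' Hierarchical interval model of mean macular thickness change
#'
#' Fits a linear mixed-effects model to the change-from-baseline long table
#' with fixed effects for every (group x gestational interval) cell, random
#' intercepts at three nested levels -- participant, eye within participant,
#' ETDRS sector within eye -- and continuous-time AR(1) (exponential-decay)
#' serial correlation across encounters within each sector series.
#' Estimation is by REML through [nlme::lme()]; confidence intervals are
#' Wald intervals on the fixed effects.
#'
#' With `by_group = TRUE` the four cohort groups are estimated separately;
#' otherwise the HDP groups are pooled against controls (or a single pooled
#' cohort is fitted when no `group` column is present). Degenerate inputs
#' whose variance components vanish (e.g. noise-free simulations) fall back
#' to an ordinary least-squares cell-means fit with a warning.
#'
#' @param table Long tibble from [build_long_table()].
#' @param by_group Estimate each group separately (requires a `group`
#'   column).
#' @param correlation `"car1"` (default) or `"none"`.
#' @return An object of class `interval_fit` with elements `estimates`
#'   (tibble: `group`, `epoch`, `n_participants`, `mean`, `ci_lo`, `ci_hi`,
#'   `p_vs_baseline`), `contrasts` (epoch differences within group with
#'   p-values), `varcomp` (per-level standard deviations), `phi` (serial
#'   correlation at 1-week separation), `fit` (the underlying model) and
#'   `degenerate`.
#' @export
fit_interval_model <- function(table, by_group = FALSE,
                               correlation = c("car1", "none")) {
  correlation <- match.arg(correlation)
  stopifnot(all(c("participant_id", "eye", "sector", "epoch", "encounter_time",
                  "change_from_baseline") %in% names(table)))
  if (!all(is.finite(table$change_from_baseline))) {
    stop("non-finite change_from_baseline")
  }
  d <- tibble::as_tibble(table)
  if (by_group) {
    if (!"group" %in% names(d)) {
      stop("by_group = TRUE requires a 'group' column")
    }
    d$.group <- as.character(d$group)
  } else if ("group" %in% names(d)) {
    d$.group <- ifelse(d$group == "control", "control", "hdp")
  } else {
    d$.group <- "all"
  }
  d$.epoch <- factor(as.character(d$epoch), levels = c("early", "mid", "delivery"))
  if (any(is.na(d$.epoch))) {
    stop("epoch must be one of early, mid, delivery")
  }
  n_per_group <- d |>
    dplyr::distinct(.data$.group, .data$participant_id) |>
    dplyr::count(.data$.group)
  if (any(n_per_group$n < 2)) {
    stop("fewer than 2 participants in group ",
         n_per_group$.group[n_per_group$n < 2][1])
  }
  d$.cell <- factor(paste(d$.group, as.character(d$.epoch), sep = "|"))
  single_sector <- dplyr::n_distinct(d$sector) == 1

  ranef_formula <- if (single_sector) {
    change_from_baseline ~ 1 | participant_id / eye
  } else {
    change_from_baseline ~ 1 | participant_id / eye / sector
  }
  cor_struct <- if (correlation == "car1") {
    nlme::corCAR1(form = ~encounter_time)
  } else {
    NULL
  }

  degenerate <- FALSE
  cell_var <- tapply(d$change_from_baseline, d$.cell, stats::var)
  if (max(cell_var, na.rm = TRUE) < 1e-12) {
    warning("all variance components are zero; estimating cell means at the ",
            "variance boundary")
    degenerate <- TRUE
  }
  fit <- if (degenerate) {
    NULL
  } else {
    try_lme <- function(opt) {
      tryCatch(
        nlme::lme(
          fixed = change_from_baseline ~ 0 + .cell,
          random = ranef_formula,
          correlation = cor_struct,
          data = as.data.frame(d),
          method = "REML",
          control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                     opt = opt, returnObject = TRUE)
        ),
        error = function(e) e
      )
    }
    f <- try_lme("nlminb")
    if (inherits(f, "error")) f <- try_lme("optim")
    f
  }
  if (inherits(fit, "error")) {
    warning("mixed model could not be estimated (", conditionMessage(fit),
            "); falling back to an OLS cell-means fit at the variance boundary")
    degenerate <- TRUE
  }
  if (degenerate) {
    fit <- stats::lm(change_from_baseline ~ 0 + .cell, data = d)
  }

  if (degenerate) {
    ct <- suppressWarnings(summary(fit))$coefficients
    est <- ct[, "Estimate"]
    se <- ct[, "Std. Error"]
    df <- stats::df.residual(fit)
    pv <- ct[, "Pr(>|t|)"]
    vc <- tibble::tibble(
      level = c("participant", "eye", "sector", "residual"),
      sd = c(0, 0, 0, suppressWarnings(summary(fit))$sigma)
    )
    phi <- 0
    V <- suppressWarnings(stats::vcov(fit))
  } else {
    tt <- summary(fit)$tTable
    est <- tt[, "Value"]
    se <- tt[, "Std.Error"]
    df <- tt[, "DF"]
    pv <- tt[, "p-value"]
    vc_raw <- nlme::VarCorr(fit)
    sds <- suppressWarnings(as.numeric(vc_raw[, "StdDev"]))
    sds <- sds[!is.na(sds)]
    lv <- if (single_sector) c("participant", "eye", "residual") else
      c("participant", "eye", "sector", "residual")
    vc <- tibble::tibble(level = lv, sd = sds[seq_along(lv)])
    phi <- if (correlation == "car1") {
      unname(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE))
    } else {
      0
    }
    V <- stats::vcov(fit)
  }

  cells <- sub("^\\.cell", "", names(est))
  parts <- strsplit(cells, "|", fixed = TRUE)
  grp <- vapply(parts, `[`, "", 1)
  ep <- vapply(parts, `[`, "", 2)
  npart <- d |>
    dplyr::distinct(.data$.group, .data$participant_id) |>
    dplyr::count(.data$.group, name = "n_participants")
  qt_df <- if (length(df) == 1) rep(df, length(est)) else df
  estimates <- tibble::tibble(
    group = grp,
    epoch = factor(ep, levels = c("early", "mid", "delivery")),
    mean = unname(est),
    se = unname(se),
    ci_lo = unname(est - stats::qt(0.975, qt_df) * se),
    ci_hi = unname(est + stats::qt(0.975, qt_df) * se),
    p_vs_baseline = unname(pv)
  ) |>
    dplyr::left_join(npart, by = c(group = ".group")) |>
    dplyr::arrange(.data$group, .data$epoch)

  # epoch contrasts within group (Wald z on the fixed-effect covariance)
  contrasts <- purrr::map_dfr(unique(grp), function(g) {
    eps <- ep[grp == g]
    combn_eps <- utils::combn(sort(factor(eps, levels = c("early", "mid", "delivery"))), 2)
    purrr::map_dfr(seq_len(ncol(combn_eps)), function(j) {
      e1 <- as.character(combn_eps[1, j])
      e2 <- as.character(combn_eps[2, j])
      i1 <- which(grp == g & ep == e1)
      i2 <- which(grp == g & ep == e2)
      delta <- est[i2] - est[i1]
      sed <- sqrt(V[i1, i1] + V[i2, i2] - 2 * V[i1, i2])
      tibble::tibble(
        group = g, epoch_a = e1, epoch_b = e2,
        estimate = unname(delta), se = unname(sed),
        p_value = unname(2 * stats::pnorm(-abs(delta / sed)))
      )
    })
  })

  structure(
    list(
      estimates = estimates,
      contrasts = contrasts,
      varcomp = vc,
      phi = phi,
      fit = fit,
      by_group = by_group,
      correlation = correlation,
      degenerate = degenerate,
      nobs = nrow(d)
    ),
    class = "interval_fit"
  )
}

#' @export
print.interval_fit <- function(x, ...) {
  cat("Hierarchical interval model of macular thickness change (um)\n")
  if (x$degenerate) {
    cat("(degenerate fit: OLS cell means at the variance boundary)\n")
  }
  print(x$estimates)
  cat(sprintf("Serial correlation at 1 week: %.3f\n", x$phi))
  invisible(x)
}

#' Tidy an interval model fit
#'
#' @param x An `interval_fit` object.
#' @param effects `"means"` (per group x epoch estimates) or `"contrasts"`
#'   (epoch differences within group).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.interval_fit <- function(x, effects = c("means", "contrasts"), ...) {
  effects <- match.arg(effects)
  if (effects == "means") x$estimates else x$contrasts
}

#' @rdname tidy.interval_fit
#' @return `glance()`: a one-row model summary.
#' @export
glance.interval_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$nobs,
    sigma = x$varcomp$sd[x$varcomp$level == "residual"],
    sd_participant = x$varcomp$sd[x$varcomp$level == "participant"],
    sd_eye = x$varcomp$sd[x$varcomp$level == "eye"],
    sd_sector = if ("sector" %in% x$varcomp$level) {
      x$varcomp$sd[x$varcomp$level == "sector"]
    } else {
      NA_real_
    },
    phi = x$phi,
    logLik = if (x$degenerate) as.numeric(stats::logLik(x$fit)) else
      as.numeric(x$fit$logLik),
    degenerate = x$degenerate
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
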