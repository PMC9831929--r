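# polar layout of the ETDRS grid used by plot_sector_map(): the central disc,
# then inner/outer quadrant annuli. Angles in degrees, temporal on the left
# (right-eye convention; purely presentational).
etdrs_layout <- function() {
  quad <- function(prefix, rmin, rmax) {
    tibble::tibble(
      sector = paste0(prefix, c("S", "T", "I", "N")),
      tmin = c(-45, 45, 135, 225), tmax = c(45, 135, 225, 315),
      rmin = rmin, rmax = rmax
    )
  }
  dplyr::bind_rows(
    tibble::tibble(sector = "C", tmin = -45, tmax = 315, rmin = 0, rmax = 0.5),
    quad("I", 0.5, 1.5),
    quad("O", 1.5, 3)
  )
}

#' Plot a sector map or difference map on the ETDRS grid
#'
#' Schematic polar rendering of nine per-sector values (thicknesses or
#' interval differences, um) on the ETDRS layout. Diverging maps (any
#' negative value, e.g. interval changes) are coloured blue-to-red around
#' zero.
#'
#' @param values Named numeric vector over the nine sectors.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
#' @examples
#' d <- stats::setNames(c(0, rep(-5, 4), rep(-2, 4)), etdrs_sectors())
#' plot_sector_map(d, "Interval change (um)")
plot_sector_map <- function(values, title = NULL) {
  values <- complete_sector_vector(values)
  d <- etdrs_layout() |>
    dplyr::mutate(value = values[.data$sector],
                  mid_t = (.data$tmin + .data$tmax) / 2,
                  mid_r = (.data$rmin + .data$rmax) / 2)
  p <- ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$tmin, xmax = .data$tmax,
      ymin = .data$rmin, ymax = .data$rmax, fill = .data$value
    ), colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      x = .data$mid_t, y = .data$mid_r,
      label = sprintf("%s\n%.1f", .data$sector, .data$value)
    ), size = 2.8) +
    ggplot2::coord_polar(theta = "x", start = -pi / 4) +
    ggplot2::scale_x_continuous(limits = c(-45, 315)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = title, fill = "um")
  if (any(values < 0)) {
    p <- p + ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                           high = "firebrick", midpoint = 0)
  }
  p
}

#' Plot interval model estimates
#'
#' Point estimates with 95% confidence intervals for the mean change in
#' macular thickness from the non-pregnant baseline, by gestational
#' interval and cohort group.
#'
#' @param object An `interval_fit` from [fit_interval_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interval_fit <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(
    x = .data$epoch, y = .data$mean, colour = .data$group, group = .data$group
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      position = ggplot2::position_dodge(width = 0.3)
    ) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(
      x = "Gestational interval",
      y = "Change in macular thickness from non-pregnant baseline (um)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the empirical null calibration surface
#'
#' Firing frequency of every weaker rule (tau', k') over the null
#' same-encounter pairs; the frequency is monotone non-increasing in both
#' the threshold and the contiguity count.
#'
#' @param object A `null_calibration` from [calibrate_null()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.null_calibration <- function(object, ...) {
  ggplot2::ggplot(object$freq, ggplot2::aes(
    x = .data$k, y = .data$freq, colour = factor(.data$tau),
    group = .data$tau
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = 1:9) +
    ggplot2::labs(
      x = "Minimum contiguous sector count k",
      y = "Null firing frequency (either direction)",
      colour = "Threshold tau (um)"
    ) +
    ggplot2::theme_minimal()
}
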