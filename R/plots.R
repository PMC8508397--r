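#' Plot a daily UVI profile against its clear-sky reference
#'
#' @param uvi A UVI series tibble (one day).
#' @param reference Optional clear-sky reference from
#'   [daily_clearsky_profile()].
#' @param station Optional [uv_station()]; when given, the x axis shows
#'   station-local civil time.
#' @return A ggplot object.
#' @export
plot_daily_profile <- function(uvi, reference = NULL, station = NULL) {
  assert_uvi_series(uvi)
  shift <- if (is.null(station)) 0 else station$utc_offset * 3600
  p <- ggplot2::ggplot(uvi, ggplot2::aes(x = .data$timestamp + shift,
                                         y = .data$uvi)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = if (is.null(station)) "time (UTC)" else "local time",
                  y = "UVI")
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_line(
      data = reference,
      ggplot2::aes(x = .data$timestamp + shift, y = .data$uvi_cs),
      colour = "grey40", linetype = 2
    )
  }
  p
}

#' Plot a mean diurnal cycle
#'
#' @param cycle Output of [diurnal_cycle()].
#' @param value Which column to draw (`"mean"` or `"count"`).
#' @return A ggplot object.
#' @export
plot_diurnal_cycle <- function(cycle, value = c("mean", "count")) {
  value <- match.arg(value)
  ggplot2::ggplot(cycle, ggplot2::aes(x = .data$minute_of_day / 60,
                                      y = .data[[value]])) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "local hour of day", y = value)
}

#' Plot a monthly climatology as a box-and-whisker summary
#'
#' @param clim Output of [monthly_climatology()].
#' @return A ggplot object.
#' @export
plot_monthly_climatology <- function(clim) {
  present <- clim[clim$n > 0, ]
  out <- tidyr::unnest(present[, c("month", "outliers")], "outliers")
  ggplot2::ggplot(present, ggplot2::aes(x = factor(.data$month))) +
    ggplot2::geom_boxplot(
      ggplot2::aes(ymin = .data$whisker_low, lower = .data$q25,
                   middle = .data$median, upper = .data$q75,
                   ymax = .data$whisker_high),
      stat = "identity", fill = "lightsteelblue"
    ) +
    ggplot2::geom_point(data = out,
                        ggplot2::aes(x = factor(.data$month),
                                     y = .data$outliers), shape = 1) +
    ggplot2::labs(x = "month", y = "value")
}

#' Plot daily dose accumulation against phototype thresholds
#'
#' @param doses Output of [cumulative_sed()] for one day.
#' @param thresholds A [fitzpatrick_thresholds()] table (rows to draw).
#' @param station Optional [uv_station()] for a local-time axis.
#' @return A ggplot object.
#' @export
plot_cumulative_dose <- function(doses, thresholds = fitzpatrick_thresholds(),
                                 station = NULL) {
  shift <- if (is.null(station)) 0 else station$utc_offset * 3600
  ggplot2::ggplot(doses, ggplot2::aes(x = .data$window_start + shift,
                                      y = .data$csed)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(data = thresholds,
                        ggplot2::aes(yintercept = .data$threshold_sed),
                        linetype = 3, colour = "firebrick") +
    ggplot2::labs(x = if (is.null(station)) "time (UTC)" else "local time",
                  y = "cumulative dose (SED)")
}

#' Scatter plot of matched ground and estimate UVI
#'
#' @param object A `uv_comparison` from [compare_pairs()].
#' @param ... Unused.
#' @return A ggplot object with the identity line.
#' @method autoplot uv_comparison
#' @export
autoplot.uv_comparison <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$ground_uvi, y = .data$estimate_uvi)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ground UVI", y = "estimate UVI")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
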