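#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a mass trace
#'
#' Buoyant mass against time, with optional division/annotation marks.
#'
#' @param object A `mass_trace` (or any tibble with `time_min`, `mass_pg`).
#' @param annotation Optional cycle annotation whose event times are drawn
#'   as dashed verticals.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mass_trace <- function(object, annotation = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$time_min / 60, .data$mass_pg)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "time (hr)", y = "buoyant mass (pg)")
  if (!is.null(annotation)) {
    ev <- c(annotation$t_g2m_min, annotation$t_ma_min,
            annotation$t_abscission_min) / 60
    p <- p + ggplot2::geom_vline(xintercept = ev, linetype = "dashed",
                                 colour = "steelblue")
  }
  p
}

#' Plot sliding-window MAR/mass
#'
#' @param object A `mar_windows` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mar_windows <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_center_min / 60,
                                       .data$mar_per_mass_per_hr)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "time (hr)", y = "MAR/mass (1/hr)")
}

#' Plot an aligned ensemble with its dispersion band
#'
#' Mean MAR/mass over relative time with an SD or SEM ribbon.
#'
#' @param object An `ensemble_grid`.
#' @param band `"sd"` or `"sem"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ensemble_grid <- function(object, band = c("sd", "sem"), ...) {
  band <- match.arg(band)
  half <- if (band == "sd") object$sd else object$sem
  df <- tibble::as_tibble(object)
  df$lo <- df$mean - half
  df$hi <- df$mean + half
  ggplot2::ggplot(df, ggplot2::aes(.data$rel_time_min, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time relative to M/A transition (min)",
                  y = "MAR/mass (1/hr)")
}
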