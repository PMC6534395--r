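#' Synthesize the raw frequency record of one cell transit
#'
#' Models a transit through the second-bending-mode SMR: the cell enters at
#' the cantilever base, travels at constant speed along the embedded
#' channel to the U-turn at the interior displacement node, and returns.
#' The instantaneous frequency shift is the mode-shape-squared weighting of
#' the cell's (possibly extended) axial mass distribution, normalised so a
#' point mass at the interior measurement antinode produces a shift of
#' `-mass / pg_per_hz`. A point-mass transit therefore shows two equal
#' minima (the two antinode crossings) separated by a near-zero node
#' region -- the morphology [detect_transits()] expects. An extended cell's
#' minima are shallower by its bias factor (see [bias_factor()]).
#'
#' @param mass_pg Buoyant mass of the particle, pg.
#' @param geom Optional `cell_geometry` (default: point mass).
#' @param baseline_hz Resonant-frequency baseline (typical ~1.1 MHz).
#' @param pg_per_hz Calibration factor, pg/Hz.
#' @param data_rate_hz Sampling rate (typical ~3000 Hz).
#' @param transit_s Total transit duration, seconds (typical ~0.3 s).
#' @param t_start Time of channel entry, seconds.
#' @param pad_s Flat baseline emitted on each side of the transit.
#' @param noise_sd_hz Additive white frequency noise SD, Hz.
#' @param node_dev_pg Injected node-deviation amplitude, pg-equivalent
#'   (signed); adds a narrow bump at the node crossing.
#' @param L_cant_um Cantilever length, micrometres.
#' @return Tibble with `time_s`, `frequency_hz`.
#' @export
generate_raw_peaks <- function(mass_pg, geom = NULL, baseline_hz = 1.1e6,
                               pg_per_hz = 25, data_rate_hz = 3000,
                               transit_s = 0.3, t_start = 0, pad_s = 0.3,
                               noise_sd_hz = 0, node_dev_pg = 0,
                               L_cant_um = 350) {
  stopifnot(mass_pg >= 0, pg_per_hz > 0, transit_s > 0)
  dt <- 1 / data_rate_hz
  tt <- seq(t_start - pad_s, t_start + transit_s + pad_s, by = dt)
  shift <- .transit_shift(tt - t_start, mass_pg, geom, pg_per_hz,
                          transit_s, node_dev_pg, L_cant_um)
  f <- baseline_hz + shift
  if (noise_sd_hz > 0) f <- f + stats::rnorm(length(f), 0, noise_sd_hz)
  tibble::tibble(time_s = tt, frequency_hz = f)
}

# frequency shift (Hz) at times `tau` (0 = entry) for one transit
.transit_shift <- function(tau, mass_pg, geom, pg_per_hz, transit_s,
                           node_dev_pg, L_cant_um) {
  xi_node <- smr_node_position()
  xi_meas <- smr_antinode_position()
  u2_meas <- mode_shape(xi_meas)^2
  shift <- numeric(length(tau))
  inside <- tau >= 0 & tau <= transit_s
  if (!any(inside)) return(shift)
  # triangular path: base -> node -> base at constant speed
  prog <- tau[inside] / transit_s
  xi_c <- xi_node * (1 - abs(2 * prog - 1))
  if (is.null(geom)) {
    w2 <- mode_shape(xi_c)^2 / u2_meas
  } else {
    dens <- line_density(geom, n = 201)
    s_um <- dens$s
    wgt <- dens$density
    wtrap <- wgt * (c(diff(s_um), 0) + c(0, diff(s_um))) / 2
    w2 <- vapply(xi_c, function(x) {
      xi_pts <- pmin(pmax(x + s_um / L_cant_um, 0), 1)
      sum(wtrap * mode_shape(xi_pts)^2) / u2_meas
    }, numeric(1))
  }
  shift[inside] <- -mass_pg / pg_per_hz * w2
  if (node_dev_pg != 0) {
    # narrow Gaussian bump in xi around the node crossing
    bump <- exp(-((xi_c - xi_node) / 0.04)^2)
    shift[inside] <- shift[inside] + node_dev_pg / pg_per_hz * bump
  }
  shift
}

#' Synthesize a full raw frequency record with scheduled transits
#'
#' Flat baseline with one transit per row of `schedule`, plus optional
#' white noise; used to exercise the full detection/calibration path on a
#' record with known ground truth.
#'
#' @param schedule Tibble with `t_s` (entry times) and `mass_pg`; optional
#'   `node_dev_pg` column.
#' @param duration_s Total record length, seconds.
#' @param noise_sd_hz Additive white noise SD, Hz.
#' @inheritParams generate_raw_peaks
#' @return Tibble with `time_s`, `frequency_hz`.
#' @export
generate_raw_signal <- function(schedule, duration_s, baseline_hz = 1.1e6,
                                pg_per_hz = 25, data_rate_hz = 3000,
                                transit_s = 0.3, noise_sd_hz = 0,
                                L_cant_um = 350) {
  stopifnot(is.data.frame(schedule),
            all(c("t_s", "mass_pg") %in% names(schedule)))
  tt <- seq(0, duration_s, by = 1 / data_rate_hz)
  f <- rep(baseline_hz, length(tt))
  nd <- if ("node_dev_pg" %in% names(schedule)) schedule$node_dev_pg
        else rep(0, nrow(schedule))
  for (k in seq_len(nrow(schedule))) {
    sel <- tt >= schedule$t_s[k] - 0.01 &
      tt <= schedule$t_s[k] + transit_s + 0.01
    f[sel] <- f[sel] + .transit_shift(
      tt[sel] - schedule$t_s[k], schedule$mass_pg[k], NULL, pg_per_hz,
      transit_s, nd[k], L_cant_um
    )
  }
  if (noise_sd_hz > 0) f <- f + stats::rnorm(length(f), 0, noise_sd_hz)
  tibble::tibble(time_s = tt, frequency_hz = f)
}
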