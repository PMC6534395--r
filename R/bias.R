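#' Buoyant-mass measurement bias of an extended cell
#'
#' A point mass at the measurement antinode shifts the resonant frequency in
#' proportion to its mass times the squared mode displacement there. A cell
#' of finite axial extent averages the squared displacement over its mass
#' distribution, so its apparent mass is reduced by the factor
#' `kappa <= 1` computed here:
#' `kappa = max over centroid position of integral(density(s) *
#'  u(xi_c + s / L)^2 ds) / u(xi_meas)^2`.
#' The maximisation over the centroid position mirrors the instrument
#' reporting the extremal frequency shift attained during the transit.
#'
#' @param density A `line_density` object from [line_density()].
#' @param L_cant Cantilever length, micrometres.
#' @param xi_meas Fractional position of the measurement antinode; defaults
#'   to the interior antinode of the second mode (see
#'   [smr_antinode_position()]).
#' @return Scalar `kappa` in (0, 1].
#' @examples
#' g <- geometry_at(512, t_ma = 500, tau_e = 12, R = 6)
#' bias_factor(line_density(g), L_cant = 350)
#' @export
bias_factor <- function(density, L_cant, xi_meas = smr_antinode_position()) {
  stopifnot(inherits(density, "line_density"), L_cant > 0)
  ell <- attr(density, "ell")
  if (ell / L_cant > 0.2) {
    warning("cell extent exceeds 20% of the cantilever length; ",
            "the small-cell bias model is inaccurate", call. = FALSE)
  }
  half <- ell / 2 / L_cant
  if (half >= xi_meas || half >= 1 - xi_meas) {
    stop("cell does not fit on the cantilever around the antinode",
         call. = FALSE)
  }
  s <- density$s
  w <- density$density
  u2_meas <- mode_shape(xi_meas)^2
  kappa_at <- function(xi_c) {
    .trapz(s, w * mode_shape(xi_c + s / L_cant)^2) / u2_meas
  }
  lo <- max(half, xi_meas - 0.1)
  hi <- min(1 - half, xi_meas + 0.1)
  opt <- stats::optimize(kappa_at, c(lo, hi), maximum = TRUE, tol = 1e-10)
  # the antinode itself is always a candidate; guard optimize() misses
  max(opt$objective, kappa_at(xi_meas))
}

#' Relative elongation-bias schedule over cytokinesis
#'
#' Tabulates the relative bias factor `kappa_rel(t) = kappa(t) / kappa_sphere`
#' on `[t_ma, t_abscission]`. The single-sphere bias is divided out because
#' the bead calibration of the instrument already absorbs the finite-size
#' bias of a round cell; `kappa_rel` is exactly 1 before elongation starts
#' and decreases as the cell elongates into a doublet.
#'
#' @param t_min Numeric vector of times (minutes) at which to evaluate the
#'   schedule; values outside `[t_ma, t_ma + tau_e]` are handled by the
#'   constant sphere/doublet limits.
#' @param t_ma M/A transition time, minutes.
#' @param tau_e Elongation duration, minutes (default 12, L1210).
#' @param R Equivalent-sphere radius of the round cell, micrometres.
#' @param L_cant Cantilever length, micrometres (instrument-specific).
#' @param xi_meas Measurement antinode position, fractional.
#' @return A tibble of class `bias_schedule` with columns `t_min` and
#'   `kappa_rel`.
#' @export
bias_schedule <- function(t_min, t_ma, tau_e = 12, R, L_cant = 350,
                          xi_meas = smr_antinode_position()) {
  stopifnot(is.numeric(t_min), tau_e > 0, R > 0)
  k_sphere <- bias_factor(
    line_density(geometry_at(t_ma, t_ma, tau_e, R)), L_cant, xi_meas
  )
  # kappa is constant once elongation is complete: evaluate each distinct
  # clamped time once
  t_clamp <- pmin(pmax(t_min, t_ma), t_ma + tau_e)
  uniq <- unique(t_clamp)
  k_uniq <- vapply(uniq, function(t) {
    if (t <= t_ma) return(1)
    g <- geometry_at(t, t_ma, tau_e, R)
    bias_factor(line_density(g), L_cant, xi_meas) / k_sphere
  }, numeric(1))
  kappa_rel <- k_uniq[match(t_clamp, uniq)]
  out <- tibble::tibble(t_min = t_min, kappa_rel = kappa_rel)
  class(out) <- c("bias_schedule", class(out))
  out
}

#' Convert buoyant mass to an equivalent-sphere radius
#'
#' Buoyant mass is the cell volume times the density contrast between the
#' cell and the surrounding medium; inverting with a configured contrast
#' gives the volume and hence the round-cell radius used by the geometry
#' model. The default contrast of 75 kg/m^3 is a configuration choice, not
#' measured biology.
#'
#' @param mass_pg Buoyant mass, picograms.
#' @param density_contrast Cell-medium density contrast, kg/m^3.
#' @return Radius in micrometres.
#' @export
mass_to_radius <- function(mass_pg, density_contrast = 75) {
  stopifnot(all(mass_pg > 0), density_contrast > 0)
  V_um3 <- mass_pg / density_contrast * 1e3 # pg / (kg m^-3) = 1e3 um^3
  (3 * V_um3 / (4 * pi))^(1 / 3)
}

#' Correct a mass trace for the cytokinetic elongation bias
#'
#' Elongated cells register lighter than round cells of equal mass because
#' their mass is spread along the cantilever axis. Between the M/A
#' transition and abscission the measured mass is divided by the relative
#' bias factor `kappa_rel(t)`; points outside that interval are unchanged.
#'
#' @param trace A mass trace tibble (columns `time_min`, `mass_pg`, ...).
#' @param annotation A one-row cycle annotation (columns `t_ma_min`,
#'   `t_abscission_min`, `tau_e_min`), e.g. from [annotate_cycle()].
#' @param schedule Optional precomputed [bias_schedule()]; when `NULL` one is
#'   computed from the trace, with the round-cell radius taken from the
#'   median mass over the 10 min preceding the M/A transition.
#' @param L_cant,density_contrast,xi_meas Instrument/model configuration,
#'   used only when `schedule` is `NULL`.
#' @return The trace with `mass_pg` replaced by the corrected mass and the
#'   applied factor in column `kappa_rel`.
#' @export
correct_trace <- function(trace, annotation, schedule = NULL,
                          L_cant = 350, density_contrast = 75,
                          xi_meas = smr_antinode_position()) {
  stopifnot(is.data.frame(trace), all(c("time_min", "mass_pg") %in% names(trace)))
  t_ma <- annotation$t_ma_min[1]
  t_ab <- annotation$t_abscission_min[1]
  tau_e <- annotation$tau_e_min[1]
  # strict upper bound: the sample at the detected abscission time is the
  # first (round) daughter measurement and carries no elongation bias
  in_ck <- trace$time_min > t_ma & trace$time_min < t_ab
  if (is.null(schedule)) {
    pre <- trace$mass_pg[trace$time_min <= t_ma &
                           trace$time_min >= t_ma - 10]
    if (length(pre) == 0) pre <- trace$mass_pg[trace$time_min <= t_ma]
    R <- mass_to_radius(stats::median(pre), density_contrast)
    schedule <- bias_schedule(
      sort(unique(trace$time_min[in_ck])), t_ma, tau_e, R, L_cant, xi_meas
    )
  }
  kr <- rep(1, nrow(trace))
  if (any(in_ck)) {
    kr[in_ck] <- stats::approx(
      schedule$t_min, schedule$kappa_rel, xout = trace$time_min[in_ck],
      rule = 2
    )$y
  }
  if (any(kr <= 0)) stop("non-positive bias factor", call. = FALSE)
  out <- trace
  out$mass_pg <- trace$mass_pg / kr
  out$kappa_rel <- kr
  out
}
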