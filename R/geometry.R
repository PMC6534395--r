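#' Cell geometry during cytokinetic elongation
#'
#' A dividing cell is modelled as a sphere before anaphase, two overlapping
#' equal spheres while it elongates, and a touching spherical doublet once
#' elongation is over. Total volume is conserved throughout: at every centre
#' separation `d` the sub-sphere radius `r` solves
#' `V_union(r, d) = 4/3 * pi * R^3`, where `R` is the equivalent-sphere
#' radius of the round cell.
#'
#' The centre separation ramps linearly from 0 at the metaphase-to-anaphase
#' (M/A) transition to `2 * r_final` at `t_ma + tau_e` (end of elongation) and
#' stays constant afterwards.
#'
#' @param t Time (minutes) at which to evaluate the geometry.
#' @param t_ma M/A transition time (minutes).
#' @param tau_e Elongation (anaphase) duration in minutes; 12 for L1210.
#' @param R Equivalent-sphere radius of the round cell, micrometres.
#' @return An object of class `cell_geometry`: a list with `stage`
#'   (`"sphere"`, `"overlapping"` or `"doublet"`), `R`, `r`, `d` (micrometres).
#' @examples
#' geometry_at(506, t_ma = 500, tau_e = 12, R = 5.5)
#' @export
geometry_at <- function(t, t_ma, tau_e, R) {
  stopifnot(length(t) == 1, is.finite(t), tau_e > 0, R > 0)
  if (t < t_ma) {
    stop("`t` must not precede the M/A transition", call. = FALSE)
  }
  r_final <- R * 2^(-1 / 3)
  d_final <- 2 * r_final
  frac <- min(1, (t - t_ma) / tau_e)
  d <- frac * d_final
  if (d <= 0) {
    geom <- list(stage = "sphere", R = R, r = R, d = 0)
  } else if (frac >= 1) {
    geom <- list(stage = "doublet", R = R, r = r_final, d = d_final)
  } else {
    V <- 4 / 3 * pi * R^3
    r <- stats::uniroot(
      function(r) sphere_union_volume(r, d) - V,
      lower = r_final * (1 - 1e-9), upper = R * (1 + 1e-9), tol = 1e-12
    )$root
    geom <- list(stage = "overlapping", R = R, r = r, d = d)
  }
  structure(geom, class = "cell_geometry")
}

#' Union volume of two equal spheres
#'
#' Volume of the union of two spheres of radius `r` whose centres are `d`
#' apart (`0 <= d <= 2r`), using the closed-form lens (overlap) volume
#' `pi/12 * (4r + d) * (2r - d)^2`.
#'
#' @param r Sphere radius.
#' @param d Centre separation, `0 <= d <= 2r`.
#' @return Union volume in the cube of the unit of `r`.
#' @export
sphere_union_volume <- function(r, d) {
  stopifnot(all(d >= 0), all(d <= 2 * r + 1e-12))
  lens <- pi / 12 * (4 * r + d) * pmax(2 * r - d, 0)^2
  2 * (4 / 3) * pi * r^3 - lens
}

#' Normalised axial line density of a cell geometry
#'
#' Cross-sectional area of the (coaxial) sphere-union as a function of axial
#' position, normalised to integrate to 1. This is the mass distribution the
#' cantilever "sees" along its axis when the cell's long axis is aligned with
#' the channel.
#'
#' @param geom A `cell_geometry` object from [geometry_at()].
#' @param n Number of grid points used to tabulate the density.
#' @return A tibble with columns `s` (axial offset from the cell centroid,
#'   micrometres) and `density` (1/micrometre), with attributes `ell` (total
#'   axial extent) carried for downstream quadrature. Class `line_density`.
#' @export
line_density <- function(geom, n = 1001) {
  stopifnot(inherits(geom, "cell_geometry"))
  r <- geom$r
  d <- geom$d
  ell <- d + 2 * r
  s <- seq(-ell / 2, ell / 2, length.out = n)
  # disc area (over pi) under each sub-sphere; union = max because coaxial
  a1 <- pmax(r^2 - (s + d / 2)^2, 0)
  a2 <- pmax(r^2 - (s - d / 2)^2, 0)
  area <- pmax(a1, a2)
  z <- .trapz(s, area)
  out <- tibble::tibble(s = s, density = area / z)
  attr(out, "ell") <- ell
  class(out) <- c("line_density", class(out))
  out
}

# trapezoidal rule on an ordered grid
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
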