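#' Second flexural bending mode of a clamped-free cantilever
#'
#' Displacement of an Euler--Bernoulli clamped-free beam vibrating in its
#' second flexural bending mode, as a function of the fractional position
#' `xi` along the beam (0 = clamped base, 1 = free tip). The shape is
#' normalised so that the largest absolute displacement on `[0, 1]` (at the
#' free tip for this mode) equals 1.
#'
#' The second mode has one interior displacement node; a particle flowing
#' along the embedded channel therefore produces two frequency minima per
#' transit (one per antinode pass) separated by a near-zero node region.
#'
#' @param xi Numeric vector of fractional positions in `[0, 1]`.
#' @return Numeric vector of signed displacements, `max(abs(u)) == 1`.
#' @examples
#' mode_shape(c(0, smr_node_position(), 1))
#' @export
mode_shape <- function(xi) {
  if (any(!is.finite(xi)) || any(xi < 0) || any(xi > 1)) {
    stop("`xi` must lie in [0, 1]", call. = FALSE)
  }
  .beam_bracket(xi) / .beam_norm()
}

# clamped-free mode-2 eigenvalue and modal constant
.beam_lambda2 <- 4.69409113
.beam_sigma <- (cosh(.beam_lambda2) - cos(.beam_lambda2)) /
  (sinh(.beam_lambda2) + sin(.beam_lambda2))

.beam_bracket <- function(xi) {
  l <- .beam_lambda2
  cosh(l * xi) - cos(l * xi) - .beam_sigma * (sinh(l * xi) - sin(l * xi))
}

# normalisation constant: max |bracket| on [0, 1]; attained at the free end
.beam_norm_cache <- new.env(parent = emptyenv())
.beam_norm <- function() {
  if (is.null(.beam_norm_cache$N)) {
    xg <- seq(0, 1, length.out = 20001)
    .beam_norm_cache$N <- max(abs(.beam_bracket(xg)))
  }
  .beam_norm_cache$N
}

#' Interior displacement node of the second bending mode
#'
#' Fractional position `xi` at which the second-mode displacement crosses
#' zero in the interior of the beam (approximately 0.783 for a clamped-free
#' cantilever). The "node deviation" signal of an SMR is recorded while the
#' cell sits at this position.
#'
#' @return Scalar fractional position in (0, 1).
#' @export
smr_node_position <- function() {
  if (is.null(.beam_norm_cache$node)) {
    .beam_norm_cache$node <- stats::uniroot(
      .beam_bracket, c(0.5, 0.95), tol = 1e-12
    )$root
  }
  .beam_norm_cache$node
}

#' Interior measurement antinode of the second bending mode
#'
#' Fractional position of the interior displacement antinode (approximately
#' 0.470), i.e. the extremum of `|u|` between the base and the interior node.
#' The fluid channel turns around at the node, so a transiting cell crosses
#' this antinode twice; the per-transit mass readout is normalised here.
#'
#' @return Scalar fractional position in (0, 1).
#' @export
smr_antinode_position <- function() {
  if (is.null(.beam_norm_cache$antinode)) {
    .beam_norm_cache$antinode <- stats::optimize(
      function(x) abs(.beam_bracket(x)),
      c(0.05, smr_node_position()), maximum = TRUE, tol = 1e-12
    )$maximum
  }
  .beam_norm_cache$antinode
}
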