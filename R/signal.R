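#' Refine a frequency minimum with a quartic fit
#'
#' Least-squares fit of a fourth-order polynomial to a short window of raw
#' samples around a discrete minimum; the refined minimum is the interior
#' minimiser of the fitted polynomial over the window's time span. When the
#' fitted polynomial has no interior minimum the discrete minimum is
#' returned and flagged unrefined.
#'
#' @param t,f Numeric vectors: sample times (seconds) and frequencies (Hz)
#'   of the window; at least 7 samples bracketing a discrete minimum.
#' @return A list with `t_min`, `f_min` and logical `refined`.
#' @export
refine_minimum <- function(t, f) {
  stopifnot(length(t) == length(f), length(t) >= 7)
  i0 <- which.min(f)
  if (i0 == 1 || i0 == length(f)) {
    stop("window does not bracket a discrete minimum", call. = FALSE)
  }
  # centre and scale for conditioning
  tc <- mean(t)
  sc <- max(t) - min(t)
  x <- (t - tc) / sc
  fit <- stats::lm(f ~ x + I(x^2) + I(x^3) + I(x^4))
  b <- stats::coef(fit)
  b[is.na(b)] <- 0
  # critical points: roots of the derivative cubic b1 + 2 b2 x + 3 b3 x^2 + 4 b4 x^3
  dcoef <- c(b[2], 2 * b[3], 3 * b[4], 4 * b[5])
  if (all(abs(dcoef[-1]) < 1e-300)) {
    return(list(t_min = t[i0], f_min = f[i0], refined = FALSE))
  }
  rts <- polyroot(dcoef[1:max(which(abs(dcoef) > 0))])
  re <- Re(rts)[abs(Im(rts)) < 1e-8 * (1 + abs(Re(rts)))]
  re <- re[re > min(x) & re < max(x)]
  if (length(re) == 0) {
    return(list(t_min = t[i0], f_min = f[i0], refined = FALSE))
  }
  pv <- function(x) b[1] + b[2] * x + b[3] * x^2 + b[4] * x^3 + b[5] * x^4
  # second derivative to keep only local minima
  d2 <- function(x) 2 * b[3] + 6 * b[4] * x + 12 * b[5] * x^2
  mins <- re[d2(re) > 0]
  if (length(mins) == 0) {
    return(list(t_min = t[i0], f_min = f[i0], refined = FALSE))
  }
  best <- mins[which.min(pv(mins))]
  list(t_min = tc + best * sc, f_min = unname(pv(best)), refined = TRUE)
}

#' Detect cell transits in a raw resonance-frequency record
#'
#' Locates transit peaks -- each containing two local frequency minima (one
#' per antinode pass of the second bending mode) separated by a node region
#' -- in a raw `(time_s, frequency_hz)` record. The baseline is estimated
#' with a running median that is robust to the dips; candidate samples are
#' those deviating below the baseline by more than `threshold_hz`
#' (default: 5 times the median absolute deviation of the baseline-subtracted
#' signal). Nearby below-threshold segments are merged into one transit and
#' each minimum is refined with [refine_minimum()].
#'
#' Transits in which two minima cannot be established are dropped (the
#' number dropped is reported via the `dropped` attribute); no other
#' exclusion is applied.
#'
#' @param trace Data frame with columns `time_s` (strictly increasing) and
#'   `frequency_hz`.
#' @param baseline_window_s Width (seconds) of the running-median baseline
#'   window.
#' @param threshold_hz Detection threshold below baseline, Hz; `NULL` for
#'   the 5-MAD automatic choice.
#' @param merge_gap_s Below-threshold segments closer than this are one
#'   transit (covers the node region between the two dips).
#' @param refine_halfwidth Samples on each side of a discrete minimum used
#'   for the quartic refinement; the default (60, i.e. +/-20 ms at 3 kHz)
#'   matches the width of the antinode-crossing dip of a ~300 ms node-turn
#'   transit, averaging enough samples to keep the fitted minimum unbiased
#'   at realistic frequency noise.
#' @return A tibble with one row per transit: `t_enter`, `t_exit`,
#'   `baseline_hz`, `t_min1`, `min1_shift_hz`, `t_min2`, `min2_shift_hz`,
#'   `node_shift_hz`, `refined1`, `refined2`.
#' @export
detect_transits <- function(trace, baseline_window_s = 2,
                            threshold_hz = NULL, merge_gap_s = 0.2,
                            refine_halfwidth = 60) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "frequency_hz") %in% names(trace)))
  t <- trace$time_s
  f <- trace$frequency_hz
  bad <- which(!is.finite(t) | !is.finite(f))
  if (length(bad) > 0) {
    stop("non-finite samples at indices: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  if (any(diff(t) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  dt <- stats::median(diff(t))
  win <- round(baseline_window_s / dt)
  if (length(t) < win || win < 3) stop("insufficient baseline", call. = FALSE)
  win <- win + (win + 1) %% 2 # odd
  base1 <- stats::runmed(f, win, endrule = "median")
  dev <- f - base1
  sigma <- stats::mad(dev)
  thr <- if (is.null(threshold_hz)) 5 * sigma else threshold_hz
  if (thr <= 0) thr <- 1e-12
  below <- dev < -thr
  if (!any(below)) {
    out <- .empty_transits()
    attr(out, "dropped") <- 0L
    return(out)
  }
  segs <- .runs(below)
  # merge segments separated by less than merge_gap_s
  merged <- list()
  cur <- segs[[1]]
  for (sg in segs[-1]) {
    if (t[sg[1]] - t[cur[2]] < merge_gap_s) cur[2] <- sg[2]
    else {
      merged[[length(merged) + 1]] <- cur
      cur <- sg
    }
  }
  merged[[length(merged) + 1]] <- cur

  pad <- max(3L, round(0.05 / dt))
  rows <- list()
  dropped <- 0L
  for (sg in merged) {
    i1 <- max(1L, sg[1] - pad)
    i2 <- min(length(t), sg[2] + pad)
    idx <- i1:i2
    d <- dev[idx]
    lm_idx <- .local_minima(d)
    lm_idx <- lm_idx[d[lm_idx] < -thr]
    if (length(lm_idx) < 2) { dropped <- dropped + 1L; next }
    # second-mode physics: exactly two antinode passes separated by the node
    # region, where the signal recovers toward baseline. Keep the deepest
    # minimum, then the deepest other minimum from which it is separated by
    # an interior maximum recovering at least half of the deeper dip.
    first <- lm_idx[which.min(d[lm_idx])]
    depth <- d[first]
    cand <- lm_idx[lm_idx != first]
    recov <- vapply(cand, function(j) {
      if (abs(j - first) < 2) return(-Inf)
      max(d[(min(j, first) + 1):(max(j, first) - 1)])
    }, numeric(1))
    cand <- cand[recov >= 0.5 * depth]
    if (length(cand) == 0) { dropped <- dropped + 1L; next }
    second <- cand[which.min(d[cand])]
    keep <- sort(c(first, second))
    # baseline for this transit from samples outside any merged segment
    nb <- t >= t[i1] - 2 & t <= t[i2] + 2
    for (sg2 in merged) nb[max(1, sg2[1] - pad):min(length(t), sg2[2] + pad)] <- FALSE
    base_hz <- if (any(nb)) stats::median(f[nb]) else stats::median(base1[idx])
    r1 <- .refine_at(t, f, idx[keep[1]], refine_halfwidth)
    r2 <- .refine_at(t, f, idx[keep[2]], refine_halfwidth)
    inner <- idx[(keep[1] + 1):(keep[2] - 1)]
    node_shift <- max(f[inner]) - base_hz
    rows[[length(rows) + 1]] <- tibble::tibble(
      t_enter = t[i1], t_exit = t[i2], baseline_hz = base_hz,
      t_min1 = r1$t_min, min1_shift_hz = r1$f_min - base_hz,
      t_min2 = r2$t_min, min2_shift_hz = r2$f_min - base_hz,
      node_shift_hz = node_shift,
      refined1 = r1$refined, refined2 = r2$refined
    )
  }
  out <- if (length(rows) == 0) .empty_transits() else dplyr::bind_rows(rows)
  attr(out, "dropped") <- dropped
  out
}

.empty_transits <- function() {
  tibble::tibble(
    t_enter = numeric(), t_exit = numeric(), baseline_hz = numeric(),
    t_min1 = numeric(), min1_shift_hz = numeric(),
    t_min2 = numeric(), min2_shift_hz = numeric(),
    node_shift_hz = numeric(), refined1 = logical(), refined2 = logical()
  )
}

# index ranges (start, end) of TRUE runs
.runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  purrr::map2(starts[r$values], ends[r$values], c)
}

# indices of strict-or-plateau local minima of a vector
.local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(c(FALSE, x[2:(n - 1)] <= x[1:(n - 2)] &
            x[2:(n - 1)] < x[3:n], FALSE))
}

.refine_at <- function(t, f, i, hw) {
  i1 <- max(1L, i - hw)
  i2 <- min(length(t), i + hw)
  if (i2 - i1 + 1 < 7 || which.min(f[i1:i2]) %in% c(1, i2 - i1 + 1)) {
    return(list(t_min = t[i], f_min = f[i], refined = FALSE))
  }
  refine_minimum(t[i1:i2], f[i1:i2])
}

#' Calibrate the frequency-to-mass conversion with bead transits
#'
#' Monodisperse polystyrene beads of known buoyant mass are run through the
#' device; the picogram-per-Hertz factor is the bead mass divided by the
#' mean (negated, averaged two-minima) frequency shift.
#'
#' @param bead_peaks Transit tibble from [detect_transits()] for the beads;
#'   at least 3 transits.
#' @param bead_buoyant_mass_pg Known bead buoyant mass, picograms.
#' @param max_cv Maximum tolerated coefficient of variation of the bead
#'   shifts before the set is rejected as polydisperse/unstable.
#' @return A list of class `smr_calibration` with `pg_per_hz`, `n_beads`,
#'   `residual_cv`.
#' @examples
#' peaks <- tibble::tibble(min1_shift_hz = rep(-2, 5), min2_shift_hz = rep(-2, 5))
#' calibrate(peaks, bead_buoyant_mass_pg = 50)
#' @export
calibrate <- function(bead_peaks, bead_buoyant_mass_pg, max_cv = 0.1) {
  stopifnot(is.data.frame(bead_peaks), bead_buoyant_mass_pg > 0)
  if (nrow(bead_peaks) < 3) {
    stop("need at least 3 bead transits", call. = FALSE)
  }
  shift <- -(bead_peaks$min1_shift_hz + bead_peaks$min2_shift_hz) / 2
  cv <- stats::sd(shift) / mean(shift)
  if (!is.finite(cv)) cv <- 0
  if (cv > max_cv) {
    stop("polydisperse or unstable calibration (CV = ",
         signif(cv, 3), ")", call. = FALSE)
  }
  structure(
    list(pg_per_hz = bead_buoyant_mass_pg / mean(shift),
         n_beads = nrow(bead_peaks), residual_cv = cv),
    class = "smr_calibration"
  )
}

#' Buoyant mass from a transit peak
#'
#' The two refined frequency minima of a transit are averaged and converted
#' to picograms with the bead calibration; the sign convention stores
#' mass-like shifts as negative Hz, so masses come out positive for cells
#' denser than the medium.
#'
#' @param peaks Transit tibble (columns `min1_shift_hz`, `min2_shift_hz`).
#' @param calib An `smr_calibration` from [calibrate()].
#' @return Numeric vector of buoyant masses, picograms.
#' @export
compute_buoyant_mass <- function(peaks, calib) {
  stopifnot(inherits(calib, "smr_calibration"))
  s1 <- peaks$min1_shift_hz
  s2 <- peaks$min2_shift_hz
  if (any(sign(s1) * sign(s2) < 0)) {
    stop("asymmetric transit: minima shifts of opposite sign", call. = FALSE)
  }
  -(s1 + s2) / 2 * calib$pg_per_hz
}

#' Node-deviation signal of a transit, in picogram equivalents
#'
#' The frequency shift recorded while the cell sits at the interior
#' displacement node, scaled by the calibration factor with its sign
#' preserved. Near zero for an ideal point mass; sensitive to cell shape
#' and stiffness, which makes it a useful mitotic changepoint signal. The
#' scalar used here (interior node extremum times the calibration factor)
#' is a pragmatic stand-in for the full acoustic definition in the
#' literature, which this package does not model.
#'
#' @inheritParams compute_buoyant_mass
#' @return Numeric vector of signed node deviations, pg-equivalent.
#' @export
compute_node_deviation <- function(peaks, calib) {
  stopifnot(inherits(calib, "smr_calibration"))
  peaks$node_shift_hz * calib$pg_per_hz
}

#' Convert detected transits to a mass-point table
#'
#' @param peaks Transit tibble from [detect_transits()].
#' @param calib An `smr_calibration`.
#' @return Tibble with `t_min` (transit midpoint, minutes),
#'   `buoyant_mass_pg`, `node_deviation_pg`, `baseline_hz`, `refined`.
#' @export
transits_to_masses <- function(peaks, calib) {
  tibble::tibble(
    t_min = (peaks$t_min1 + peaks$t_min2) / 2 / 60,
    buoyant_mass_pg = compute_buoyant_mass(peaks, calib),
    node_deviation_pg = compute_node_deviation(peaks, calib),
    baseline_hz = peaks$baseline_hz,
    refined = peaks$refined1 & peaks$refined2
  )
}
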