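#' Detect the metaphase-to-anaphase transition from a FUCCI reporter
#'
#' The mAG-hGeminin component of the FUCCI reporter is degraded at the
#' metaphase-to-anaphase (M/A) transition. The detector reports the
#' earliest time at which the intensity falls below `drop_fraction` times a
#' rolling pre-mitotic plateau median (median over `[t - 60, t - 10]` min)
#' and stays below that level for `sustain_min` minutes.
#'
#' Note that with first-order degradation kinetics the reported crossing
#' lags the biological transition by `halflife * log2(1 / drop_fraction)`;
#' [annotate_cycle()] subtracts that configured lag when it combines
#' detectors.
#'
#' @param fucci Data frame with columns `time_min` and `fucci_au`
#'   (intensity, arbitrary units), index-aligned with the cell's mass trace.
#' @param drop_fraction Fraction of the plateau below which the signal must
#'   fall (default 0.5).
#' @param sustain_min Minutes the signal must stay below threshold.
#' @param plateau_window Offsets (min) defining the rolling plateau window
#'   before each candidate time, default `c(60, 10)`.
#' @return Crossing time, minutes.
#' @export
detect_ma_fucci <- function(fucci, drop_fraction = 0.5, sustain_min = 5,
                            plateau_window = c(60, 10)) {
  stopifnot(is.data.frame(fucci),
            all(c("time_min", "fucci_au") %in% names(fucci)))
  t <- fucci$time_min
  y <- fucci$fucci_au
  if (length(t) < 5 || (max(t) - min(t)) < 30) {
    stop("FUCCI series too short for a pre-mitotic plateau", call. = FALSE)
  }
  for (i in seq_along(t)) {
    if (t[i] - t[1] < 30) next # require >= 30 min of plateau history
    pl <- y[t >= t[i] - plateau_window[1] & t <= t[i] - plateau_window[2]]
    if (length(pl) < 3) next
    thr <- drop_fraction * stats::median(pl)
    if (y[i] < thr) {
      sustained <- y[t >= t[i] & t <= t[i] + sustain_min]
      if (all(sustained < thr)) return(t[i])
    }
  }
  stop("no M/A detected (FUCCI)", call. = FALSE)
}

#' Detect the M/A transition from biophysical signals
#'
#' At the M/A transition the node-deviation signal drops sharply and the
#' (uncorrected) buoyant-mass trace shows a momentary dip, both partly due
#' to anaphase cell elongation. The detector requires both signatures
#' within a coincidence window and returns the onset of the mass dip.
#' Because mass accumulation decays to zero as the cell approaches M/A and
#' the elongation bias pulls the measured mass down immediately after it,
#' the dip onset is the local maximum of the (lightly smoothed) mass trace
#' near the node drop; a genuine dip additionally requires a sustained
#' decline after that maximum, clearly exceeding the measurement noise.
#'
#' @param trace Mass trace with a `node_pg` channel.
#' @param coincidence_min Maximum separation between the node drop and the
#'   mass-dip onset, minutes.
#' @param min_node_drop_sd Node step threshold in units of the node
#'   channel's local noise SD.
#' @param min_dip_sd Total mass decline over the fit window, in units of
#'   the mass noise SD, required to call a dip.
#' @return Mass-dip onset time, minutes.
#' @export
detect_ma_biophysical <- function(trace, coincidence_min = 10,
                                  min_node_drop_sd = 5, min_dip_sd = 3) {
  stopifnot(is.data.frame(trace),
            all(c("time_min", "mass_pg") %in% names(trace)))
  if (!"node_pg" %in% names(trace) || all(is.na(trace$node_pg))) {
    stop("node deviation missing: no node_pg channel", call. = FALSE)
  }
  t <- trace$time_min
  nd <- trace$node_pg
  m <- trace$mass_pg
  # --- node condition: largest short-range decrease, must exceed noise ---
  k <- max(1L, round(4 / stats::median(diff(t)))) # ~4 min span
  n <- length(t)
  if (n <= k + 3) stop("trace too short", call. = FALSE)
  step <- nd[seq_len(n - k)] - nd[seq_len(n - k) + k]
  nd_sigma <- stats::mad(diff(nd)) / sqrt(2)
  i_node <- which.max(step)
  if (!is.finite(nd_sigma) || nd_sigma == 0) nd_sigma <- 1e-12
  if (step[i_node] < min_node_drop_sd * nd_sigma) {
    stop("node deviation missing: no sharp node-deviation drop",
         call. = FALSE)
  }
  t_node <- t[i_node]
  # --- mass condition: local mass maximum followed by a sustained decline ---
  pre <- t >= t_node - 35 & t <= t_node - 5
  if (sum(pre) < 5) stop("insufficient pre-mitotic mass data", call. = FALSE)
  m_sigma <- stats::mad(diff(m[pre])) / sqrt(2)
  if (!is.finite(m_sigma) || m_sigma == 0) m_sigma <- 1e-12
  sm <- smooth_trace(tibble::tibble(time_min = t, mass_pg = m),
                     window_min = 5)$mass_pg
  sig_sm <- m_sigma / sqrt(5)
  # the dip begins at/just after the node drop: search asymmetrically
  near <- which(t >= t_node - 0.8 * coincidence_min &
                  t <= t_node + 0.4 * coincidence_min)
  if (length(near) < 3) stop("trace too short around node drop", call. = FALSE)
  i_pk <- near[which.max(sm[near])]
  after <- which(t > t[i_pk] & t <= t[i_pk] + 30)
  if (length(after) < 3) stop("trace too short around node drop", call. = FALSE)
  decline <- sm[i_pk] - min(sm[after])
  if (decline < min_dip_sd * sig_sm) {
    stop("mass dip missing: no transient mass reduction near the node drop",
         call. = FALSE)
  }
  # sub-sample refinement: vertex of a quadratic fit around the maximum
  w <- which(t >= t[i_pk] - 6 & t <= t[i_pk] + 6)
  if (length(w) >= 5) {
    b <- stats::coef(stats::lm(sm[w] ~ stats::poly(t[w], 2, raw = TRUE)))
    vtx <- -b[2] / (2 * b[3])
    if (is.finite(vtx) && b[3] < 0 &&
          vtx > t_node - 0.8 * coincidence_min &&
          vtx < t_node + 0.4 * coincidence_min) {
      return(unname(vtx))
    }
  }
  t[i_pk]
}

#' Assign the G2/M transition (mitotic entry)
#'
#' Mitotic entry is located either from the node-deviation channel -- the
#' changepoint at which the signal begins a sustained decrease before the
#' M/A transition, found by a two-piece linear fit minimising the summed
#' squared error over candidate breakpoints -- or as a fixed offset before
#' the M/A transition (30 min for L1210; supply a per-experiment offset for
#' perturbations that prolong early mitosis).
#'
#' @param trace Mass trace (needs `node_pg` for `mode = "node_deviation"`).
#' @param t_ma M/A transition time, minutes.
#' @param mode `"node_deviation"` or `"fixed_offset"`.
#' @param offset_min Offset used by `fixed_offset` mode, minutes.
#' @param search_min Length of the pre-M/A window searched for the
#'   changepoint.
#' @return G2/M time, minutes.
#' @export
assign_g2m <- function(trace, t_ma, mode = c("node_deviation", "fixed_offset"),
                       offset_min = 30, search_min = 90) {
  mode <- match.arg(mode)
  if (mode == "fixed_offset") return(t_ma - offset_min)
  if (!"node_pg" %in% names(trace) || all(is.na(trace$node_pg))) {
    stop("node_pg channel absent; use mode = \"fixed_offset\"", call. = FALSE)
  }
  # exclude the sharp M/A drop itself from the fit window
  sel <- trace$time_min >= t_ma - search_min & trace$time_min <= t_ma - 3
  t <- trace$time_min[sel]
  y <- trace$node_pg[sel]
  if (length(t) < 10) stop("too few node-deviation points before t_ma",
                           call. = FALSE)
  idx <- seq(4, length(t) - 3)
  sse <- vapply(idx, function(i) {
    s1 <- sum(stats::lm.fit(cbind(1, t[1:i]), y[1:i])$residuals^2)
    s2 <- sum(stats::lm.fit(cbind(1, t[i:length(t)]),
                            y[i:length(t)])$residuals^2)
    s1 + s2
  }, numeric(1))
  t[idx[which.min(sse)]]
}

#' Anaphase (elongation) window
#'
#' The elongation interval `(t_ma, t_ma + tau_e)`; 12 min for L1210 cells.
#' Clipped, with a warning, if it would extend past abscission.
#'
#' @param t_ma M/A transition time, minutes.
#' @param tau_e Elongation duration, minutes (> 0).
#' @param t_abscission Optional abscission time used for clipping.
#' @return Numeric vector `c(start, end)`.
#' @export
anaphase_window <- function(t_ma, tau_e = 12, t_abscission = NULL) {
  stopifnot(tau_e > 0)
  end <- t_ma + tau_e
  if (!is.null(t_abscission) && end > t_abscission) {
    warning("anaphase window clipped at abscission", call. = FALSE)
    end <- t_abscission
  }
  c(start = t_ma, end = end)
}

#' Annotate one cell cycle with its mitotic events
#'
#' Combines the available detectors into a per-cycle annotation. The M/A
#' transition is taken from the FUCCI reporter when present (crossing time
#' minus the configured degradation lag), falling back to the biophysical
#' (node-deviation + mass-dip) detector. G2/M defaults to the fixed offset
#' before M/A (30 min for L1210, the standard assignment, which the
#' node-deviation changepoint independently validates); set
#' `g2m_mode = "node_deviation"` to use the changepoint instead.
#' M-phase is defined as `[t_g2m, t_abscission]`, early mitosis as
#' `[t_g2m, t_ma]` and cytokinesis as `[t_ma, t_abscission]`.
#'
#' @param trace Mass trace with optional `node_pg`, `fucci_au` channels.
#' @param t_abscission Abscission time for this cycle (e.g. from
#'   [detect_divisions()]).
#' @param tau_e Elongation duration, minutes.
#' @param g2m_mode `"fixed_offset"` (default) or `"node_deviation"`.
#' @param g2m_offset_min Fixed G2/M offset before M/A, minutes.
#' @param drop_fraction,sustain_min FUCCI detector settings.
#' @param fucci_halflife_min Assumed reporter degradation half-life used to
#'   remove the crossing lag (set 0 to disable the correction).
#' @param cell_id,cycle_index Identifiers copied into the output.
#' @return One-row tibble of class `cycle_annotation`: `cell_id`,
#'   `cycle_index`, `t_g2m_min`, `t_ma_min`, `t_abscission_min`,
#'   `tau_e_min`, `method_g2m`, `method_ma`.
#' @export
annotate_cycle <- function(trace, t_abscission, tau_e = 12,
                           g2m_mode = c("fixed_offset", "node_deviation"),
                           g2m_offset_min = 30, drop_fraction = 0.5,
                           sustain_min = 5, fucci_halflife_min = 10,
                           cell_id = attr(trace, "cell_id") %||% "cell_1",
                           cycle_index = 1L) {
  g2m_mode <- match.arg(g2m_mode)
  stopifnot(is.data.frame(trace))
  pre <- trace[trace$time_min <= t_abscission, , drop = FALSE]
  t_ma <- NULL
  method_ma <- NA_character_
  if ("fucci_au" %in% names(pre) && !all(is.na(pre$fucci_au))) {
    t_ma <- tryCatch(
      detect_ma_fucci(pre, drop_fraction, sustain_min),
      error = function(e) NULL
    )
    if (!is.null(t_ma)) {
      t_ma <- t_ma - fucci_halflife_min * log2(1 / drop_fraction)
      method_ma <- "fucci"
    }
  }
  if (is.null(t_ma)) {
    t_ma <- detect_ma_biophysical(pre)
    method_ma <- "biophysical"
  }
  if (g2m_mode == "node_deviation" &&
        "node_pg" %in% names(pre) && !all(is.na(pre$node_pg))) {
    t_g2m <- assign_g2m(pre, t_ma, "node_deviation")
    method_g2m <- "node_deviation"
  } else {
    t_g2m <- assign_g2m(pre, t_ma, "fixed_offset", offset_min = g2m_offset_min)
    method_g2m <- "fixed_offset"
  }
  if (!(t_g2m < t_ma && t_ma < t_abscission)) {
    stop("event ordering violated: need t_g2m < t_ma < t_abscission",
         call. = FALSE)
  }
  out <- tibble::tibble(
    cell_id = cell_id, cycle_index = as.integer(cycle_index),
    t_g2m_min = t_g2m, t_ma_min = t_ma, t_abscission_min = t_abscission,
    tau_e_min = tau_e, method_g2m = method_g2m, method_ma = method_ma
  )
  class(out) <- c("cycle_annotation", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
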