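#' Stage-level mass accumulation rate
#'
#' Ordinary least-squares slope of the mass trace over one cell-cycle stage
#' `[t0, t1]`. The point set is the trace samples inside the stage
#' augmented with linearly interpolated points at exactly `t0` and `t1`, so
#' stage boundaries falling between samples are pinpointed rather than
#' rounded to the grid. The slope is the MAR (pg/hr); dividing by the mean
#' mass of the same point set gives the size-normalised rate MAR/mass
#' (1/hr).
#'
#' @param trace Mass trace (columns `time_min`, `mass_pg`).
#' @param t0,t1 Stage boundaries, minutes, inside the trace span.
#' @param stage Optional stage label copied to the output.
#' @return One-row tibble: `stage`, `t0_min`, `t1_min`, `slope_pg_per_hr`,
#'   `mean_mass_pg`, `mar_per_mass_per_hr`, `n_points`.
#' @export
stage_mar <- function(trace, t0, t1, stage = NA_character_) {
  stopifnot(is.data.frame(trace), t1 > t0)
  t <- trace$time_min
  m <- trace$mass_pg
  if (t0 < min(t) || t1 > max(t)) {
    stop("stage [", t0, ", ", t1, "] extends outside the trace", call. = FALSE)
  }
  inside <- t >= t0 & t <= t1
  ts <- t[inside]
  ms <- m[inside]
  if (!any(ts == t0)) {
    ts <- c(t0, ts)
    ms <- c(stats::approx(t, m, xout = t0)$y, ms)
  }
  if (!any(ts == t1)) {
    ts <- c(ts, t1)
    ms <- c(ms, stats::approx(t, m, xout = t1)$y)
  }
  if (length(ts) < 3) stop("stage too sparse", call. = FALSE)
  sl <- .ols_slope(ts, ms) * 60 # pg/min -> pg/hr
  mm <- mean(ms)
  tibble::tibble(
    stage = stage, t0_min = t0, t1_min = t1,
    slope_pg_per_hr = sl, mean_mass_pg = mm,
    mar_per_mass_per_hr = sl / mm, n_points = length(ts)
  )
}

.ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' Sliding-window MAR and MAR/mass
#'
#' Quantifies the slope (MAR, pg/hr) and mean mass in windows of
#' `window_min` minutes whose starts are `step_min` apart, anchored at the
#' start of the trace; window centres are reported. The default 10-min
#' windows every 5 min match the standard analysis; a high-resolution 4/2
#' variant is selected by passing `window_min = 4, step_min = 2`. Windows
#' with fewer than 3 points are skipped (count in attribute `skipped`).
#'
#' @param trace Mass trace.
#' @param window_min Window length, minutes.
#' @param step_min Spacing of window starts, minutes.
#' @return A `mar_windows` tibble: `t_center_min`, `slope_pg_per_hr`,
#'   `mean_mass_pg`, `mar_per_mass_per_hr`, `n_points`; attributes
#'   `window_min`, `step_min`, `skipped`.
#' @export
sliding_mar <- function(trace, window_min = 10, step_min = 5) {
  stopifnot(is.data.frame(trace), window_min > 0, step_min > 0)
  t <- trace$time_min
  m <- trace$mass_pg
  span <- max(t) - min(t)
  if (span < window_min) stop("trace shorter than one window", call. = FALSE)
  starts <- seq(min(t), max(t) - window_min, by = step_min)
  skipped <- 0L
  rows <- purrr::map(starts, function(s) {
    sel <- t >= s & t <= s + window_min
    if (sum(sel) < 3) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    sl <- .ols_slope(t[sel], m[sel]) * 60
    mm <- mean(m[sel])
    tibble::tibble(
      t_center_min = s + window_min / 2,
      slope_pg_per_hr = sl, mean_mass_pg = mm,
      mar_per_mass_per_hr = sl / mm, n_points = sum(sel)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "window_min") <- window_min
  attr(out, "step_min") <- step_min
  attr(out, "skipped") <- skipped
  class(out) <- c("mar_windows", class(out))
  out
}

#' Moving-average smoothing of a mass trace
#'
#' Centred moving average over a `window_min` window (used for single-cell
#' display); endpoints use truncated windows. On a regular 1-min grid the
#' default covers 10 samples.
#'
#' @param trace Mass trace.
#' @param window_min Window length, minutes.
#' @return The trace with `mass_pg` smoothed.
#' @export
smooth_trace <- function(trace, window_min = 10) {
  stopifnot(is.data.frame(trace), window_min > 0)
  t <- trace$time_min
  m <- trace$mass_pg
  sm <- vapply(seq_along(t), function(i) {
    sel <- t >= t[i] - window_min / 2 & t < t[i] + window_min / 2
    mean(m[sel])
  }, numeric(1))
  out <- trace
  out$mass_pg <- sm
  out
}

#' Per-cell peak MAR/mass: late G2 versus early mitosis
#'
#' Compares the highest MAR/mass attained in early mitosis
#' `[t_g2m, t_ma]` with the highest attained in the preceding G2 segment
#' `[t_g2m - g2_search_min, t_g2m]`, per cell, as a percent increase.
#'
#' Windows are assigned to a segment only when fully contained in it, so a
#' window straddling mitotic entry cannot leak burst growth into the G2
#' maximum. The default G2 segment is the 30-min late-G2 stage, matching
#' the early-mitosis segment length so the two maxima carry the same
#' noise-induced inflation.
#'
#' @param trace Mass trace covering both segments.
#' @param annotation One-row cycle annotation for the cycle.
#' @param window_min,step_min Sliding-window settings.
#' @param g2_search_min G2 search segment length before mitotic entry,
#'   minutes (truncated to available data).
#' @param smooth Smooth the trace with [smooth_trace()] first.
#' @return Percent increase (positive = faster growth in early mitosis).
#' @export
g2_vs_mitosis_peak <- function(trace, annotation, window_min = 10,
                               step_min = 5, g2_search_min = 30,
                               smooth = FALSE) {
  peak_mar_pair(trace, annotation, window_min, step_min, g2_search_min,
                smooth)$peak_increase_pct
}

#' Per-cell peak MAR/mass in late G2 and in early mitosis
#'
#' The two maxima underlying [g2_vs_mitosis_peak()], returned separately
#' (for population boxplots and the Welch comparison of the two sets).
#'
#' @inheritParams g2_vs_mitosis_peak
#' @return One-row tibble: `max_g2`, `max_mitosis`, `peak_increase_pct`.
#' @export
peak_mar_pair <- function(trace, annotation, window_min = 10, step_min = 5,
                          g2_search_min = 30, smooth = FALSE) {
  t_g2m <- annotation$t_g2m_min[1]
  t_ma <- annotation$t_ma_min[1]
  if (smooth) trace <- smooth_trace(trace, window_min)
  g2_start <- max(t_g2m - g2_search_min, min(trace$time_min))
  seg <- trace[trace$time_min >= g2_start &
                 trace$time_min <= t_ma, , drop = FALSE]
  w <- sliding_mar(seg, window_min, step_min)
  half <- window_min / 2
  g2 <- w$mar_per_mass_per_hr[w$t_center_min >= g2_start + half &
                                w$t_center_min <= t_g2m - half]
  mit <- w$mar_per_mass_per_hr[w$t_center_min >= t_g2m + half &
                                 w$t_center_min <= t_ma - half]
  if (length(g2) == 0 || length(mit) == 0) {
    stop("a peak segment contains no fully contained window", call. = FALSE)
  }
  tibble::tibble(
    max_g2 = max(g2), max_mitosis = max(mit),
    peak_increase_pct = 100 * (max(mit) - max(g2)) / max(g2)
  )
}

#' Normalise stage-level MAR values to control means
#'
#' Divides each value by the control mean of its stage (the display
#' normalisation used when comparing perturbations to control).
#'
#' @param stage_values Tibble with columns `stage` and a value column.
#' @param control_means Tibble with columns `stage` and `control_mean`.
#' @param value_col Name of the value column, default `"slope_pg_per_hr"`.
#' @return `stage_values` with an added `normalized` column.
#' @export
normalize_to_control <- function(stage_values, control_means,
                                 value_col = "slope_pg_per_hr") {
  stopifnot(is.data.frame(stage_values), is.data.frame(control_means),
            "stage" %in% names(stage_values),
            all(c("stage", "control_mean") %in% names(control_means)))
  if (any(control_means$control_mean == 0)) {
    stop("zero control mean for at least one stage", call. = FALSE)
  }
  out <- dplyr::left_join(tibble::as_tibble(stage_values), control_means,
                          by = "stage")
  if (any(is.na(out$control_mean))) {
    stop("stages without a control mean: ",
         paste(unique(out$stage[is.na(out$control_mean)]), collapse = ", "),
         call. = FALSE)
  }
  out$normalized <- out[[value_col]] / out$control_mean
  out
}

#' Stage MAR table for an annotated cycle
#'
#' Computes the four standard stages -- late G2 (last 30 min before G2/M),
#' early mitosis (G2/M to M/A), cytokinesis (M/A to abscission) and newborn
#' G1 (first 30 min after abscission, if covered) -- for one cell.
#'
#' @param trace Mass trace.
#' @param annotation One-row cycle annotation.
#' @param g2_min,g1_min Durations of the late-G2 and newborn-G1 stages.
#' @return Tibble with one row per stage (see [stage_mar()]), plus
#'   `cell_id`.
#' @export
stage_mar_table <- function(trace, annotation, g2_min = 30, g1_min = 30) {
  t_g2m <- annotation$t_g2m_min[1]
  t_ma <- annotation$t_ma_min[1]
  t_ab <- annotation$t_abscission_min[1]
  # the sample at t_ab is the first (halved) daughter point: cytokinesis
  # ends at the last mother measurement, newborn G1 starts at t_ab
  pre_ab <- trace$time_min[trace$time_min < t_ab]
  t_ck_end <- if (length(pre_ab) > 0) max(pre_ab) else t_ab
  stages <- list(
    late_G2 = c(t_g2m - g2_min, t_g2m),
    early_mitosis = c(t_g2m, t_ma),
    cytokinesis = c(t_ma, t_ck_end),
    newborn_G1 = c(t_ab, t_ab + g1_min)
  )
  rows <- purrr::imap(stages, function(b, nm) {
    if (b[1] < min(trace$time_min) || b[2] > max(trace$time_min)) return(NULL)
    stage_mar(trace, b[1], b[2], stage = nm)
  })
  out <- dplyr::bind_rows(rows)
  out$cell_id <- annotation$cell_id[1]
  out
}
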