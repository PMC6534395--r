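#' Mass accumulated in mitosis and cytokinesis, as cell-cycle fractions
#'
#' The total mass accumulated over the whole cell cycle is taken as half
#' the abscission mass (birth size assumed to be exactly half the
#' abscission size). Accumulation during early mitosis (G2/M to M/A) and
#' cytokinesis (M/A to abscission) is then expressed relative to that
#' total. Only measurements before abscission are used, so the halved
#' daughter point never contaminates the event masses; masses at the event
#' times are linearly interpolated.
#'
#' @param trace Mass trace for one cycle (corrected for the elongation bias
#'   unless `use_uncorrected` analyses are intended).
#' @param annotation One-row cycle annotation.
#' @return One-row tibble: `cell_id`, `f_mitosis`, `f_cytokinesis`,
#'   `f_mphase`, `abscission_mass_pg`, `total_accumulation_pg`.
#' @export
mass_fractions <- function(trace, annotation) {
  stopifnot(is.data.frame(trace))
  t_g2m <- annotation$t_g2m_min[1]
  t_ma <- annotation$t_ma_min[1]
  t_ab <- annotation$t_abscission_min[1]
  pre <- trace[trace$time_min < t_ab, , drop = FALSE]
  if (nrow(pre) < 3 || t_g2m < min(pre$time_min)) {
    stop("trace does not cover the annotated M-phase", call. = FALSE)
  }
  m_at <- function(tt) stats::approx(pre$time_min, pre$mass_pg, xout = tt,
                                     rule = 2)$y
  m_g2m <- m_at(t_g2m)
  m_ma <- m_at(t_ma)
  m_ab <- m_at(t_ab)
  total <- m_ab / 2
  if (total <= 0) stop("non-positive total accumulation", call. = FALSE)
  tibble::tibble(
    cell_id = annotation$cell_id[1],
    f_mitosis = (m_ma - m_g2m) / total,
    f_cytokinesis = (m_ab - m_ma) / total,
    f_mphase = (m_ab - m_g2m) / total,
    abscission_mass_pg = m_ab,
    total_accumulation_pg = total
  )
}

#' Align per-cell MAR/mass series to the M/A transition
#'
#' Each cell's MAR/mass series is shifted so the M/A transition is time
#' zero, linearly interpolated onto a common grid of exactly 100 points
#' spanning `span`, and averaged across cells point-by-point (mean, SD,
#' SEM). Cells whose windows do not cover the span are dropped (count in
#' attribute `n_dropped`). With a single cell the SD is reported as 0 and
#' flagged.
#'
#' @param windows Long tibble of sliding-window results with columns
#'   `cell_id`, `t_center_min` and a value column.
#' @param annotations Cycle-annotation tibble with `cell_id`, `t_ma_min`.
#' @param span Relative-time span `c(lo, hi)` in minutes around M/A;
#'   default `c(-90, 60)`.
#' @param value_col Column to aggregate, default `"mar_per_mass_per_hr"`.
#' @param n_grid Number of grid points (100, the standard choice).
#' @return An `ensemble_grid` tibble: `rel_time_min`, `mean`, `sd`, `sem`,
#'   `n`.
#' @export
align_to_ma <- function(windows, annotations, span = c(-90, 60),
                        value_col = "mar_per_mass_per_hr", n_grid = 100) {
  .align_ensemble(windows, annotations, anchor_col = "t_ma_min",
                  span = span, value_col = value_col, n_grid = n_grid,
                  smoothing_length = 1)
}

#' Align per-cell MAR/mass series to mitotic entry
#'
#' As [align_to_ma()] but anchored at the G2/M transition, for experiments
#' (e.g. drug-induced mitotic arrest) where no M/A transition exists; each
#' cell's series is first smoothed with a moving-average filter of length
#' `smoothing_length` (default 3).
#'
#' @inheritParams align_to_ma
#' @param smoothing_length Length of the per-cell moving-average filter.
#' @return An `ensemble_grid` tibble.
#' @export
align_to_entry <- function(windows, annotations, span = c(-60, 180),
                           value_col = "mar_per_mass_per_hr", n_grid = 100,
                           smoothing_length = 3) {
  .align_ensemble(windows, annotations, anchor_col = "t_g2m_min",
                  span = span, value_col = value_col, n_grid = n_grid,
                  smoothing_length = smoothing_length)
}

.align_ensemble <- function(windows, annotations, anchor_col, span,
                            value_col, n_grid, smoothing_length) {
  stopifnot(is.data.frame(windows), is.data.frame(annotations),
            length(span) == 2, span[1] < span[2], n_grid >= 2)
  grid <- seq(span[1], span[2], length.out = n_grid)
  per_cell <- list()
  dropped <- 0L
  for (cid in unique(windows$cell_id)) {
    anchor <- annotations[[anchor_col]][match(cid, annotations$cell_id)]
    if (is.na(anchor)) { dropped <- dropped + 1L; next }
    w <- windows[windows$cell_id == cid, , drop = FALSE]
    rel <- w$t_center_min - anchor
    val <- w[[value_col]]
    if (smoothing_length > 1) val <- .movavg(val, smoothing_length)
    if (min(rel) > span[1] || max(rel) < span[2]) {
      dropped <- dropped + 1L
      next
    }
    per_cell[[cid]] <- stats::approx(rel, val, xout = grid)$y
  }
  if (length(per_cell) == 0) stop("no cell covers the requested span",
                                  call. = FALSE)
  mat <- do.call(rbind, per_cell)
  n <- nrow(mat)
  sd_ <- if (n > 1) apply(mat, 2, stats::sd) else rep(0, ncol(mat))
  out <- tibble::tibble(
    rel_time_min = grid,
    mean = colMeans(mat),
    sd = sd_,
    sem = sd_ / sqrt(n),
    n = n
  )
  attr(out, "n_dropped") <- dropped
  attr(out, "single_cell") <- n == 1
  class(out) <- c("ensemble_grid", class(out))
  out
}

# centred moving average with truncated ends, length k
.movavg <- function(x, k) {
  n <- length(x)
  half_lo <- floor((k - 1) / 2)
  half_hi <- ceiling((k - 1) / 2)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
}

#' Normalise traces so the typical abscission mass is 2
#'
#' Each cell's trace is scaled by `2 / abscission mass`, so that under the
#' birth-is-half-of-abscission convention birth mass is about 1 -- the
#' display normalisation used for trace overlays.
#'
#' @param traces Long tibble with `cell_id`, `time_min`, `mass_pg`.
#' @param annotations Cycle-annotation tibble giving `t_abscission_min` per
#'   `cell_id`.
#' @return `traces` with `mass_pg` scaled (column `mass_norm`).
#' @export
normalize_abscission_two <- function(traces, annotations) {
  stopifnot(is.data.frame(traces), is.data.frame(annotations))
  scale_tbl <- purrr::map_dfr(unique(traces$cell_id), function(cid) {
    tr <- traces[traces$cell_id == cid, , drop = FALSE]
    t_ab <- annotations$t_abscission_min[match(cid, annotations$cell_id)]
    pre <- tr[tr$time_min < t_ab, , drop = FALSE]
    m_ab <- stats::approx(pre$time_min, pre$mass_pg, xout = t_ab,
                          rule = 2)$y
    tibble::tibble(cell_id = cid, abscission_mass_pg = m_ab)
  })
  out <- dplyr::left_join(tibble::as_tibble(traces), scale_tbl,
                          by = "cell_id")
  out$mass_norm <- out$mass_pg * 2 / out$abscission_mass_pg
  out
}

#' Two-tailed Welch t-test
#'
#' Unequal-variance t statistic with Welch--Satterthwaite degrees of
#' freedom and a two-tailed p-value (wraps [stats::t.test()]). Two
#' zero-variance samples with equal means return `t = 0, p = 1`.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return One-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(t = 0, df = NA_real_, p = 1,
                            mean_a = mean(a), mean_b = mean(b)))
    }
    return(tibble::tibble(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                          p = 0, mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, mean_a = mean(a), mean_b = mean(b)
  )
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Wraps [stats::aov()] and [stats::TukeyHSD()] (studentized-range
#' adjustment); all pairwise comparisons are reported.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of group labels; >= 3 groups, each
#'   with >= 2 observations.
#' @return List with `F`, `p`, and `pairwise` (tibble: `comparison`,
#'   `diff`, `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 3) stop("need at least 3 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(
    F = an[["F value"]][1],
    p = an[["Pr(>F)"]][1],
    pairwise = tibble::tibble(
      comparison = rownames(tk),
      diff = tk[, "diff"],
      p_adj = tk[, "p adj"]
    )
  )
}
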