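#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy sliding-window MAR results
#'
#' @param x A `mar_windows` tibble from [sliding_mar()].
#' @param ... Unused.
#' @return A plain tibble of the window estimates with the window settings
#'   as columns.
#' @export
tidy.mar_windows <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$window_min <- attr(x, "window_min")
  out$step_min <- attr(x, "step_min")
  out
}

#' @rdname tidy.mar_windows
#' @export
glance.mar_windows <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x),
    skipped = attr(x, "skipped") %||% 0L,
    window_min = attr(x, "window_min"),
    step_min = attr(x, "step_min"),
    mean_mar_per_mass = mean(x$mar_per_mass_per_hr),
    max_mar_per_mass = max(x$mar_per_mass_per_hr)
  )
}

#' Tidy an ensemble grid
#'
#' @param x An `ensemble_grid` from [align_to_ma()] / [align_to_entry()].
#' @param ... Unused.
#' @return Tibble of the grid values / a one-row summary.
#' @export
tidy.ensemble_grid <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.ensemble_grid
#' @export
glance.ensemble_grid <- function(x, ...) {
  tibble::tibble(
    n_cells = x$n[1],
    n_dropped = attr(x, "n_dropped") %||% 0L,
    n_grid = nrow(x),
    span_lo = min(x$rel_time_min),
    span_hi = max(x$rel_time_min)
  )
}

#' Summarise a bead calibration
#'
#' @param x An `smr_calibration` from [calibrate()].
#' @param ... Unused.
#' @return One-row tibble with `pg_per_hz`, `n_beads`, `residual_cv`.
#' @export
tidy.smr_calibration <- function(x, ...) {
  tibble::tibble(pg_per_hz = x$pg_per_hz, n_beads = x$n_beads,
                 residual_cv = x$residual_cv)
}

#' @export
print.smr_calibration <- function(x, ...) {
  cat("SMR bead calibration:", signif(x$pg_per_hz, 6), "pg/Hz from",
      x$n_beads, "beads (CV", signif(x$residual_cv, 3), ")\n")
  invisible(x)
}
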