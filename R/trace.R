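#' Assemble a validated per-cell mass trace
#'
#' Sorts, validates and classes a table of repeated buoyant-mass
#' measurements of one cell (typically one point per ~1 min). Optional
#' auxiliary channels (node deviation, FUCCI reporter intensity) travel as
#' extra columns, index-aligned with the mass points.
#'
#' @param points Data frame with columns `time_min` and `mass_pg`; optional
#'   `node_pg` (node deviation, pg-equivalent) and `fucci_au`.
#' @param cell_id Identifier of the tracked cell.
#' @param parent_id Identifier of the mother cell, or `NA`.
#' @param max_gap_min Gaps longer than this (default 10 min) set the
#'   `gappy` attribute and raise a warning.
#' @return A `mass_trace` tibble sorted by time with attributes `cell_id`,
#'   `parent_id`, `gappy`.
#' @examples
#' assemble_trace(tibble::tibble(time_min = 0:2, mass_pg = c(40, 40.1, 40.2)))
#' @export
assemble_trace <- function(points, cell_id = "cell_1", parent_id = NA_character_,
                           max_gap_min = 10) {
  stopifnot(is.data.frame(points),
            all(c("time_min", "mass_pg") %in% names(points)))
  if (nrow(points) < 2) stop("need at least 2 mass points", call. = FALSE)
  if (any(!is.finite(points$time_min)) || any(!is.finite(points$mass_pg))) {
    stop("non-finite values in trace", call. = FALSE)
  }
  out <- dplyr::arrange(tibble::as_tibble(points), .data$time_min)
  if (any(diff(out$time_min) == 0)) {
    stop("duplicate timestamps in trace", call. = FALSE)
  }
  if (any(out$mass_pg <= 0)) {
    stop("non-positive masses in trace", call. = FALSE)
  }
  gappy <- any(diff(out$time_min) > max_gap_min)
  if (gappy) {
    warning("trace '", cell_id, "' contains gaps > ", max_gap_min, " min",
            call. = FALSE)
  }
  attr(out, "cell_id") <- cell_id
  attr(out, "parent_id") <- parent_id
  attr(out, "gappy") <- gappy
  class(out) <- c("mass_trace", class(out))
  out
}

#' Detect division (abscission) events in a mass trace
#'
#' A division appears as an approximately 50% loss of buoyant mass between
#' two measurements no more than `max_gap_min` apart (the discarded daughter
#' is flushed away). Every consecutive point pair whose fractional loss
#' falls inside `loss_band` is emitted as one event at the later point's
#' time. The rule is ratio-based and therefore invariant under uniform mass
#' rescaling. Events closer than `refractory_min` to the previous event are
#' suppressed (a cell cannot divide twice in half an hour).
#'
#' @param trace A mass trace (tibble with `time_min`, `mass_pg`).
#' @param loss_band Accepted fractional-loss interval; the default
#'   `c(0.35, 0.65)` brackets "approximately 50%" while tolerating division
#'   asymmetry without firing on the few-percent anaphase dip.
#' @param max_gap_min Maximum time between the bracketing points, minutes.
#' @param refractory_min Minimum spacing between successive events.
#' @return Tibble with one row per event: `t_abscission_min`, `mass_before`,
#'   `mass_after`, `loss_fraction`.
#' @export
detect_divisions <- function(trace, loss_band = c(0.35, 0.65),
                             max_gap_min = 2, refractory_min = 30) {
  stopifnot(is.data.frame(trace), nrow(trace) >= 2,
            length(loss_band) == 2, loss_band[1] < loss_band[2])
  t <- trace$time_min
  m <- trace$mass_pg
  n <- length(t)
  dt <- diff(t)
  loss <- (m[-n] - m[-1]) / m[-n]
  hit <- which(dt <= max_gap_min & loss >= loss_band[1] & loss <= loss_band[2])
  ev <- tibble::tibble(
    t_abscission_min = t[hit + 1],
    mass_before = m[hit],
    mass_after = m[hit + 1],
    loss_fraction = loss[hit]
  )
  if (nrow(ev) > 1) {
    keep <- rep(TRUE, nrow(ev))
    last <- ev$t_abscission_min[1]
    for (i in seq_len(nrow(ev))[-1]) {
      if (ev$t_abscission_min[i] - last < refractory_min) keep[i] <- FALSE
      else last <- ev$t_abscission_min[i]
    }
    ev <- ev[keep, ]
  }
  ev
}

#' Split a multi-generation trace into cell cycles
#'
#' Cuts a lineage trace at its division events. Cycle `k` runs from the
#' post-division point of event `k - 1` (the daughter's first measurement,
#' its birth mass) up to and including the pre-division point of event `k`
#' (the abscission mass). The first and last cycles of a recording are
#' flagged incomplete and are excluded from population statistics by
#' default elsewhere.
#'
#' @param trace A mass trace.
#' @param divisions Event tibble from [detect_divisions()] on the same trace.
#' @return Tibble with one row per cycle: `cycle_index`, `trace`
#'   (list-column of sub-traces), `birth_mass`, `abscission_mass`,
#'   `complete`.
#' @export
split_cycles <- function(trace, divisions) {
  stopifnot(is.data.frame(trace))
  td <- divisions$t_abscission_min
  if (is.unsorted(td, strictly = TRUE) && length(td) > 1) {
    stop("division events must be sorted and non-overlapping", call. = FALSE)
  }
  bounds <- c(-Inf, td, Inf)
  n_cyc <- length(td) + 1
  out <- vector("list", n_cyc)
  for (k in seq_len(n_cyc)) {
    # include the birth point (time == previous event time), exclude the
    # post-division point of the closing event (time == closing event time)
    sel <- trace$time_min >= bounds[k] & trace$time_min < bounds[k + 1]
    sub <- trace[sel, , drop = FALSE]
    complete <- k > 1 & k < n_cyc & nrow(sub) >= 2
    out[[k]] <- tibble::tibble(
      cycle_index = k,
      trace = list(tibble::as_tibble(sub)),
      birth_mass = if (k > 1) divisions$mass_after[k - 1] else NA_real_,
      abscission_mass = if (k < n_cyc) divisions$mass_before[k] else NA_real_,
      complete = complete
    )
  }
  dplyr::bind_rows(out)
}

#' Interdivision times of a lineage
#'
#' Successive differences between abscission events, in hours (~9 hr for
#' L1210 cells in this system).
#'
#' @param divisions Event tibble from [detect_divisions()].
#' @return Tibble with `interval_hr`; zero rows when fewer than 2 events.
#' @export
interdivision_times <- function(divisions) {
  td <- divisions$t_abscission_min
  if (length(td) < 2) return(tibble::tibble(interval_hr = numeric()))
  tibble::tibble(interval_hr = diff(td) / 60)
}

#' Read and write per-cell trace tables
#'
#' Long-format TSV with header `cell_id`, `time_min`, `buoyant_mass_pg` and
#' optional `node_deviation_pg`, `fucci_au`; one row per measurement.
#' Internally the mass column is named `mass_pg` and the node column
#' `node_pg`.
#'
#' @param path File path (gzip transparent on read).
#' @param traces Long tibble with `cell_id`, `time_min`, `mass_pg`, optional
#'   `node_pg`, `fucci_au`.
#' @return `read_traces_tsv()`: a long tibble in internal naming;
#'   `write_traces_tsv()`: `path`, invisibly.
#' @export
read_traces_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cell_id", "time_min", "buoyant_mass_pg")
  if (!all(need %in% names(df))) {
    stop("trace table must have columns: ", paste(need, collapse = ", "),
         "; found: ", paste(names(df), collapse = ", "), call. = FALSE)
  }
  out <- dplyr::rename(df, mass_pg = "buoyant_mass_pg")
  if ("node_deviation_pg" %in% names(out)) {
    out <- dplyr::rename(out, node_pg = "node_deviation_pg")
  }
  out
}

#' @rdname read_traces_tsv
#' @export
write_traces_tsv <- function(traces, path) {
  out <- dplyr::rename(tibble::as_tibble(traces), buoyant_mass_pg = "mass_pg")
  if ("node_pg" %in% names(out)) {
    out <- dplyr::rename(out, node_deviation_pg = "node_pg")
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
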