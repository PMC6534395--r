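#' Configuration of the synthetic lineage generator
#'
#' Collects every parameter of the ground-truth simulator with defaults
#' that emulate L1210 lymphocytes growing in an SMR: ~9 hr interdivision
#' time, one mass point per minute with 0.05 pg measurement noise, mitotic
#' entry 30 min before the metaphase-to-anaphase (M/A) transition, a
#' prophase MAR burst (x1.16 for 20 min) followed by a rapid decay to zero
#' at M/A, zero accumulation for the 12 min of elongation, and a linear
#' recovery that continues through abscission into the newborn daughter.
#' Division halves the mass with a small Gaussian asymmetry.
#'
#' The specific growth rate is exponential in mass (MAR proportional to
#' mass) during interphase, the default 0.08/hr giving close to a mass
#' doubling over the 9 hr cycle.
#'
#' @param ... Named overrides of any default listed below.
#' @return A validated list of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_cells = 10, noise_sd_pg = 0)
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_cells = 100,
    generations = 5,
    interdivision_hr = 9,
    interdivision_cv = 0.05,
    sampling_min = 1,
    noise_sd_pg = 0.05,
    birth_mass_pg = 35,
    birth_mass_cv = 0.1,
    alpha_interphase = 0.08,     # 1/hr
    prophase_multiplier = 1.16,
    prophase_duration_min = 20,
    g2m_offset_min = 30,         # G2/M precedes M/A by this
    tau_e_min = 12,              # elongation (anaphase) duration
    recovery_min = 40,           # MAR ramp back to alpha after elongation
    cytokinesis_min = 50,        # M/A to abscission
    division_asymmetry_sd = 0.02,
    bias_injection = TRUE,
    channels = TRUE,
    node_plateau_pg = 3,
    node_noise_pg = 0.1,
    fucci_plateau_au = 100,
    fucci_halflife_min = 10,
    fucci_noise_au = 3,
    density_contrast = 75,       # kg/m^3
    L_cant_um = 350,
    scenario = "control",
    arrest_decay_min = 150,      # MAR decay span in prometaphase arrest
    cyto_mar_factor = 1          # recovery amplitude scale (drug scenarios)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  with(cfg, {
    stopifnot(
      n_cells >= 1, generations >= 1, interdivision_hr > 0,
      interdivision_cv >= 0, sampling_min > 0, noise_sd_pg >= 0,
      birth_mass_pg > 0, alpha_interphase > 0, prophase_multiplier >= 0,
      prophase_duration_min > 0, g2m_offset_min > prophase_duration_min,
      tau_e_min > 0, recovery_min > 0, cytokinesis_min > tau_e_min,
      division_asymmetry_sd >= 0, cyto_mar_factor >= 0
    )
    if (!scenario %in% c("control", "prometaphase_arrest",
                         "cytokinesis_block")) {
      stop("unknown scenario: ", scenario, call. = FALSE)
    }
  })
  structure(cfg, class = "synth_config")
}

# ---- piecewise-linear specific-growth-rate profile ------------------------

# Segment table for one lineage: rows (t0, t1, a0, a1), alpha linear within.
# `births` and `cycle_len` are absolute birth times / cycle durations.
.profile_segments <- function(cfg, births, cycle_len, horizon) {
  al <- cfg$alpha_interphase / 60 # per minute
  segs <- list()
  cursor <- births[1]
  for (k in seq_along(births)) {
    b <- births[k]
    T_k <- cycle_len[k]
    t_ma <- b + T_k - cfg$cytokinesis_min
    t_g2m <- t_ma - cfg$g2m_offset_min
    burst_end <- t_g2m + cfg$prophase_duration_min
    ab <- al * cfg$prophase_multiplier
    segs[[length(segs) + 1]] <- c(cursor, t_g2m, al, al)
    if (cfg$scenario == "prometaphase_arrest") {
      dec_end <- burst_end + cfg$arrest_decay_min
      segs[[length(segs) + 1]] <- c(t_g2m, burst_end, ab, ab)
      segs[[length(segs) + 1]] <- c(burst_end, dec_end, ab, 0)
      segs[[length(segs) + 1]] <- c(dec_end, horizon, 0, 0)
      break # arrested: no further cycles
    }
    rec_start <- t_ma + cfg$tau_e_min
    rec_end <- rec_start + cfg$recovery_min
    a_rec <- al * cfg$cyto_mar_factor
    segs[[length(segs) + 1]] <- c(t_g2m, burst_end, ab, ab)
    segs[[length(segs) + 1]] <- c(burst_end, t_ma, ab, 0)
    segs[[length(segs) + 1]] <- c(t_ma, rec_start, 0, 0)
    segs[[length(segs) + 1]] <- c(rec_start, rec_end, 0, a_rec)
    cursor <- rec_end
  }
  if (cfg$scenario != "prometaphase_arrest" && cursor < horizon) {
    segs[[length(segs) + 1]] <- c(cursor, horizon, al, al)
  }
  m <- do.call(rbind, segs)
  tibble::tibble(t0 = m[, 1], t1 = m[, 2], a0 = m[, 3], a1 = m[, 4])
}

# cumulative integral of the piecewise-linear profile at arbitrary times
.profile_integral <- function(tvec, segs) {
  seg_int <- (segs$a0 + segs$a1) / 2 * (segs$t1 - segs$t0)
  cum <- c(0, cumsum(seg_int))
  idx <- findInterval(tvec, segs$t0, rightmost.closed = FALSE)
  idx <- pmax(pmin(idx, nrow(segs)), 1)
  t0 <- segs$t0[idx]
  t1 <- segs$t1[idx]
  a0 <- segs$a0[idx]
  a1 <- segs$a1[idx]
  dt <- pmin(pmax(tvec - t0, 0), t1 - t0)
  a_t <- a0 + (a1 - a0) * dt / (t1 - t0)
  cum[idx] + (a0 + a_t) / 2 * dt
}

# ---- auxiliary channels ---------------------------------------------------

#' Synthesize node-deviation and FUCCI reporter channels
#'
#' Node deviation: plateau, linear decrease starting at mitotic entry, a
#' sharp drop at the M/A transition, low through cytokinesis, recovery
#' after abscission. FUCCI (mAG-hGeminin): off in G1, accumulating through
#' S/G2 to a plateau, exponential degradation (configurable half-life)
#' from the M/A transition. Gaussian noise on both.
#'
#' @param time_min Sample times, minutes.
#' @param events Truth events tibble (columns `t_g2m`, `t_ma`,
#'   `t_abscission`; `NA` allowed for missing events in arrest scenarios).
#' @param cfg A [synth_config()].
#' @return Tibble with `node_pg` and `fucci_au` aligned with `time_min`.
#' @export
synthesize_channels <- function(time_min, events, cfg) {
  np <- cfg$node_plateau_pg
  node <- rep(np, length(time_min))
  fucci <- rep(5, length(time_min))
  for (k in seq_len(nrow(events))) {
    g2m <- events$t_g2m[k]
    ma <- events$t_ma[k]
    ab <- events$t_abscission[k]
    b <- events$t_birth[k]
    Tk <- if (is.na(ab)) 9 * 60 else ab - b
    # FUCCI accumulation through S/G2
    rise0 <- b + 0.3 * Tk
    rise1 <- b + 0.6 * Tk
    sel <- time_min >= rise0 & time_min < rise1
    fucci[sel] <- 5 + (cfg$fucci_plateau_au - 5) *
      (time_min[sel] - rise0) / (rise1 - rise0)
    sel <- time_min >= rise1 & time_min < (if (is.na(ma)) Inf else ma)
    fucci[sel] <- cfg$fucci_plateau_au
    if (!is.na(ma)) {
      sel <- time_min >= ma
      fucci[sel] <- pmax(
        cfg$fucci_plateau_au * 2^(-(time_min[sel] - ma) / cfg$fucci_halflife_min),
        5
      )
    }
    # node deviation
    if (!is.na(g2m)) {
      end_dec <- if (is.na(ma)) max(time_min) else ma
      sel <- time_min >= g2m & time_min < end_dec
      node[sel] <- np - 0.5 * np * (time_min[sel] - g2m) / (end_dec - g2m)
    }
    if (!is.na(ma)) {
      drop_end <- ma + 2
      sel <- time_min >= ma & time_min < drop_end
      node[sel] <- 0.5 * np + (-np - 0.5 * np) * (time_min[sel] - ma) / 2
      sel <- time_min >= drop_end & time_min < ab
      node[sel] <- -np
      sel <- time_min >= ab & time_min < ab + 20
      node[sel] <- -np + 2 * np * (time_min[sel] - ab) / 20
    }
  }
  tibble::tibble(
    node_pg = node + stats::rnorm(length(node), 0, cfg$node_noise_pg),
    fucci_au = pmax(
      fucci + stats::rnorm(length(fucci), 0, cfg$fucci_noise_au), 0
    )
  )
}

# ---- lineage simulation ---------------------------------------------------

#' Simulate a multi-generation lineage with ground truth
#'
#' Generates the buoyant-mass trace of one tracked lineage: in each
#' generation the cell grows with the piecewise MAR/mass profile of
#' [synth_config()], divides with its mass halved (small Gaussian
#' asymmetry; one daughter retained), and the next generation continues.
#' Optionally the cytokinetic elongation bias is applied to the measured
#' mass (see [inject_elongation_bias()]) and node-deviation / FUCCI
#' channels are emitted. Measurement noise is additive Gaussian. The
#' output is deterministic for a fixed `seed`.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @param cell_id Identifier for the lineage.
#' @return List with `trace` (tibble: `time_min`, `mass_pg`, optional
#'   `node_pg`, `fucci_au`), `truth` (list: `events` tibble with per-cycle
#'   event times/masses, `segments` profile table, `true_mass` the
#'   noise-free unbiased masses), and `config`.
#' @export
simulate_lineage <- function(cfg = synth_config(), seed = 1,
                             cell_id = "lineage_1") {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed)
  T_mean <- cfg$interdivision_hr * 60
  n_gen <- cfg$generations
  cycle_len <- stats::rnorm(n_gen, T_mean, cfg$interdivision_cv * T_mean)
  cycle_len <- pmax(cycle_len, cfg$cytokinesis_min + cfg$g2m_offset_min + 60)
  births <- cumsum(c(0, cycle_len[-n_gen]))
  .simulate_from_schedule(cfg, births, cycle_len, cell_id,
                          t_start = 0,
                          horizon = sum(cycle_len) + 30)
}

.simulate_from_schedule <- function(cfg, births, cycle_len, cell_id,
                                    t_start, horizon) {
  arrested <- cfg$scenario == "prometaphase_arrest"
  n_gen <- length(births)
  t_ma <- births + cycle_len - cfg$cytokinesis_min
  t_g2m <- t_ma - cfg$g2m_offset_min
  t_ab <- births + cycle_len
  if (arrested) {
    t_ma[] <- NA_real_
    t_ab[] <- NA_real_
  }
  segs <- .profile_segments(cfg, births, cycle_len, horizon)
  tgrid <- seq(t_start, horizon, by = cfg$sampling_min)
  logm <- log(cfg$birth_mass_pg) + .profile_integral(tgrid, segs) -
    .profile_integral(births[1], segs)
  # division steps
  frac <- 0.5 + stats::rnorm(n_gen, 0, cfg$division_asymmetry_sd)
  frac <- pmin(pmax(frac, 0.36), 0.64)
  mass_ab <- rep(NA_real_, n_gen)
  mass_birth <- rep(NA_real_, n_gen)
  mass_birth[1] <- cfg$birth_mass_pg
  if (!arrested) {
    for (k in seq_len(n_gen)) {
      la <- log(mass_birth[k]) + .profile_integral(t_ab[k], segs) -
        .profile_integral(births[k], segs)
      mass_ab[k] <- exp(la)
      step <- log(frac[k]) # retained daughter fraction
      logm[tgrid >= t_ab[k]] <- logm[tgrid >= t_ab[k]] + step
      if (k < n_gen) mass_birth[k + 1] <- mass_ab[k] * frac[k]
    }
  }
  true_mass <- exp(logm)
  ev_mass <- function(tt) {
    out <- rep(NA_real_, length(tt))
    ok <- !is.na(tt)
    if (any(ok)) {
      out[ok] <- stats::approx(tgrid, true_mass, xout = tt[ok], rule = 2)$y
    }
    out
  }
  events <- tibble::tibble(
    cell_id = cell_id,
    generation = seq_len(n_gen),
    t_birth = births,
    t_g2m = t_g2m,
    t_ma = t_ma,
    t_abscission = t_ab,
    mass_birth = mass_birth,
    mass_g2m = ev_mass(t_g2m),
    mass_ma = ev_mass(t_ma),
    mass_abscission = if (arrested) rep(NA_real_, n_gen) else mass_ab,
    loss_fraction = if (arrested) rep(NA_real_, n_gen) else 1 - frac
  )
  trace <- tibble::tibble(time_min = tgrid, mass_pg = true_mass)
  if (cfg$bias_injection && !arrested) {
    trace <- inject_elongation_bias(trace, events, cfg)
  }
  trace$mass_pg <- trace$mass_pg +
    stats::rnorm(nrow(trace), 0, cfg$noise_sd_pg)
  if (cfg$channels) {
    trace <- dplyr::bind_cols(
      trace, synthesize_channels(tgrid, events, cfg)
    )
  }
  list(
    trace = trace,
    truth = list(events = events, segments = segs, true_mass = true_mass),
    config = cfg
  )
}

#' Apply the forward elongation bias to a true mass trace
#'
#' Multiplies the true mass by the relative bias factor `kappa_rel(t)`
#' between each M/A transition and the corresponding abscission,
#' reproducing the momentary dip an elongating cell shows in the measured
#' trace. Exact inverse of [correct_trace()] for the same schedule: the
#' round-cell radius is derived from the median mass over the 10 min
#' preceding M/A, the same rule the correction uses.
#'
#' @param trace Tibble with `time_min`, `mass_pg` (true masses).
#' @param events Tibble with `t_ma`, `t_abscission` rows per cycle.
#' @param cfg A [synth_config()] (uses `tau_e_min`, `density_contrast`,
#'   `L_cant_um`).
#' @return `trace` with biased `mass_pg`.
#' @export
inject_elongation_bias <- function(trace, events, cfg = synth_config()) {
  out <- trace
  for (k in seq_len(nrow(events))) {
    t_ma <- events$t_ma[k]
    t_ab <- events$t_abscission[k]
    if (is.na(t_ma) || is.na(t_ab)) next
    sel <- out$time_min > t_ma & out$time_min < t_ab
    if (!any(sel)) next
    pre <- out$mass_pg[out$time_min <= t_ma & out$time_min >= t_ma - 10]
    R <- mass_to_radius(stats::median(pre), cfg$density_contrast)
    sch <- bias_schedule(out$time_min[sel], t_ma, cfg$tau_e_min, R,
                         cfg$L_cant_um)
    out$mass_pg[sel] <- out$mass_pg[sel] * sch$kappa_rel
  }
  out
}

#' Simulate a population of single-cycle M-phase traces
#'
#' Generates `cfg$n_cells` independent cells, each observed from late
#' interphase through abscission and 30 min into the newborn daughter --
#' the observation design of an SMR population experiment. Per-cell birth
#' masses are lognormally dispersed (`birth_mass_cv`). Each cell uses a
#' seed derived from `seed` and its index, so any cell can be regenerated
#' independently.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @param pre_g2m_min Observation starts this many minutes before mitotic
#'   entry.
#' @param post_abscission_min Observation ends this many minutes after
#'   abscission.
#' @return List with `traces` (long tibble, `cell_id` + trace columns),
#'   `events` (one truth row per cell) and `config`.
#' @export
simulate_population <- function(cfg = synth_config(), seed = 1,
                                pre_g2m_min = 150, post_abscission_min = 30) {
  stopifnot(inherits(cfg, "synth_config"))
  traces <- vector("list", cfg$n_cells)
  events <- vector("list", cfg$n_cells)
  for (i in seq_len(cfg$n_cells)) {
    seed_i <- (seed + 1009L * i) %% .Machine$integer.max
    set.seed(seed_i)
    Tk <- max(
      stats::rnorm(1, cfg$interdivision_hr * 60,
                   cfg$interdivision_cv * cfg$interdivision_hr * 60),
      cfg$cytokinesis_min + cfg$g2m_offset_min + pre_g2m_min + 30
    )
    m_birth <- cfg$birth_mass_pg *
      exp(stats::rnorm(1, 0, cfg$birth_mass_cv))
    cfg_i <- cfg
    cfg_i$birth_mass_pg <- m_birth
    cid <- sprintf("cell_%03d", i)
    t_g2m <- Tk - cfg$cytokinesis_min - cfg$g2m_offset_min
    sim <- .simulate_from_schedule(
      cfg_i, births = 0, cycle_len = Tk, cell_id = cid,
      t_start = max(0, t_g2m - pre_g2m_min),
      horizon = Tk + post_abscission_min
    )
    tr <- sim$trace
    tr$cell_id <- cid
    traces[[i]] <- tr
    events[[i]] <- sim$truth$events
  }
  list(
    traces = dplyr::bind_rows(traces),
    events = dplyr::bind_rows(events),
    config = cfg
  )
}

#' Analytic stage fractions implied by a simulator configuration
#'
#' Integrates the piecewise-linear MAR/mass profile in closed form to give
#' the true mass fractions accumulated in early mitosis and cytokinesis
#' (relative to half the abscission mass), the values the pipeline should
#' recover from simulated data.
#'
#' @param cfg A [synth_config()].
#' @return One-row tibble: `f_mitosis`, `f_cytokinesis`, `f_mphase`,
#'   `peak_increase_pct`.
#' @export
true_fractions <- function(cfg = synth_config()) {
  al <- cfg$alpha_interphase / 60
  decay_min <- cfg$g2m_offset_min - cfg$prophase_duration_min
  int_mit <- al * cfg$prophase_multiplier *
    (cfg$prophase_duration_min + decay_min / 2)
  rec_len <- min(cfg$cytokinesis_min - cfg$tau_e_min, cfg$recovery_min)
  a_rec <- al * cfg$cyto_mar_factor
  int_ck <- a_rec * rec_len^2 / (2 * cfg$recovery_min)
  if (cfg$cytokinesis_min - cfg$tau_e_min > cfg$recovery_min) {
    int_ck <- a_rec * cfg$recovery_min / 2 +
      a_rec * (cfg$cytokinesis_min - cfg$tau_e_min - cfg$recovery_min)
  }
  g_m <- exp(int_mit) - 1
  g_c <- exp(int_ck) - 1
  tibble::tibble(
    f_mitosis = 2 * g_m / ((1 + g_m) * (1 + g_c)),
    f_cytokinesis = 2 * g_c / (1 + g_c),
    f_mphase = 2 * g_m / ((1 + g_m) * (1 + g_c)) + 2 * g_c / (1 + g_c),
    peak_increase_pct = 100 * (cfg$prophase_multiplier - 1)
  )
}
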