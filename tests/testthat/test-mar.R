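# MAR estimation: stage fits, sliding windows, smoothing, peak comparison

test_that("stage and window slopes match the closed-form OLS oracle on
           1000 random windows", {
  set.seed(41)
  t <- seq(0, 600, by = 1)
  m <- 40 * exp(0.08 * t / 60) + stats::rnorm(length(t), 0, 0.05)
  tr <- tibble::tibble(time_min = t, mass_pg = m)
  for (i in 1:1000) {
    t0 <- stats::runif(1, 0, 550)
    t1 <- t0 + stats::runif(1, 6, 45)
    s <- stage_mar(tr, t0, t1)
    # oracle on the identical augmented point set
    inside <- t >= t0 & t <= t1
    xs <- c(t0, t[inside], t1)
    ys <- c(stats::approx(t, m, t0)$y, m[inside], stats::approx(t, m, t1)$y)
    keep <- !duplicated(xs)
    expect_equal(s$slope_pg_per_hr, oracle_slope(xs[keep], ys[keep]) * 60,
                 tolerance = 1e-9)
    expect_equal(s$mar_per_mass_per_hr,
                 s$slope_pg_per_hr / s$mean_mass_pg, tolerance = 1e-12)
  }
})

test_that("stage_mar interpolates exact boundary points and validates", {
  t <- 0:60
  tr <- tibble::tibble(time_min = t, mass_pg = 40 + 2 * t / 60)
  s <- stage_mar(tr, 2.5, 32.5)
  expect_equal(s$slope_pg_per_hr, 2, tolerance = 1e-12)
  expect_equal(s$n_points, 32) # 30 interior samples + 2 interpolated ends
  expect_error(stage_mar(tr, -5, 20), "outside")
  expect_error(stage_mar(tibble::tibble(time_min = c(0, 30, 60),
                                        mass_pg = c(40, 41, 42)), 5, 8),
               "sparse")
  # constant mass: zero slope
  expect_equal(stage_mar(tibble::tibble(time_min = t, mass_pg = rep(7, 61)),
                         5, 25)$slope_pg_per_hr, 0)
})

test_that("every 10-min window of a noiseless exponential recovers the
           specific growth rate within 0.5%", {
  tr <- exp_trace(alpha_hr = 0.08)
  w <- sliding_mar(tr, 10, 5)
  expect_true(all(abs(w$mar_per_mass_per_hr - 0.08) / 0.08 < 0.005))
  # high-resolution variant
  w2 <- sliding_mar(tr, 4, 2)
  expect_true(all(abs(w2$mar_per_mass_per_hr - 0.08) / 0.08 < 0.005))
})

test_that("window bookkeeping: counts, centres, linear-trace behaviour", {
  t <- 0:60
  tr <- tibble::tibble(time_min = t, mass_pg = 40 + t / 10)
  w <- sliding_mar(tr, 10, 5)
  expect_equal(nrow(w), 11)
  expect_equal(w$t_center_min, seq(5, 55, by = 5))
  expect_equal(w$slope_pg_per_hr, rep(6, 11), tolerance = 1e-12)
  # linear trace: equal slopes, mar/mass decreasing in time
  expect_true(all(diff(w$mar_per_mass_per_hr) < 0))
  expect_error(sliding_mar(tr[1:5, ], 10, 5), "shorter")
})

test_that("moving-average smoothing attenuates a spike tenfold and
           suppresses white noise by sqrt(window)", {
  t <- 0:99
  m <- rep(50, 100)
  m[50] <- 51
  sm <- smooth_trace(tibble::tibble(time_min = t, mass_pg = m), 10)
  expect_equal(sm$mass_pg[50] - 50, 0.1, tolerance = 1e-12)
  # constant trace unchanged
  smc <- smooth_trace(tibble::tibble(time_min = t, mass_pg = rep(5, 100)), 10)
  expect_equal(smc$mass_pg, rep(5, 100))
  set.seed(43)
  sds <- replicate(40, {
    y <- stats::rnorm(400, 0, 0.1)
    sm <- smooth_trace(tibble::tibble(time_min = seq_len(400), mass_pg = 50 + y),
                       10)
    stats::sd(sm$mass_pg[30:370])
  })
  expect_equal(mean(sds), 0.1 / sqrt(10), tolerance = 0.05)
})

test_that("identical dynamics in G2 and mitosis give zero peak increase", {
  tr <- exp_trace(alpha_hr = 0.08, t_end = 600)
  ann <- tibble::tibble(t_g2m_min = 400, t_ma_min = 430,
                        t_abscission_min = 480, tau_e_min = 12,
                        cell_id = "c")
  expect_equal(g2_vs_mitosis_peak(tr, ann), 0, tolerance = 0.5)
})

test_that("the prophase burst multiplier is recovered by the per-cell peak
           comparison on noiseless data", {
  cfg <- cfg_noiseless(n_cells = 1)
  sim <- simulate_population(cfg, seed = 51)
  truth <- sim$events
  ann <- tibble::tibble(t_g2m_min = truth$t_g2m, t_ma_min = truth$t_ma,
                        t_abscission_min = truth$t_abscission,
                        tau_e_min = 12, cell_id = truth$cell_id)
  inc <- g2_vs_mitosis_peak(sim$traces, ann)
  expect_equal(inc, 16, tolerance = 0.01) # percent, multiplier 1.16
})

test_that("normalize_to_control divides by the per-stage control mean", {
  ctrl <- tibble::tibble(stage = c("late_G2", "cytokinesis"),
                         control_mean = c(4, 2))
  sv <- tibble::tibble(stage = c("late_G2", "cytokinesis", "late_G2"),
                       slope_pg_per_hr = c(4, 1, 0))
  out <- normalize_to_control(sv, ctrl)
  expect_equal(out$normalized, c(1, 0.5, 0))
  expect_error(normalize_to_control(
    sv, tibble::tibble(stage = "late_G2", control_mean = 0)
  ), "zero control")
  expect_error(normalize_to_control(
    sv, tibble::tibble(stage = "late_G2", control_mean = 2)
  ), "without a control mean")
})

test_that("a synthetic cytokinesis-block scenario halves normalized
           cytokinesis MAR", {
  ctrl_cfg <- cfg_noiseless(n_cells = 6, bias_injection = FALSE)
  drug_cfg <- cfg_noiseless(n_cells = 6, scenario = "cytokinesis_block",
                            cyto_mar_factor = 0.5, bias_injection = FALSE)
  get_stages <- function(cfg, seed) {
    sim <- simulate_population(cfg, seed = seed)
    purrr::map_dfr(unique(sim$traces$cell_id), function(cid) {
      tr <- sim$traces[sim$traces$cell_id == cid, ]
      e <- sim$events[sim$events$cell_id == cid, ]
      ann <- tibble::tibble(t_g2m_min = e$t_g2m, t_ma_min = e$t_ma,
                            t_abscission_min = e$t_abscission,
                            tau_e_min = 12, cell_id = cid)
      stage_mar_table(tr, ann)
    })
  }
  ctrl <- get_stages(ctrl_cfg, 61)
  drug <- get_stages(drug_cfg, 71)
  cm <- dplyr::summarise(dplyr::group_by(ctrl, .data$stage),
                         control_mean = mean(.data$slope_pg_per_hr))
  norm <- normalize_to_control(drug, cm)
  ck <- norm$normalized[norm$stage == "cytokinesis"]
  expect_equal(mean(ck), 0.5, tolerance = 0.1)
  g2 <- norm$normalized[norm$stage == "late_G2"]
  expect_equal(mean(g2), 1, tolerance = 0.1)
})
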