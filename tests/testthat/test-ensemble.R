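# Population-level aggregation and hypothesis tests

test_that("mass_fractions computes the half-abscission normalisation and is
           scale invariant", {
  t <- 0:100
  m <- stats::approx(c(0, 40, 70, 100, 101), c(90, 94, 97, 100, 50),
                     xout = t)$y
  tr <- tibble::tibble(time_min = t, mass_pg = m)
  ann <- tibble::tibble(cell_id = "c", t_g2m_min = 40, t_ma_min = 70,
                        t_abscission_min = 101, tau_e_min = 12)
  f <- mass_fractions(tr, ann)
  expect_equal(f$total_accumulation_pg, 50)
  expect_equal(f$f_mitosis, 0.06)
  expect_equal(f$f_cytokinesis, 0.06)
  expect_equal(f$f_mphase, f$f_mitosis + f$f_cytokinesis)

  tr2 <- tr
  tr2$mass_pg <- tr$mass_pg * 3.7
  f2 <- mass_fractions(tr2, ann)
  expect_equal(f2$f_mitosis, f$f_mitosis, tolerance = 1e-12)
  expect_equal(f2$f_cytokinesis, f$f_cytokinesis, tolerance = 1e-12)

  # flat M-phase: zero fractions
  trf <- tibble::tibble(time_min = t, mass_pg = rep(80, 101))
  ff <- mass_fractions(trf, ann)
  expect_equal(ff$f_mitosis, 0)
  expect_equal(ff$f_cytokinesis, 0)
})

test_that("ensemble of identical cells equals any one cell with zero sd,
           and interpolation preserves sample values", {
  w1 <- tibble::tibble(cell_id = "a", t_center_min = seq(0, 200, 5),
                       mar_per_mass_per_hr = sin(seq(0, 200, 5) / 30) + 2)
  w2 <- w1
  w2$cell_id <- "b"
  ann <- tibble::tibble(cell_id = c("a", "b"), t_ma_min = c(100, 100),
                        t_g2m_min = c(70, 70))
  g <- align_to_ma(dplyr::bind_rows(w1, w2), ann, span = c(-90, 60))
  expect_equal(nrow(g), 100)
  expect_true(all(g$sd == 0))
  expect_equal(g$n[1], 2)
  # grid points that coincide with original samples reproduce them exactly
  on_grid <- g$rel_time_min %in% (w1$t_center_min - 100)
  ref <- stats::approx(w1$t_center_min - 100, w1$mar_per_mass_per_hr,
                       xout = g$rel_time_min[on_grid])$y
  expect_equal(g$mean[on_grid], ref, tolerance = 1e-12)

  # single cell: sd reported 0 with flag
  g1 <- align_to_ma(w1, ann[1, ], span = c(-90, 60))
  expect_true(attr(g1, "single_cell"))
  expect_true(all(g1$sd == 0))

  # a cell not covering the span is dropped and counted
  w3 <- w1[w1$t_center_min >= 60, ]
  w3$cell_id <- "c"
  ann3 <- dplyr::bind_rows(ann, tibble::tibble(cell_id = "c", t_ma_min = 100,
                                               t_g2m_min = 70))
  g3 <- align_to_ma(dplyr::bind_rows(w1, w2, w3), ann3, span = c(-90, 60))
  expect_equal(g3$n[1], 2)
  expect_equal(attr(g3, "n_dropped"), 1L)
})

test_that("entry-aligned averaging smooths per cell with a length-3 filter", {
  # impulse spreads to 1/3 over three windows
  w <- tibble::tibble(cell_id = "a", t_center_min = seq(0, 100, 5),
                      mar_per_mass_per_hr = 0)
  w$mar_per_mass_per_hr[w$t_center_min == 50] <- 1
  ann <- tibble::tibble(cell_id = "a", t_g2m_min = 50, t_ma_min = 80)
  g <- align_to_entry(w, ann, span = c(-40, 40), smoothing_length = 3)
  at0 <- which.min(abs(g$rel_time_min))
  expect_equal(g$mean[at0], 1 / 3, tolerance = 1e-9)
  # constant series unchanged
  wc <- w
  wc$mar_per_mass_per_hr <- 4
  gc <- align_to_entry(wc, ann, span = c(-40, 40))
  expect_true(all(abs(gc$mean - 4) < 1e-12))
})

test_that("an arrest scenario's ensemble reproduces the configured decay
           half-time", {
  cfg <- synth_config(n_cells = 8, scenario = "prometaphase_arrest",
                      arrest_decay_min = 150, channels = FALSE)
  sim <- simulate_population(cfg, seed = 81)
  wins <- purrr::map_dfr(unique(sim$traces$cell_id), function(cid) {
    w <- sliding_mar(sim$traces[sim$traces$cell_id == cid, ], 10, 5)
    w$cell_id <- cid
    w
  })
  ann <- tibble::tibble(cell_id = sim$events$cell_id,
                        t_g2m_min = sim$events$t_g2m)
  g <- align_to_entry(wins, ann, span = c(-30, 100))
  # MAR/mass halves (relative to the burst plateau) mid-decay:
  # burst ends 20 min after entry, decay spans 150 min
  target <- 0.08 * 1.16 / 2
  half_t <- g$rel_time_min[min(which(g$mean <= target))]
  expect_lt(abs(half_t - (20 + 75)), 10)
})

test_that("abscission-two normalisation scales traces and preserves
           fractions", {
  cfg <- cfg_noiseless(n_cells = 2)
  sim <- simulate_population(cfg, seed = 91)
  ann <- tibble::tibble(cell_id = sim$events$cell_id,
                        t_g2m_min = sim$events$t_g2m,
                        t_ma_min = sim$events$t_ma,
                        t_abscission_min = sim$events$t_abscission,
                        tau_e_min = 12)
  out <- normalize_abscission_two(sim$traces, ann)
  for (cid in unique(out$cell_id)) {
    oc <- out[out$cell_id == cid, ]
    a <- ann[ann$cell_id == cid, ]
    pre <- oc[oc$time_min < a$t_abscission_min, ]
    expect_equal(max(pre$mass_norm), 2, tolerance = 0.01)
    post <- oc[oc$time_min >= a$t_abscission_min, ]
    expect_equal(post$mass_norm[1], 1, tolerance = 0.05)
    f1 <- mass_fractions(oc[, c("time_min", "mass_pg")], a)
    oc2 <- oc
    oc2$mass_pg <- oc$mass_norm
    f2 <- mass_fractions(oc2[, c("time_min", "mass_pg")], a)
    expect_equal(f2$f_mphase, f1$f_mphase, tolerance = 1e-9)
  }
})

test_that("Welch t matches hand arithmetic and reduces to Student t for
           equal variances", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 3, 4, 5, 6)
  got <- welch_t_test(a, b)
  # closed-form Welch arithmetic
  se <- sqrt(stats::var(a) / 5 + stats::var(b) / 5)
  t_or <- (mean(a) - mean(b)) / se
  df_or <- (stats::var(a) / 5 + stats::var(b) / 5)^2 /
    ((stats::var(a) / 5)^2 / 4 + (stats::var(b) / 5)^2 / 4)
  expect_equal(got$t, t_or, tolerance = 1e-9)
  expect_equal(got$df, df_or, tolerance = 1e-9)
  expect_equal(got$p, 2 * stats::pt(-abs(t_or), df_or), tolerance = 1e-9)
  # symmetry
  rev <- welch_t_test(b, a)
  expect_equal(rev$t, -got$t)
  expect_equal(rev$p, got$p)
  # identical samples
  same <- welch_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # degenerate zero-variance pair
  z <- welch_t_test(rep(2, 3), rep(2, 4))
  expect_equal(z$p, 1)
})

test_that("one-way ANOVA F matches the sum-of-squares oracle and Tukey
           orders shifted groups first", {
  set.seed(101)
  g1 <- stats::rnorm(10, 0)
  g2 <- stats::rnorm(10, 0)
  g3 <- stats::rnorm(10, 3)
  vals <- c(g1, g2, g3)
  grp <- rep(c("a", "b", "c"), each = 10)
  got <- anova_tukey(vals, grp)
  # between/within mean squares computed independently
  gm <- mean(vals)
  ssb <- 10 * sum((tapply(vals, grp, mean) - gm)^2)
  ssw <- sum((vals - tapply(vals, grp, mean)[grp])^2)
  F_or <- (ssb / 2) / (ssw / 27)
  expect_equal(got$F, F_or, tolerance = 1e-9)
  expect_equal(got$p, stats::pf(F_or, 2, 27, lower.tail = FALSE),
               tolerance = 1e-9)
  # the shifted group has the smallest adjusted p-values
  pw <- got$pairwise
  involving_c <- grepl("c", pw$comparison)
  expect_true(max(pw$p_adj[involving_c]) < min(pw$p_adj[!involving_c]))
  # three identical groups
  same <- anova_tukey(rep(c(1, 2), 6), rep(c("a", "b", "c"), each = 4))
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_true(all(same$pairwise$p_adj == 1))
  expect_error(anova_tukey(1:3, c("a", "b", "c")), "at least")
})
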