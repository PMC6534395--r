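# Raw-signal processing: quartic refinement, transit detection, calibration

test_that("refine_minimum is exact on polynomial data", {
  # quartic with local minima at offsets +/- 1 around 0.1
  t <- seq(-1.15, 0.35, by = 0.05) + 0.1
  y <- (t - 0.1)^4 - 2 * (t - 0.1)^2
  r <- refine_minimum(t, y)
  expect_true(r$refined)
  expect_equal(r$t_min, 0.1 - 1, tolerance = 1e-9)
  expect_equal(r$f_min, -1, tolerance = 1e-9)

  # parabola
  t2 <- seq(1, 3, by = 0.1)
  r2 <- refine_minimum(t2, 5 + (t2 - 2)^2)
  expect_equal(r2$t_min, 2, tolerance = 1e-9)
  expect_equal(r2$f_min, 5, tolerance = 1e-9)
})

test_that("refine_minimum beats the sample spacing on noisy quartics", {
  set.seed(11)
  dt <- 0.01
  t <- seq(-0.15, 0.15, by = dt)
  reps <- vapply(1:100, function(i) {
    y <- 30 * t^2 - t^3 + 0.5 * t^4 + stats::rnorm(length(t), 0, 0.01)
    refine_minimum(t, y)$t_min
  }, numeric(1))
  expect_lt(stats::sd(reps), dt / 2)
})

test_that("refine_minimum requires a bracketed discrete minimum", {
  t <- seq(0, 1, by = 0.05)
  expect_error(refine_minimum(t, rep(1, length(t))), "bracket")
  expect_error(refine_minimum(t, t), "bracket")
})

test_that("a constructed double-dip transit is detected with two minima", {
  dt <- 1 / 3000
  t <- seq(0, 2, by = dt)
  f <- rep(1.1e6, length(t))
  # two Gaussian dips, node bump between, riding on a flat baseline
  f <- f - 3 * exp(-((t - 0.95) / 0.02)^2) - 3 * exp(-((t - 1.05) / 0.02)^2) +
    0.3 * exp(-((t - 1.0) / 0.01)^2)
  peaks <- detect_transits(tibble::tibble(time_s = t, frequency_hz = f),
                           threshold_hz = 1)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$min1_shift_hz, -3, tolerance = 0.01)
  expect_equal(peaks$min2_shift_hz, -3, tolerance = 0.01)
  expect_gt(peaks$node_shift_hz, 0)
  expect_lt(peaks$t_min1, peaks$t_min2)
})

test_that("a constant trace yields no transits and bad samples error", {
  t <- seq(0, 3, by = 1 / 3000)
  flat <- tibble::tibble(time_s = t, frequency_hz = rep(1.1e6, length(t)))
  expect_equal(nrow(detect_transits(flat, threshold_hz = 1)), 0)

  bad <- flat
  bad$frequency_hz[c(5, 9)] <- NaN
  expect_error(detect_transits(bad), "indices")
  expect_error(detect_transits(flat[1:10, ]), "insufficient baseline")
})

test_that("20 injected transits are all recovered at their scheduled times", {
  set.seed(3)
  sched <- tibble::tibble(t_s = seq(2, 59, by = 3)[1:20],
                          mass_pg = stats::runif(20, 30, 80))
  sig <- generate_raw_signal(sched, duration_s = 62, noise_sd_hz = 0.05)
  peaks <- detect_transits(sig)
  expect_equal(nrow(peaks), 20)
  mid <- (peaks$t_min1 + peaks$t_min2) / 2
  expect_true(all(abs(mid - (sched$t_s + 0.15)) < 0.010))
  # intervals disjoint and sorted
  expect_true(all(diff(peaks$t_enter) > 0))
  expect_true(all(peaks$t_enter[-1] > peaks$t_exit[-nrow(peaks)]))
})

test_that("bead calibration recovers the pg/Hz factor and flags
           polydisperse sets", {
  mk <- function(shifts) tibble::tibble(min1_shift_hz = shifts,
                                        min2_shift_hz = shifts)
  cal <- calibrate(mk(rep(-2, 5)), bead_buoyant_mass_pg = 50)
  expect_equal(cal$pg_per_hz, 25)
  expect_equal(cal$n_beads, 5)
  # doubling all shifts halves pg/Hz
  cal2 <- calibrate(mk(rep(-4, 5)), 50)
  expect_equal(cal2$pg_per_hz, cal$pg_per_hz / 2)
  # noisy beads stay within 1% of the noiseless value
  set.seed(5)
  cal3 <- calibrate(mk(-2 + stats::rnorm(30, 0, 0.02)), 50)
  expect_equal(cal3$pg_per_hz, 25, tolerance = 0.01)
  expect_error(calibrate(mk(c(-1, -2, -4)), 50), "polydisperse")
  expect_error(calibrate(mk(c(-2, -2)), 50), "at least 3")
})

test_that("buoyant mass and node deviation convert linearly", {
  cal <- calibrate(tibble::tibble(min1_shift_hz = rep(-2, 3),
                                  min2_shift_hz = rep(-2, 3)), 50)
  pk <- tibble::tibble(min1_shift_hz = -1.9, min2_shift_hz = -2.1,
                       node_shift_hz = 0.2)
  expect_equal(compute_buoyant_mass(pk, cal), 50)
  expect_equal(compute_node_deviation(pk, cal), 5)
  expect_error(
    compute_buoyant_mass(tibble::tibble(min1_shift_hz = -2,
                                        min2_shift_hz = 2), cal),
    "asymmetric"
  )
  # node deviation linear in injected amplitude, slope = pg_per_hz
  amps <- seq(-0.4, 0.4, by = 0.1)
  nd <- compute_node_deviation(tibble::tibble(node_shift_hz = amps), cal)
  expect_equal(oracle_slope(amps, nd), cal$pg_per_hz, tolerance = 1e-12)
})

test_that("round trip: simulated point masses are recovered through
           detection, refinement and calibration", {
  # calibration beads
  bead_sched <- tibble::tibble(t_s = seq(2, 14, by = 3), mass_pg = 50)
  bsig <- generate_raw_signal(bead_sched, duration_s = 17)
  cal <- calibrate(detect_transits(bsig), 50)
  expect_equal(cal$pg_per_hz, 25, tolerance = 1e-3)

  masses <- c(10, 40, 120, 200)
  sched <- tibble::tibble(t_s = seq(2, by = 3, length.out = length(masses)),
                          mass_pg = masses)
  peaks <- detect_transits(generate_raw_signal(sched, duration_s = 14))
  got <- compute_buoyant_mass(peaks, cal)
  expect_equal(got, masses, tolerance = 0.002) # 0.2% noiseless

  set.seed(8)
  peaks_n <- detect_transits(
    generate_raw_signal(sched, duration_s = 14, noise_sd_hz = 0.02)
  )
  expect_true(all(abs(compute_buoyant_mass(peaks_n, cal) - masses) < 0.1))
})

test_that("an extended doublet registers shallower than a sphere of equal
           mass by its relative bias factor", {
  sph <- geometry_at(0, 0, 12, 6)
  dbl <- geometry_at(20, 0, 12, 6)
  p_s <- detect_transits(generate_raw_peaks(80, geom = sph),
                         baseline_window_s = 0.5, threshold_hz = 0.5)
  p_d <- detect_transits(generate_raw_peaks(80, geom = dbl),
                         baseline_window_s = 0.5, threshold_hz = 0.5)
  k_rel <- bias_factor(line_density(dbl), 350) /
    bias_factor(line_density(sph), 350)
  depth_ratio <- mean(c(p_d$min1_shift_hz, p_d$min2_shift_hz)) /
    mean(c(p_s$min1_shift_hz, p_s$min2_shift_hz))
  expect_equal(depth_ratio, k_rel, tolerance = 1e-3)
})
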