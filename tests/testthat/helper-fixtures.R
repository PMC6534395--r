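# Small shared fixtures, built in code at test time.

# noiseless, channel-free configuration for exactness checks
cfg_noiseless <- function(...) {
  synth_config(noise_sd_pg = 0, channels = FALSE, division_asymmetry_sd = 0,
               interdivision_cv = 0, birth_mass_cv = 0, ...)
}

# independent closed-form OLS slope (sum formulas), the regression oracle
oracle_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# simple exponential-growth trace
exp_trace <- function(alpha_hr = 0.08, m0 = 30, t_end = 300, dt = 1) {
  t <- seq(0, t_end, by = dt)
  tibble::tibble(time_min = t, mass_pg = m0 * exp(alpha_hr * t / 60))
}
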