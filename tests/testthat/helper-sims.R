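# Shared fixtures: memoized scenario simulations and analytic test series.

.sim_cache <- new.env(parent = emptyenv())

scenario_sim <- function(name, stability, t_end = 140) {
  key <- paste(name, stability, t_end)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_reporter(scenario_params(name, stability),
                                           t_end = t_end)
  }
  .sim_cache[[key]]
}

scenario_series <- function(name, stability, t_end = 140) {
  as_lum_series(scenario_sim(name, stability, t_end), "L")
}

cosine_series <- function(t0 = 0, t1 = 130, A = 0.25, period = 26,
                          trough_h = 0, mean = 1, step = 1 / 3) {
  t <- seq(t0, t1, by = step)
  lum_series(t, mean * (1 - A * cos(2 * pi * (t - trough_h) / period)))
}

# Printed reference values of the simulation rhythm-property table
# (rows B, C, D, E).
printed_table <- data.frame(
  analysis = c("SIM_B", "SIM_C", "SIM_D", "SIM_E"),
  mean_st = c(14.3, 14.3, 14.3, 14.3),
  mean_unst = c(4.4, 4.4, 4.4, 4.4),
  mean_ratio = c(3.3, 3.3, 3.3, 3.2),
  amp_st = c(NA, 0.22, 0.06, 0.06),
  amp_unst = c(NA, 0.22, 0.15, 0.15),
  amp_ratio = c(NA, 1.00, 0.41, 0.41),
  phase_st = c(NA, 19.0, 13.7, 0.7),
  phase_unst = c(NA, 19.0, 15.7, 2.5),
  phase_diff = c(NA, 0.0, -2.0, -1.8))
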