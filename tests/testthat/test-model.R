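test_that("cosine modulation has the documented waveform and bounds", {
  om <- 2 * pi / 26
  expect_equal(modulation(0, 0.25, 0, om), 0.75)
  expect_equal(modulation(13, 0.25, 0, om), 1.25)
  expect_equal(modulation(c(-5, 0, 7, 100), 0, 1.2, om), rep(1, 4))
  t <- seq(0, 52, by = 0.1)
  m <- modulation(t, 0.4, 1, om)
  expect_true(all(m >= 0.6 - 1e-12 & m <= 1.4 + 1e-12))
  expect_equal(modulation(t + 26, 0.4, 1, om), m)
  expect_error(modulation(0, 1.5), "\\[0, 1\\]")
  expect_error(modulation(0, -0.1), "\\[0, 1\\]")
})

test_that("reporter derivative follows production minus degradation", {
  pB <- scenario_params("SIM_B", "stable")
  expect_equal(reporter_derivative(0, 0, pB), 1)
  expect_equal(reporter_derivative(37.7, pB$k / pB$gamma, pB), 0)
  pD <- scenario_params("SIM_D", "stable")
  expect_equal(reporter_derivative(0, 0, pD), 0.75)
  expect_error(reporter_derivative(0, -1, pB), ">= 0")
})

test_that("luminescence output scales the amount by the efficiency factor", {
  p <- model_params(gamma = 0.07, A_eff = 0.25)
  expect_equal(luminescence(0, 10, p), 7.5)
  p0 <- model_params(gamma = 0.07, eff0 = 2.5)
  expect_equal(luminescence(c(0, 5, 80), c(1, 2, 3), p0), 2.5 * c(1, 2, 3))
  expect_equal(luminescence(13, 1 / 0.07, p), 1.25 / 0.07, tolerance = 1e-12)
})

test_that("half-life matches known reporter stabilities", {
  expect_equal(half_life(0.23), 3.01, tolerance = 0.002)
  expect_equal(half_life(0.07), 9.90, tolerance = 0.001)
  expect_equal(half_life(log(2)), 1)
  expect_error(half_life(0), "positive")
})

test_that("simulated unmodulated kinetics match the exponential closed form", {
  for (gam in c(0.07, 0.23)) {
    p <- model_params(gamma = gam)
    tr <- simulate_reporter(p, t_end = 130)
    xeq <- p$k / gam
    expect_equal(tr$x[-1], (xeq * (1 - exp(-gam * tr$time_h)))[-1],
                 tolerance = 1e-8)
  }
  tr <- simulate_reporter(model_params(gamma = 0.07), t_end = 120)
  expect_equal(tr$x[tr$time_h == 120], (1 / 0.07) * (1 - exp(-0.07 * 120)),
               tolerance = 1e-9)
  expect_equal(round(tr$x[tr$time_h == 120], 3), 14.283)
  # pure decay when production is off
  pd <- model_params(k = 0, gamma = 0.23, x0 = 5)
  trd <- simulate_reporter(pd, t_end = 26)
  expect_equal(trd$x, 5 * exp(-0.23 * trd$time_h), tolerance = 1e-9)
})

test_that("simulate validates its time arguments", {
  p <- model_params(gamma = 0.07)
  expect_error(simulate_reporter(p, t_end = -5), "positive")
  expect_error(simulate_reporter(p, t_end = 100, dt_sample = 0), "positive")
  expect_error(simulate_reporter(p, t_end = 100.1, dt_sample = 1 / 3),
               "divide")
})

test_that("trajectories scale linearly in the production rate", {
  base <- scenario_sim("SIM_E", "unstable")
  p2 <- scenario_params("SIM_E", "unstable")
  p2$k <- 3.7 * p2$k
  tr2 <- simulate_reporter(p2)
  expect_equal(tr2$x, 3.7 * base$x, tolerance = 1e-14)
  expect_equal(tr2$L, 3.7 * base$L, tolerance = 1e-14)
})

test_that("all scenarios keep amount and luminescence non-negative and settle into a 26-h cycle", {
  for (nm in c("SIM_B", "SIM_C", "SIM_D", "SIM_E")) {
    for (st in c("stable", "unstable")) {
      tr <- scenario_sim(nm, st)
      expect_true(all(tr$x >= 0) && all(tr$L >= 0),
                  info = paste(nm, st, "positivity"))
      # after ~100 h the x0 = 0 transient has decayed below 1e-3 even for
      # the stable luciferase (exp(-0.07 * 100) ~ 9e-4)
      late <- tr$time_h >= 100 & tr$time_h <= 114
      shifted <- tr$x[match(round(tr$time_h[late] + 26, 9),
                            round(tr$time_h, 9))]
      expect_lt(max(abs(shifted - tr$x[late]) / tr$x[late]), 1e-3)
    }
  }
})

test_that("without modulation the late window sits at the k/gamma equilibrium", {
  for (gam in c(0.07, 0.23)) {
    tr <- simulate_reporter(model_params(gamma = gam))
    sel <- tr$time_h >= 93 & tr$time_h <= 119
    expect_lt(max(abs(tr$x[sel] - 1 / gam)) / (1 / gam), 0.002)
  }
})

test_that("production-rhythm linearisation gives the expected equilibrium amplitude and lag", {
  om <- 2 * pi / 26
  expect_equal(amount_rhythm_linear(0.25, 0.07, om)$relative_amplitude,
               0.0696, tolerance = 1e-3)
  expect_equal(amount_rhythm_linear(0.25, 0.23, om)$relative_amplitude,
               0.1723, tolerance = 1e-3)
  expect_equal(amount_rhythm_linear(0.25, 0.07, om)$lag_h, 5.33,
               tolerance = 1e-3)
  # the closed form itself shows that amplitude and lag at equilibrium
  p <- scenario_params("SIM_D", "stable")
  t <- seq(104, 130, by = 1 / 3)
  x <- closed_form_production(p, t)$x
  xeq <- p$k / p$gamma
  expect_equal((max(x) - min(x)) / 2 / xeq, 0.0696, tolerance = 2e-3)
})

test_that("degradation-rhythm quadrature reduces to the closed form when A_deg = 0", {
  p <- model_params(gamma = 0.23)
  t <- seq(0, 60, by = 1)
  q <- quadrature_degradation(p, t)
  expect_equal(q$x, (1 / 0.23) * (1 - exp(-0.23 * t)), tolerance = 1e-9)
})

test_that("oracles reject parameter sets outside their regime", {
  expect_error(closed_form_efficiency(scenario_params("SIM_D", "stable"),
                                      0:10), "A_prod")
  expect_error(closed_form_production(scenario_params("SIM_C", "stable"),
                                      0:10), "A_eff")
  expect_error(quadrature_degradation(scenario_params("SIM_D", "stable"),
                                      0:10), "A_prod")
})

test_that("degradation-rhythm oracle reproduces the published stable/unstable mean ratio", {
  t <- seq(0, 140, by = 1 / 3)
  qs <- quadrature_degradation(scenario_params("SIM_E", "stable"), t)
  qu <- quadrature_degradation(scenario_params("SIM_E", "unstable"), t)
  sel <- t >= 93 - 1e-9 & t <= 119 + 1e-9
  expect_equal(mean(qs$L[sel]) / mean(qu$L[sel]), 3.2, tolerance = 0.02)
})

test_that("model parameters validate and round-trip through the config format", {
  expect_error(model_params(gamma = 0), "gamma")
  expect_error(model_params(A_prod = 1.2), "A_prod")
  expect_error(model_params(x0 = -1), "x0")
  expect_error(model_params(eff0 = 0), "eff0")
  p <- model_params(k = 2, gamma = 0.11, A_deg = 0.3, phi_deg = 1.2,
                    eff0 = 0.5, x0 = 4)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_params_config(p, path)
  p2 <- read_params_config(path)
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-12)
})
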