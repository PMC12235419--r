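test_that("centred moving average is exact on constants and restricted to the valid region", {
  t <- seq(0, 60, by = 1 / 3)
  ts <- lum_series(t, rep(3.7, length(t)))
  ma <- moving_average(ts, 26)
  expect_equal(ma$value, rep(3.7, nrow(ma)))
  expect_equal(range(ma$time_h), c(13, 47), tolerance = 1e-9)
  expect_equal(nrow(ma), length(t) - 78L)
  expect_error(moving_average(lum_series(seq(0, 20, 1 / 3),
                                         rep(1, 61)), 26), "window")
  expect_error(moving_average(ts, 13.5), "multiple")
})

test_that("one-period moving average nearly cancels a 26-h cosine", {
  ts <- cosine_series(0, 130, A = 0.25)
  ma <- moving_average(ts, 26)
  expect_lt(max(abs(ma$value - 1)), 0.25 * 0.013)
})

test_that("moving average of the unmodulated stable trajectory approaches equilibrium", {
  ma <- moving_average(scenario_series("SIM_B", "stable"), 26)
  at106 <- ma$value[which.min(abs(ma$time_h - 106))]
  expect_equal(at106, 14.28, tolerance = 0.001)
})

test_that("relative values normalise constants to one and are scale invariant", {
  t <- seq(0, 60, by = 1 / 3)
  ts <- lum_series(t, rep(5, length(t)))
  rel <- relative_series(ts)
  expect_equal(rel$value, rep(1, length(t) - 78L))
  sc <- scenario_series("SIM_D", "unstable")
  r1 <- relative_series(sc)
  r2 <- relative_series(lum_series(sc$time_h, 137.2 * sc$value))
  expect_equal(r1$value, r2$value, tolerance = 1e-13)
  zero <- lum_series(t, c(rep(0, 40), rep(1, 21), rep(0, length(t) - 61)))
  expect_error(relative_series(zero), "zero")
})

test_that("smoothing preserves constants and attenuates a 26-h cosine by the Dirichlet factor", {
  t <- seq(0, 104, by = 1 / 3)
  expect_equal(smooth_series(lum_series(t, rep(2, length(t))))$value,
               rep(2, length(t) - 20L))
  sm <- smooth_series(cosine_series(0, 130, A = 0.25), window_h = 7)
  mid <- sm[sm$time_h >= 26 & sm$time_h <= 104, ]
  expect_equal((max(mid$value) - min(mid$value)) / 2,
               0.25 * cosine_attenuation(21), tolerance = 2e-3)
  expect_equal(0.25 * cosine_attenuation(21), 0.221, tolerance = 2e-3)
  # zero-phase: peak times untouched
  ex_raw <- detect_extrema(cosine_series(13, 117, A = 0.25))
  ex_sm <- detect_extrema(sm)
  pk_raw <- ex_raw$time_h[ex_raw$kind == "peak" & ex_raw$time_h < 100]
  pk_sm <- ex_sm$time_h[ex_sm$kind == "peak" & ex_sm$time_h < 100 &
                          ex_sm$time_h > 16]
  expect_true(all(abs(pk_sm - pk_raw[seq_along(pk_sm)]) < 0.05))
  expect_error(smooth_series(cosine_series(), n_samples = 20), "odd")
})

test_that("extrema of a sampled cosine are found at analytic times with sub-sample accuracy", {
  ex <- detect_extrema(cosine_series(13, 130, A = 0.25))
  expect_true(all(abs(ex$time_h[ex$kind == "trough"] -
                        c(26, 52, 78, 104)) < 0.05))
  expect_true(all(abs(ex$time_h[ex$kind == "peak"] -
                        c(39, 65, 91, 117)) < 0.05))
  expect_equal(ex$value[ex$kind == "trough"], rep(0.75, 4), tolerance = 1e-3)
  # kinds alternate
  expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]))
  expect_error(detect_extrema(lum_series(1:4, c(1, 2, 1, 2))), "5 samples")
})

test_that("extrema alternate on every scenario relative series", {
  for (nm in c("SIM_C", "SIM_D", "SIM_E")) {
    for (st in c("stable", "unstable")) {
      ex <- detect_extrema(smooth_series(relative_series(
        scenario_series(nm, st))))
      expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]),
                  info = paste(nm, st))
    }
  }
})

test_that("plateaus are reported at their midpoint and flagged", {
  t <- seq(0, 20, by = 1 / 3)
  v <- c(seq(0, 1, length.out = 20), rep(1.2, 5),
         seq(1, 0, length.out = length(t) - 25))
  ex <- detect_extrema(lum_series(t, v))
  expect_true(any(ex$plateau))
  pl <- ex[ex$plateau, ][1, ]
  expect_equal(pl$kind, "peak")
  expect_lt(abs(pl$time_h - t[23]), 0.01)
})

test_that("relative amplitude is half the trough-to-peak swing", {
  tr <- data.frame(time_h = 78, value = 0.75, kind = "trough")
  pk <- data.frame(time_h = 91, value = 1.25, kind = "peak")
  expect_equal(amplitude_half_swing(tr, pk), 0.25)
  expect_error(amplitude_half_swing(pk, tr), "trough and a peak")
  bad <- data.frame(time_h = 91, value = 0.5, kind = "peak")
  expect_error(amplitude_half_swing(tr, bad), "mislabeled")
})

test_that("phase is time since the most recent peak at the reference time", {
  ex <- structure(data.frame(time_h = c(26, 39, 52, 65, 78, 91),
                             value = c(0.75, 1.25, 0.75, 1.25, 0.75, 1.25),
                             kind = rep(c("trough", "peak"), 3),
                             plateau = FALSE),
                  class = c("extremum_list", "data.frame"))
  expect_equal(phase_since_last_peak(ex, 84), 19)
  expect_equal(phase_since_last_peak(ex, 65), 0)
  expect_error(phase_since_last_peak(ex[ex$time_h > 90, ], 84), "no peak")
})

test_that("window mean averages inclusive endpoints and validates its range", {
  t <- seq(80, 130, by = 1 / 3)
  ts <- lum_series(t, rep(2.5, length(t)))
  expect_equal(window_mean(ts), 2.5)
  ts2 <- lum_series(t, t)  # mean of the 79 grid points from 93 to 119
  expect_equal(window_mean(ts2), 106)
  expect_error(window_mean(lum_series(seq(95, 130, 1 / 3),
                                      rep(1, 106))), "outside")
})

test_that("phase differences wrap into half a period", {
  expect_equal(phase_difference(13.7, 15.7), -2)
  expect_equal(phase_difference(7.3, 7.3), 0)
  expect_equal(phase_difference(25, 1), -2)
  expect_equal(phase_difference(1, 25), 2)
  expect_equal(phase_difference(14, 1), 13)   # half-period maps to +13
})

test_that("rhythm_report measures the efficiency scenario at its analytic values", {
  rep_c <- rhythm_report(scenario_series("SIM_C", "stable"))
  expect_equal(rep_c$trough$time_h, 78, tolerance = 0.1)
  expect_equal(rep_c$peak$time_h, 91, tolerance = 0.1)
  # slightly above 0.25 x attenuation: the residual oscillation of the
  # one-period moving average adds ~1.3% to the relative amplitude
  expect_lt(abs(rep_c$relative_amplitude - 0.25 * cosine_attenuation(21)),
            0.005)
  expect_equal(rep_c$phase_at_ref, 19, tolerance = 0.05)
  expect_equal(rep_c$window_mean, 14.32, tolerance = 0.005)
})

test_that("series constructor rejects irregular grids naming the offending row", {
  t <- seq(0, 30, by = 1 / 3)
  t[40] <- t[40] + 0.05
  expect_error(lum_series(t, rep(1, length(t))), "row 40")
  expect_error(lum_series(c(0, 1, 1, 2), rep(1, 4)), "increasing")
})
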