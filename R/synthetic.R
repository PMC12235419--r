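#' Specification for the synthetic-data generator
#'
#' Collects every knob of the generator that emulates the standard duckweed
#' bioluminescence experiment: log-normal single-cell intensity sets and
#' replicate photomultiplier traces carrying a ~26-h cosine rhythm,
#' multiplicative log-normal noise, and an optional slow exponential decay
#' (the behaviour of an unstable, PEST-tagged reporter).
#'
#' @param n_cells Number of cells in an intensity set.
#' @param geometric_mean Geometric mean of cell intensities (photons/min).
#' @param geometric_sd Geometric standard deviation (> 1; ~3 is typical of
#'   single-cell reporter intensities spanning two decades).
#' @param trace_duration Trace length in hours. Default 96 h: with the
#'   26-h moving average plus 7-h smoothing the analyzable region loses
#'   about 16 h per end, and 96 h keeps both the trough near 59 h and its
#'   following peak measurable.
#' @param sample_step Sampling interval in hours (default 1/3 h = 20 min).
#' @param rhythm_amplitude Relative amplitude of the generated rhythm
#'   (0 <= A < 1).
#' @param rhythm_phase Trough-time offset in hours: troughs fall at
#'   `rhythm_phase + k * period`, peaks half a period later.
#' @param period Rhythm period in hours (default 26).
#' @param trend_decay_rate Exponential decay rate of the baseline (h^-1);
#'   0 for a stable reporter.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise.
#' @param baseline Mean trace intensity at t = 0 (photons/min).
#' @param n_replicates,n_experiments Replicate structure (traces per
#'   experiment, number of experiments).
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_cells = 225L, geometric_mean = 84.6,
                           geometric_sd = 3, trace_duration = 96,
                           sample_step = 1 / 3, rhythm_amplitude = 0.2,
                           rhythm_phase = 7.4, period = 26,
                           trend_decay_rate = 0, noise_cv = 0.05,
                           baseline = 100, n_replicates = 3L,
                           n_experiments = 3L, seed = 1L) {
  spec <- list(n_cells = as.integer(n_cells),
               geometric_mean = geometric_mean,
               geometric_sd = geometric_sd,
               trace_duration = trace_duration, sample_step = sample_step,
               rhythm_amplitude = rhythm_amplitude,
               rhythm_phase = rhythm_phase, period = period,
               trend_decay_rate = trend_decay_rate, noise_cv = noise_cv,
               baseline = baseline, n_replicates = as.integer(n_replicates),
               n_experiments = as.integer(n_experiments),
               seed = as.integer(seed))
  if (spec$geometric_mean <= 0) stop("'geometric_mean' must be > 0",
                                     call. = FALSE)
  if (spec$geometric_sd <= 1) stop("'geometric_sd' must be > 1",
                                   call. = FALSE)
  if (spec$rhythm_amplitude < 0 || spec$rhythm_amplitude >= 1)
    stop("'rhythm_amplitude' must lie in [0, 1)", call. = FALSE)
  if (spec$noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)
  if (spec$trace_duration < 2 * spec$period)
    stop("'trace_duration' must cover at least two periods", call. = FALSE)
  structure(spec, class = "generator_spec")
}

#' Draw a log-normal single-cell intensity set
#'
#' `n_cells` draws from a log-normal law with the requested geometric mean
#' and geometric SD (i.e. `log(x) ~ N(log(gm), log(gsd))`).
#'
#' @param spec A [generator_spec].
#' @return A list with `intensities` (positive vector) and `truth` (the
#'   generating parameters, one record).
#' @export
gen_cell_intensities <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  x <- stats::rlnorm(spec$n_cells, meanlog = log(spec$geometric_mean),
                     sdlog = log(spec$geometric_sd))
  list(intensities = x,
       truth = data.frame(what = "cells", n = spec$n_cells,
                          geometric_mean = spec$geometric_mean,
                          geometric_sd = spec$geometric_sd,
                          seed = spec$seed))
}

# One noisy trace on the 20-min grid; assumes the RNG state is already set.
trace_values <- function(spec) {
  t <- seq(0, spec$trace_duration, by = spec$sample_step)
  clean <- spec$baseline * exp(-spec$trend_decay_rate * t) *
    (1 - spec$rhythm_amplitude *
       cos(2 * pi * (t - spec$rhythm_phase) / spec$period))
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    eps <- stats::rlnorm(length(t), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    eps <- 1
  }
  lum_series(t, clean * eps)
}

#' Generate one synthetic photomultiplier trace
#'
#' `value(t) = B * exp(-delta * t) *
#'   (1 - A * cos(2 * pi * (t - phase) / period)) * eps(t)`
#' with `eps` multiplicative log-normal noise of coefficient of variation
#' `noise_cv` (unit mean), sampled every 20 min. Troughs of the noiseless
#' waveform fall at `phase + k * period`.
#'
#' @param spec A [generator_spec].
#' @return A list with `series` (a [lum_series]) and `truth` (one record
#'   of the generating amplitude, phase, period and trend).
#' @export
gen_trace <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  list(series = trace_values(spec),
       truth = data.frame(what = "trace",
                          amplitude = spec$rhythm_amplitude,
                          phase = spec$rhythm_phase, period = spec$period,
                          trend_decay_rate = spec$trend_decay_rate,
                          noise_cv = spec$noise_cv, seed = spec$seed))
}

#' Generate a replicate trace set (samples x experiments)
#'
#' Draws `n_replicates * n_experiments` traces from one [generator_spec];
#' replicate-to-replicate variation comes from the noise and from a mild
#' log-normal jitter (CV 20%) of each trace's baseline, mimicking
#' dish-to-dish differences in transfected cell number.
#'
#' @param spec A [generator_spec].
#' @return A list with `traces` (list of [lum_series]) and `truth` (one
#'   record per trace).
#' @export
gen_trace_set <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n_replicates * spec$n_experiments
  traces <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    s <- spec
    s$baseline <- spec$baseline * stats::rlnorm(1, -0.5 * log(1 + 0.2^2),
                                                sqrt(log(1 + 0.2^2)))
    traces[[i]] <- trace_values(s)
    truth[[i]] <- data.frame(what = "trace", trace = i,
                             baseline = s$baseline,
                             amplitude = s$rhythm_amplitude,
                             phase = s$rhythm_phase, period = s$period,
                             trend_decay_rate = s$trend_decay_rate,
                             noise_cv = s$noise_cv, seed = spec$seed)
  }
  list(traces = traces, truth = do.call(rbind, truth))
}

#' Synthetic two-reporter experiment bundle
#'
#' Emulates the paired stable/unstable reporter experiment: an ELuc-like
#' set (bright, no trend) and an ELuc-PEST-like set (dimmer, slow
#' exponential decay, rhythm leading by 0.6 h), each 3 samples x 3
#' experiments of constant-light trace, plus single-cell intensity sets
#' for both reporters. All generating parameters are returned as truth
#' records; the preset values are emulation choices, not measured
#' constants.
#'
#' @param preset Currently only `"EXP"`.
#' @param seed Integer seed.
#' @param noise_cv Trace noise level (default 0.05).
#' @return A list with `eluc` and `pest` (each with `traces`, `cells`,
#'   `truth`) and `preset`.
#' @export
gen_experiment_bundle <- function(preset = "EXP", seed = 1L,
                                  noise_cv = 0.05) {
  if (!identical(preset, "EXP"))
    stop("unknown preset: ", preset, call. = FALSE)
  mk <- function(gm, n_cells, amp, phase, trend, seed_off) {
    sp_tr <- generator_spec(geometric_mean = gm, n_cells = n_cells,
                            rhythm_amplitude = amp, rhythm_phase = phase,
                            trend_decay_rate = trend, noise_cv = noise_cv,
                            baseline = gm, seed = seed + seed_off)
    sp_ce <- sp_tr
    sp_ce$seed <- as.integer(seed + seed_off + 1L)
    set_tr <- gen_trace_set(sp_tr)
    cells <- gen_cell_intensities(sp_ce)
    list(traces = set_tr$traces, cells = cells$intensities,
         truth = list(traces = set_tr$truth, cells = cells$truth))
  }
  # troughs at 7.4 + 26k h -> third trough since release at 59.4 h;
  # the PEST-like rhythm leads by 0.6 h; its intensity roughly halves
  # over the monitored window.
  list(eluc = mk(84.6, 225L, 0.20, 7.4, 0, 0L),
       pest = mk(18.2, 69L, 0.24, 6.8, log(2) / 96, 100L),
       preset = preset)
}

#' Average relative series across replicate traces
#'
#' Computes the relative series (one-period moving-average normalisation)
#' of each trace and averages them pointwise — the replicate-averaging
#' convention for multi-sample photomultiplier experiments.
#'
#' @param traces List of [lum_series] on a common grid.
#' @param ma_window_h Moving-average window in hours.
#' @return A [lum_series] of mean relative values.
#' @export
average_relative_series <- function(traces, ma_window_h = 26) {
  rels <- lapply(traces, relative_series, window_h = ma_window_h)
  t0 <- rels[[1L]]$time_h
  for (r in rels[-1L])
    if (!isTRUE(all.equal(r$time_h, t0)))
      stop("traces are not on a common time grid", call. = FALSE)
  vals <- rowMeans(do.call(cbind, lapply(rels, `[[`, "value")))
  lum_series(t0, vals)
}

#' Rhythm analysis of a replicate trace set
#'
#' Averages the relative series of all traces, smooths, detects extrema,
#' and measures the amplitude at the trough nearest `trough_ref_h` (with
#' its following peak) plus that trough's refined time — the experiment-
#' style analysis where phases are referenced to a trough rather than to a
#' fixed clock time.
#'
#' @param traces List of [lum_series].
#' @param trough_ref_h Reference trough time in hours (default 59.4, the
#'   third trough after release into constant light).
#' @param ma_window_h,smooth_window_h Analysis windows in hours.
#' @return A list with `amplitude`, `trough_time`, `peak_time`,
#'   `extrema` and `mean_relative` (the averaged relative series).
#' @export
analyze_trace_set <- function(traces, trough_ref_h = 59.4,
                              ma_window_h = 26, smooth_window_h = 7) {
  rel <- average_relative_series(traces, ma_window_h)
  sm <- smooth_series(rel, smooth_window_h)
  ex <- detect_extrema(sm)
  troughs <- ex[ex$kind == "trough", , drop = FALSE]
  if (nrow(troughs) == 0L) stop("no extrema detected", call. = FALSE)
  tr <- pick_reference_trough(troughs, trough_ref_h, ma_window_h)
  pk <- following_peak(ex, tr, ma_window_h)
  list(amplitude = amplitude_half_swing(tr, pk),
       trough_time = tr$time_h, peak_time = pk$time_h,
       extrema = ex, mean_relative = rel)
}

#' Paired analysis of a synthetic experiment bundle
#'
#' Analyses both reporter trace sets of a [gen_experiment_bundle()] output
#' and assembles the stable/unstable comparison: geometric means of the
#' cell sets with their fold difference, relative amplitudes with their
#' ratio, trough-referenced phases (the stable reporter's trough defines
#' 0 h) and their difference, and the rhythm-factor classification.
#'
#' @param bundle Output of [gen_experiment_bundle()].
#' @param trough_ref_h Reference trough time in hours.
#' @return A list with `gm_st`, `gm_unst`, `fold`, `amp_st`, `amp_unst`,
#'   `amp_ratio`, `phase_st` (0 by convention), `phase_unst`,
#'   `phase_diff`, `label`.
#' @export
analyze_experiment_bundle <- function(bundle, trough_ref_h = 59.4) {
  st <- analyze_trace_set(bundle$eluc$traces, trough_ref_h)
  un <- analyze_trace_set(bundle$pest$traces, trough_ref_h)
  # trough-referenced phases: the stable reporter's trough is 0 h and the
  # unstable one's is measured against it (positive = earlier trough).
  phase_st <- 0
  phase_unst <- st$trough_time - un$trough_time
  amp_ratio <- st$amplitude / un$amplitude
  pd <- phase_difference(phase_st, phase_unst)
  list(gm_st = geometric_mean(bundle$eluc$cells),
       gm_unst = geometric_mean(bundle$pest$cells),
       fold = fold_difference(bundle$eluc$cells, bundle$pest$cells),
       amp_st = st$amplitude, amp_unst = un$amplitude,
       amp_ratio = amp_ratio,
       phase_st = phase_st, phase_unst = phase_unst, phase_diff = pd,
       label = classify_rhythm_factor(amp_ratio, pd))
}
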