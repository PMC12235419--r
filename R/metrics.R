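#' Centred one-period moving average
#'
#' Detrending baseline used to form relative values: at each time with a
#' full symmetric window inside the series, the arithmetic mean of the
#' `window_h / step + 1` samples in `[t - window_h/2, t + window_h/2]`
#' (79 samples for a 26-h window at 20-min sampling). Symmetric windows are
#' zero-phase, so the baseline never shifts peak or trough times. No edge
#' padding is applied: the output is restricted to the valid region and
#' loses `window_h / 2` at each end.
#'
#' @param ts A [lum_series].
#' @param window_h Window width in hours; must be an even multiple of the
#'   sampling step so that the sample count is odd. Default 26 h (one
#'   circadian period of the duckweed bioluminescence rhythm).
#' @return A [lum_series] on the valid region.
#' @export
moving_average <- function(ts, window_h = 26) {
  step <- series_step(ts)
  half <- window_h / (2 * step)
  if (abs(half - round(half)) > 1e-6)
    stop("'window_h' must be an even multiple of the sampling step",
         call. = FALSE)
  half <- as.integer(round(half))
  n <- 2L * half + 1L
  if (nrow(ts) < n)
    stop(sprintf("series spans %.3g h but the window needs %.3g h",
                 diff(range(ts$time_h)), window_h), call. = FALSE)
  ma <- stats::filter(ts$value, rep(1 / n, n), sides = 2)
  keep <- !is.na(ma)
  lum_series(ts$time_h[keep], as.numeric(ma[keep]))
}

#' Relative values: series normalised by its one-period moving average
#'
#' The detrended, dimensionless rhythm readout: each intensity divided by
#' the centred 26-h moving average at the same time point. Relative values
#' are invariant to any constant rescaling of the input and largely remove
#' slow trends such as the exponential decay of an unstable reporter, which
#' is what makes rhythms of reporters with very different absolute levels
#' directly comparable.
#'
#' @inheritParams moving_average
#' @return A [lum_series] of relative values on the valid region.
#' @export
relative_series <- function(ts, window_h = 26) {
  ma <- moving_average(ts, window_h)
  idx <- match(round(ma$time_h, 9), round(ts$time_h, 9))
  if (any(ma$value == 0))
    stop("moving average hits zero; relative values undefined", call. = FALSE)
  lum_series(ma$time_h, ts$value[idx] / ma$value)
}

#' Short centred smoothing before extremum detection
#'
#' A centred moving average over an odd number of samples spanning at most
#' `window_h` (21 samples for the default 7 h at 20-min sampling). A
#' symmetric linear filter is zero-phase — extremum times are untouched —
#' but attenuates a 26-h cosine by a known factor (~0.885 for the 21-sample
#' window), which is why measured relative amplitudes sit slightly below
#' the generating modulation amplitudes.
#'
#' @inheritParams moving_average
#' @param window_h Smoothing span in hours (default 7).
#' @param n_samples Optionally give the window directly as an odd sample
#'   count, overriding `window_h`.
#' @return A [lum_series] on the (shrunken) valid region.
#' @export
smooth_series <- function(ts, window_h = 7, n_samples = NULL) {
  step <- series_step(ts)
  if (is.null(n_samples)) {
    n_samples <- 2L * as.integer(window_h / (2 * step)) + 1L
  }
  if (n_samples %% 2L == 0L)
    stop("smoothing window must be an odd number of samples", call. = FALSE)
  if (nrow(ts) < n_samples)
    stop("series shorter than the smoothing window", call. = FALSE)
  sm <- stats::filter(ts$value, rep(1 / n_samples, n_samples), sides = 2)
  keep <- !is.na(sm)
  lum_series(ts$time_h[keep], as.numeric(sm[keep]))
}

#' Attenuation of a cosine under a centred discrete mean
#'
#' The factor by which an `n`-sample centred moving average scales a cosine
#' of the given period (the discrete Dirichlet kernel at the rhythm
#' frequency). Used to relate measured relative amplitudes back to
#' generating modulation amplitudes.
#'
#' @param n_samples Odd window length in samples.
#' @param period_h Cosine period in hours.
#' @param step_h Sampling interval in hours.
#' @return The attenuation factor in (0, 1].
#' @examples
#' cosine_attenuation(21)  # ~0.885: the default 7-h smoothing at 26 h
#' @export
cosine_attenuation <- function(n_samples, period_h = 26, step_h = 1 / 3) {
  th <- pi * step_h / period_h
  sin(n_samples * th) / (n_samples * sin(th))
}

#' Detect and refine peaks and troughs
#'
#' Candidate extrema are sign changes of the discrete first difference at
#' strict interior points; each candidate is refined by a least-squares
#' quadratic through the five samples centred on it, returning the vertex
#' time and value (sub-sample resolution, needed because circadian phases
#' are not multiples of the 20-min grid). Runs of three or more equal
#' samples are treated as a plateau: the midpoint is reported unrefined and
#' flagged. Entries alternate peak/trough by construction.
#'
#' @param ts A [lum_series] with at least 5 samples.
#' @return An `extremum_list`: a data frame with columns `time_h`, `value`,
#'   `kind` (`"peak"` or `"trough"`) and `plateau` (logical).
#' @export
detect_extrema <- function(ts) {
  if (nrow(ts) < 5L)
    stop("need at least 5 samples to detect extrema", call. = FALSE)
  t <- ts$time_h; v <- ts$value
  n <- length(v)
  s <- sign(diff(v))
  out_t <- numeric(0); out_v <- numeric(0)
  out_k <- character(0); out_p <- logical(0)
  last_sign <- 0
  i <- 1L
  while (i <= n - 1L) {
    if (s[i] == 0) { i <- i + 1L; next }
    if (last_sign != 0 && s[i] != last_sign) {
      # the extremum sits between the end of the previous run and here
      j <- i                       # first index of the new monotone run
      # previous nonzero difference ended at index `prev_end`
      prev_end <- j - 1L
      while (prev_end >= 1L && s[prev_end] == 0) prev_end <- prev_end - 1L
      lo <- prev_end + 1L          # first sample of the flat/turning stretch
      hi <- j                      # last sample before the new run moves
      kind <- if (last_sign > 0) "peak" else "trough"
      if (hi - lo >= 2L) {         # plateau of >= 3 equal samples
        mid <- (lo + hi) / 2
        idx <- as.integer(floor(mid))
        tm <- (t[as.integer(floor(mid))] + t[as.integer(ceiling(mid))]) / 2
        out_t <- c(out_t, tm); out_v <- c(out_v, v[idx])
        out_k <- c(out_k, kind); out_p <- c(out_p, TRUE)
      } else {
        ctr <- as.integer(round((lo + hi) / 2))
        ref <- refine_quadratic(t, v, ctr)
        out_t <- c(out_t, ref[1L]); out_v <- c(out_v, ref[2L])
        out_k <- c(out_k, kind); out_p <- c(out_p, FALSE)
      }
    }
    last_sign <- s[i]
    i <- i + 1L
  }
  structure(data.frame(time_h = out_t, value = out_v, kind = out_k,
                       plateau = out_p, stringsAsFactors = FALSE),
            class = c("extremum_list", "data.frame"))
}

# Least-squares quadratic vertex through the 5 samples centred on index ctr.
# Falls back to the grid sample when the full stencil is unavailable or the
# curvature degenerates.
refine_quadratic <- function(t, v, ctr) {
  n <- length(v)
  if (ctr < 3L || ctr > n - 2L) return(c(t[ctr], v[ctr]))
  u <- -2:2
  vv <- v[ctr + u]
  S0 <- sum(vv); S1 <- sum(u * vv); S2 <- sum(u^2 * vv)
  c1 <- S1 / 10
  c2 <- (S2 - 2 * S0) / 14
  c0 <- (S0 - 10 * c2) / 5
  if (c2 == 0) return(c(t[ctr], v[ctr]))
  ustar <- -c1 / (2 * c2)
  step <- t[ctr + 1L] - t[ctr]
  c(t[ctr] + ustar * step, c0 - c1^2 / (4 * c2))
}

#' Relative amplitude from a trough/peak pair
#'
#' Half the trough-to-peak swing of the relative-value series,
#' `(peak - trough) / 2` — the "relative amplitude" of a bioluminescence
#' rhythm.
#'
#' @param trough,peak Single rows of an `extremum_list` (or lists with
#'   `value` and `kind`).
#' @return The amplitude (dimensionless for relative series).
#' @export
amplitude_half_swing <- function(trough, peak) {
  if (!identical(as.character(trough$kind), "trough") ||
      !identical(as.character(peak$kind), "peak"))
    stop("arguments must be a trough and a peak, in that order",
         call. = FALSE)
  amp <- (peak$value - trough$value) / 2
  if (amp < 0)
    stop("peak value below trough value: mislabeled extrema", call. = FALSE)
  amp
}

#' Phase as time since the most recent peak
#'
#' The phase convention for simulated rhythms: the time elapsed at a fixed
#' reference time since the most recent peak of the (smoothed) relative
#' series.
#'
#' @param extrema An `extremum_list`.
#' @param t_ref Reference time in hours (default 84).
#' @return Hours since the last peak at or before `t_ref`.
#' @export
phase_since_last_peak <- function(extrema, t_ref = 84) {
  pk <- extrema$time_h[extrema$kind == "peak" & extrema$time_h <= t_ref]
  if (length(pk) == 0L)
    stop(sprintf("no peak at or before t_ref = %g h", t_ref), call. = FALSE)
  t_ref - max(pk)
}

#' Arithmetic mean over a fixed time window
#'
#' @param ts A [lum_series].
#' @param t0,t1 Window endpoints in hours, both inclusive (defaults 93 and
#'   119 — one 26-h period after transients have settled).
#' @return The mean of all samples with `t0 <= t <= t1`.
#' @export
window_mean <- function(ts, t0 = 93, t1 = 119) {
  eps <- 1e-9
  if (t0 < ts$time_h[1L] - eps || t1 > ts$time_h[nrow(ts)] + eps)
    stop(sprintf("window [%g, %g] h outside series [%g, %g] h",
                 t0, t1, ts$time_h[1L], ts$time_h[nrow(ts)]), call. = FALSE)
  sel <- ts$time_h >= t0 - eps & ts$time_h <= t1 + eps
  mean(ts$value[sel])
}

#' Difference of two phases, wrapped to half a period
#'
#' @param phase_a,phase_b Phases in hours (same reference time).
#' @param period_h Rhythm period in hours.
#' @return `phase_a - phase_b` wrapped into `(-period/2, period/2]`.
#' @export
phase_difference <- function(phase_a, phase_b, period_h = 26) {
  d <- phase_a - phase_b
  d <- d - period_h * round(d / period_h)
  if (d <= -period_h / 2) d <- d + period_h
  d
}

# deepest trough within half a period of the reference time (falls back to
# the nearest trough if none is that close)
pick_reference_trough <- function(troughs, trough_ref_h, period_h) {
  near <- troughs[abs(troughs$time_h - trough_ref_h) <= period_h / 2, ,
                  drop = FALSE]
  if (nrow(near) == 0L)
    return(troughs[which.min(abs(troughs$time_h - trough_ref_h)), ])
  near[which.min(near$value), ]
}

# highest peak within one period after the trough: the immediately
# following peak on clean series, robust to spurious wiggles on noisy ones
following_peak <- function(ex, trough, period_h) {
  pk <- ex[ex$kind == "peak" & ex$time_h > trough$time_h &
             ex$time_h <= trough$time_h + period_h, , drop = FALSE]
  if (nrow(pk) == 0L)
    stop("no peak follows the designated trough inside the valid region",
         call. = FALSE)
  pk[which.max(pk$value), ]
}

#' Full rhythm analysis of one luminescence series
#'
#' Runs the complete pipeline: one-period moving-average normalisation
#' (relative values), short centred smoothing, extremum detection with
#' sub-sample refinement, then the three rhythm properties: the window mean
#' of the raw series, the relative amplitude at a designated trough and the
#' immediately following peak, and the phase (time since the most recent
#' peak) at a reference time.
#'
#' The designated trough is by default the third trough inside the valid
#' region (`trough_index = 3`); for experiment-style analyses a reference
#' time can be given instead (`trough_ref_h`), selecting the deepest
#' detected trough within half a period of it. The paired peak is the
#' highest peak within one period after the designated trough, which on
#' noiseless series is simply the immediately following peak but is robust
#' to small spurious extrema on noisy replicate averages.
#'
#' @param ts A [lum_series] of raw luminescence.
#' @param ma_window_h Moving-average window in hours (default 26).
#' @param smooth_window_h Pre-extremum smoothing span in hours (default 7).
#' @param t_ref Phase reference time in hours (default 84).
#' @param mean_window Two-element window for the raw-intensity mean
#'   (default `c(93, 119)`).
#' @param trough_index Ordinal of the trough used for the amplitude.
#' @param trough_ref_h If non-`NULL`, select the trough nearest this time
#'   instead of by ordinal.
#' @return A `rhythm_report` list: `window_mean`, `relative_amplitude`,
#'   `phase_at_ref`, `trough`, `peak`, `extrema`, `valid_range`, and the
#'   settings used.
#' @export
rhythm_report <- function(ts, ma_window_h = 26, smooth_window_h = 7,
                          t_ref = 84, mean_window = c(93, 119),
                          trough_index = 3L, trough_ref_h = NULL) {
  wm <- if (is.null(mean_window)) NA_real_ else
    window_mean(ts, mean_window[1L], mean_window[2L])
  rel <- relative_series(ts, ma_window_h)
  sm <- smooth_series(rel, smooth_window_h)
  ex <- detect_extrema(sm)
  troughs <- ex[ex$kind == "trough", , drop = FALSE]
  if (nrow(troughs) == 0L)
    stop("no extrema detected", call. = FALSE)
  period_h <- ma_window_h
  tr <- if (is.null(trough_ref_h)) {
    if (nrow(troughs) < trough_index)
      stop(sprintf("only %d troughs in the valid region (need %d)",
                   nrow(troughs), trough_index), call. = FALSE)
    troughs[trough_index, ]
  } else {
    pick_reference_trough(troughs, trough_ref_h, period_h)
  }
  pk <- following_peak(ex, tr, period_h)
  structure(list(
    window_mean = wm,
    relative_amplitude = amplitude_half_swing(tr, pk),
    phase_at_ref = phase_since_last_peak(ex, t_ref),
    trough = tr, peak = pk, extrema = ex,
    valid_range = range(sm$time_h),
    settings = list(ma_window_h = ma_window_h,
                    smooth_window_h = smooth_window_h,
                    t_ref = t_ref, mean_window = mean_window)),
    class = "rhythm_report")
}

#' @export
print.rhythm_report <- function(x, ...) {
  cat("Rhythm report\n")
  cat(sprintf("  window mean        : %.4g\n", x$window_mean))
  cat(sprintf("  relative amplitude : %.4g (trough %.2f h -> peak %.2f h)\n",
              x$relative_amplitude, x$trough$time_h, x$peak$time_h))
  cat(sprintf("  phase at %g h      : %.2f h since last peak\n",
              x$settings$t_ref, x$phase_at_ref))
  cat(sprintf("  valid region       : [%.2f, %.2f] h, %d extrema\n",
              x$valid_range[1L], x$valid_range[2L], nrow(x$extrema)))
  invisible(x)
}
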