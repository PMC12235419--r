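#' Uniform-grid luminescence time series
#'
#' The unit of all analysis operations: a strictly increasing, uniformly
#' spaced time grid (hours; 20-min sampling in the standard photomultiplier
#' setup) with one finite intensity value per time point.
#'
#' @param time_h Times in hours, uniform grid.
#' @param value Intensities (arbitrary units or photons per minute).
#' @return An object of class `lum_series` (a data frame with columns
#'   `time_h` and `value`).
#' @examples
#' ts <- lum_series(seq(0, 52, by = 1 / 3), 10 + sin(seq(0, 52, by = 1 / 3)))
#' series_step(ts)
#' @export
lum_series <- function(time_h, value) {
  if (length(time_h) != length(value))
    stop("'time_h' and 'value' must have the same length", call. = FALSE)
  if (length(time_h) < 2L)
    stop("a series needs at least two samples", call. = FALSE)
  if (any(!is.finite(time_h)) || any(!is.finite(value)))
    stop("times and values must be finite", call. = FALSE)
  d <- diff(time_h)
  if (any(d <= 0))
    stop("'time_h' must be strictly increasing", call. = FALSE)
  if (max(d) - min(d) > 1e-6 * stats::median(d)) {
    bad <- which(abs(d - stats::median(d)) > 1e-6 * stats::median(d))[1L] + 1L
    stop(sprintf("irregular time grid at row %d (t = %g h)", bad, time_h[bad]),
         call. = FALSE)
  }
  structure(data.frame(time_h = time_h, value = value),
            class = c("lum_series", "data.frame"))
}

#' @rdname lum_series
#' @param ts A `lum_series`.
#' @return `series_step()` returns the sampling interval in hours.
#' @export
series_step <- function(ts) {
  stopifnot(is.data.frame(ts), nrow(ts) >= 2L)
  stats::median(diff(ts$time_h))
}

#' Extract the luminescence output of a trajectory as a series
#'
#' @param traj A `trajectory` from [simulate_reporter()] or one of the
#'   analytic oracles.
#' @param what `"L"` (luminescence, default) or `"x"` (luciferase amount).
#' @return A [lum_series].
#' @export
as_lum_series <- function(traj, what = c("L", "x")) {
  what <- match.arg(what)
  lum_series(traj$time_h, traj[[what]])
}
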