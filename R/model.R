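#' Cosine circadian modulation factor
#'
#' The multiplicative modulation applied to a rate or efficiency
#' coefficient: `1 - A * cos(omega * t - phi)`. With `A = 0.25`, `phi = 0`
#' and a 26-h period this is the relative-value waveform
#' `1 - 0.25 * cos(2 * pi * t / 26)` that an efficiency-only rhythm imprints
#' on the luminescence output at equilibrium.
#'
#' @param t Time in hours (vectorised).
#' @param A Relative amplitude, in `[0, 1]`.
#' @param phi Phase in radians.
#' @param omega Angular frequency in rad/h.
#' @return The dimensionless factor, in `[1 - A, 1 + A]`.
#' @examples
#' modulation(0, 0.25, 0, 2 * pi / 26)   # 0.75: trough at t = 0
#' modulation(13, 0.25, 0, 2 * pi / 26)  # 1.25: peak half a period later
#' @export
modulation <- function(t, A, phi = 0, omega = 2 * pi / 26) {
  if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A < 0 || A > 1)
    stop("'A' must be a single value in [0, 1]", call. = FALSE)
  1 - A * cos(omega * t - phi)
}

#' Instantaneous rate of change of the luciferase amount
#'
#' Right-hand side of the reporter ODE
#' `dx/dt = k * m_prod(t) - gamma * m_deg(t) * x`, where `m_prod` and
#' `m_deg` are the cosine modulations of the production and degradation
#' steps.
#'
#' @param t Time in hours.
#' @param x Luciferase amount (must be non-negative).
#' @param params A [model_params] object.
#' @return The rate `dx/dt` in amount per hour.
#' @export
reporter_derivative <- function(t, x, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(x < 0)) stop("'x' must be >= 0", call. = FALSE)
  params$k * modulation(t, params$A_prod, params$phi_prod, params$omega) -
    params$gamma * modulation(t, params$A_deg, params$phi_deg, params$omega) * x
}

#' Luminescence output for a given luciferase amount
#'
#' `L(t) = eff0 * m_eff(t) * x`, the measured photon flux when the
#' luminescence-efficiency step carries the modulation `m_eff`.
#'
#' @inheritParams reporter_derivative
#' @return Luminescence intensity (same vector shape as `x`).
#' @export
luminescence <- function(t, x, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(x < 0)) stop("'x' must be >= 0", call. = FALSE)
  params$eff0 * modulation(t, params$A_eff, params$phi_eff, params$omega) * x
}

new_trajectory <- function(times, x, L, params) {
  structure(data.frame(time_h = times, x = x, L = L),
            params = params, class = c("trajectory", "data.frame"))
}

#' Simulate the reporter model
#'
#' Integrates `dx/dt = k * m_prod(t) - gamma * m_deg(t) * x` from
#' `x(0) = x0` with a fixed-step classical Runge-Kutta (RK4) scheme and
#' evaluates the luminescence output on the sampling grid. The internal
#' integration step is `dt_sample / substeps`; the ODE is linear and
#' non-stiff at circadian rates, so the default 2-min internal step leaves
#' several orders of magnitude of headroom against the analytic solutions.
#'
#' @param params A [model_params] object.
#' @param t_end Simulation horizon in hours (default 140 h, so that
#'   one-period moving-average detrending remains valid through 127 h).
#' @param dt_sample Sampling interval in hours; default 1/3 h (20 min, the
#'   usual photomultiplier cadence).
#' @param substeps Internal RK4 steps per sampling interval.
#' @return A `trajectory`: a data frame with columns `time_h`, `x`
#'   (luciferase amount) and `L` (luminescence), carrying `params` as an
#'   attribute.
#' @examples
#' p <- model_params(gamma = 0.07)
#' tr <- simulate_reporter(p, t_end = 52)
#' tail(tr$x, 1)  # approaching k / gamma
#' @export
simulate_reporter <- function(params, t_end = 140, dt_sample = 1 / 3,
                              substeps = 10L) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(t_end) || t_end <= 0 || !is.numeric(dt_sample) ||
      dt_sample <= 0)
    stop("'t_end' and 'dt_sample' must be positive", call. = FALSE)
  n <- round(t_end / dt_sample)
  if (abs(n * dt_sample - t_end) > 1e-8)
    stop("'dt_sample' must divide 't_end'", call. = FALSE)
  h <- dt_sample / substeps
  times <- seq(0, by = dt_sample, length.out = n + 1L)
  k <- params$k; gam <- params$gamma; om <- params$omega
  Ap <- params$A_prod; pp <- params$phi_prod
  Ad <- params$A_deg; pd <- params$phi_deg
  f <- function(t, x) {
    k * (1 - Ap * cos(om * t - pp)) - gam * (1 - Ad * cos(om * t - pd)) * x
  }
  x <- numeric(n + 1L)
  x[1L] <- cur <- params$x0
  tcur <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(substeps)) {
      k1 <- f(tcur, cur)
      k2 <- f(tcur + h / 2, cur + h / 2 * k1)
      k3 <- f(tcur + h / 2, cur + h / 2 * k2)
      k4 <- f(tcur + h, cur + h * k3)
      cur <- cur + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tcur <- tcur + h
    }
    # realign to the exact grid to avoid drift in the cosine arguments
    tcur <- i * dt_sample
    x[i + 1L] <- cur
  }
  L <- params$eff0 * (1 - params$A_eff * cos(om * times - params$phi_eff)) * x
  new_trajectory(times, x, L, params)
}

# x(t) for constant production and degradation (A_prod = A_deg = 0)
x_unmodulated <- function(t, params) {
  xeq <- params$k / params$gamma
  xeq + (params$x0 - xeq) * exp(-params$gamma * t)
}

#' Exact trajectory for an efficiency-only rhythm
#'
#' Closed-form oracle when only the luminescence efficiency is rhythmic
#' (`A_prod = A_deg = 0`): the amount follows the unmodulated relaxation
#' `x(t) = k/gamma + (x0 - k/gamma) * exp(-gamma * t)` and the output is
#' `L = eff0 * (1 - A_eff * cos(omega * t - phi_eff)) * x`. After `x`
#' reaches equilibrium the relative value `L/x` equals the modulation
#' waveform itself, independent of the equilibrium magnitude — the
#' signature that makes efficiency-generated rhythms insensitive to
#' luciferase stability.
#'
#' @param params A [model_params] object with `A_prod = A_deg = 0`.
#' @param times Evaluation times in hours.
#' @return A `trajectory` data frame.
#' @export
closed_form_efficiency <- function(params, times) {
  stopifnot(inherits(params, "model_params"))
  if (params$A_prod != 0 || params$A_deg != 0)
    stop("closed_form_efficiency() requires A_prod = A_deg = 0", call. = FALSE)
  x <- x_unmodulated(times, params)
  L <- params$eff0 *
    (1 - params$A_eff * cos(params$omega * times - params$phi_eff)) * x
  new_trajectory(times, x, L, params)
}

#' Exact trajectory for a production-rate rhythm
#'
#' Closed-form oracle for sinusoidal forcing of the linear ODE
#' (`A_deg = A_eff = 0`):
#' `x(t) = k/gamma - (k * A_prod / sqrt(gamma^2 + omega^2)) *
#'   cos(omega * t - phi_prod - phi_lag) + C * exp(-gamma * t)`
#' with `phi_lag = atan(omega / gamma)` and `C` fixed by `x(0) = x0`. At
#' equilibrium the relative amplitude of `x` is
#' `A_prod * gamma / sqrt(gamma^2 + omega^2)` and its peak lags the
#' production modulation by `phi_lag / omega` hours — both depend on
#' `gamma`, which is why amount-mediated rhythms separate stable from
#' unstable luciferases.
#'
#' @param params A [model_params] object with `A_deg = A_eff = 0`.
#' @param times Evaluation times in hours.
#' @return A `trajectory` data frame.
#' @export
closed_form_production <- function(params, times) {
  stopifnot(inherits(params, "model_params"))
  if (params$A_deg != 0 || params$A_eff != 0)
    stop("closed_form_production() requires A_deg = A_eff = 0", call. = FALSE)
  gam <- params$gamma; om <- params$omega
  B <- params$k * params$A_prod / sqrt(gam^2 + om^2)
  phi_lag <- atan(om / gam)
  xeq <- params$k / gam
  C <- params$x0 - xeq + B * cos(params$phi_prod + phi_lag)
  x <- xeq - B * cos(om * times - params$phi_prod - phi_lag) +
    C * exp(-gam * times)
  L <- params$eff0 * x
  new_trajectory(times, x, L, params)
}

#' Equilibrium relative amplitude and peak lag of an amount rhythm
#'
#' For a rhythmic production rate the equilibrium oscillation of `x` has
#' relative amplitude `A * gamma / sqrt(gamma^2 + omega^2)` and its peaks
#' lag the forcing by `atan(omega / gamma) / omega` hours; a rhythmic
#' degradation rate yields the same magnitudes to first order in `A`.
#'
#' @param A Relative modulation amplitude of the rhythmic rate.
#' @param gamma Degradation rate coefficient (h^-1).
#' @param omega Angular frequency (rad/h).
#' @return A list with `relative_amplitude` and `lag_h`.
#' @export
amount_rhythm_linear <- function(A, gamma, omega = 2 * pi / 26) {
  list(relative_amplitude = A * gamma / sqrt(gamma^2 + omega^2),
       lag_h = atan(omega / gamma) / omega)
}

#' Quadrature trajectory for a degradation-rate rhythm
#'
#' Machine-precision oracle when only the degradation rate is rhythmic
#' (`A_prod = A_eff = 0`), via the integrating factor
#' `Gamma(t) = gamma * t - (gamma * A_deg / omega) *
#'   (sin(omega * t - phi_deg) + sin(phi_deg))`:
#' `x(t) = exp(-Gamma(t)) * (x0 + k * integral_0^t exp(Gamma(s)) ds)`,
#' with the integral evaluated piecewise by adaptive quadrature
#' (relative tolerance 1e-12 per panel).
#'
#' @param params A [model_params] object with `A_prod = A_eff = 0`.
#' @param times Evaluation times in hours, starting at 0 or later,
#'   increasing.
#' @return A `trajectory` data frame.
#' @export
quadrature_degradation <- function(params, times) {
  stopifnot(inherits(params, "model_params"))
  if (params$A_prod != 0 || params$A_eff != 0)
    stop("quadrature_degradation() requires A_prod = A_eff = 0", call. = FALSE)
  gam <- params$gamma; om <- params$omega
  Ad <- params$A_deg; pd <- params$phi_deg
  Gam <- function(t) gam * t - (gam * Ad / om) * (sin(om * t - pd) + sin(pd))
  # integrate exp(Gamma) piecewise between sample points; exp(Gamma(t))
  # grows like exp(gamma * t), so factor each panel by its left endpoint
  # to keep the quadrature well-scaled.
  knots <- c(0, times[times > 0])
  inc <- numeric(length(knots) - 1L)
  for (i in seq_along(inc)) {
    a <- knots[i]; b <- knots[i + 1L]
    g0 <- Gam(a)
    inc[i] <- exp(g0) * stats::integrate(function(s) exp(Gam(s) - g0),
                                         a, b, rel.tol = 1e-12,
                                         abs.tol = 0)$value
  }
  I <- c(0, cumsum(inc))
  Ifun <- I[match(pmax(times, 0), knots)]
  x <- exp(-Gam(times)) * (params$x0 + params$k * Ifun)
  L <- params$eff0 * x
  new_trajectory(times, x, L, params)
}
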