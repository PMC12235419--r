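#' Parameter set for the bioluminescence reporter model
#'
#' Bundles every coefficient of the reporter model: luciferase is produced at
#' mean rate `k` and degraded with mean first-order rate `gamma`; emitted
#' luminescence is `eff0` photons per unit enzyme. Each of the three steps
#' (production, degradation, luminescence efficiency) may carry a circadian
#' cosine modulation `1 - A * cos(omega * t - phi)` with relative amplitude
#' `A` in `[0, 1]` and phase `phi` (radians).
#'
#' @param k Mean production rate coefficient (amount h^-1).
#' @param gamma Mean degradation rate coefficient (h^-1). `0.07` corresponds
#'   to a stable luciferase (half-life ~10 h, ELuc-like), `0.23` to an
#'   unstable one (half-life ~3 h, ELuc-PEST-like).
#' @param A_prod,A_deg,A_eff Relative modulation amplitudes (dimensionless,
#'   each in `[0, 1]`) of production, degradation and luminescence efficiency.
#' @param phi_prod,phi_deg,phi_eff Modulation phases in radians.
#' @param omega Angular frequency (rad h^-1); default is a 26-h period.
#' @param eff0 Mean luminescence-efficiency coefficient (luminescence per
#'   unit luciferase).
#' @param x0 Initial luciferase amount.
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params(gamma = 0.07, A_eff = 0.25)
#' half_life(p$gamma)
#' @export
model_params <- function(k = 1, gamma = 0.07,
                         A_prod = 0, A_deg = 0, A_eff = 0,
                         phi_prod = 0, phi_deg = 0, phi_eff = 0,
                         omega = 2 * pi / 26, eff0 = 1, x0 = 0) {
  p <- list(k = k, gamma = gamma,
            A_prod = A_prod, A_deg = A_deg, A_eff = A_eff,
            phi_prod = phi_prod, phi_deg = phi_deg, phi_eff = phi_eff,
            omega = omega, eff0 = eff0, x0 = x0)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  for (nm in names(p)) num1(p[[nm]], nm)
  if (p$k < 0) stop("'k' must be >= 0", call. = FALSE)
  if (p$gamma <= 0) stop("'gamma' must be > 0", call. = FALSE)
  for (nm in c("A_prod", "A_deg", "A_eff"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", nm), call. = FALSE)
  if (p$omega <= 0) stop("'omega' must be > 0", call. = FALSE)
  if (p$eff0 <= 0) stop("'eff0' must be > 0", call. = FALSE)
  if (p$x0 < 0) stop("'x0' must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Bioluminescence reporter model parameters\n")
  cat(sprintf("  k = %g /h, gamma = %g /h (half-life %.2f h), eff0 = %g, x0 = %g\n",
              x$k, x$gamma, half_life(x$gamma), x$eff0, x$x0))
  cat(sprintf("  period = %.3g h (omega = %g rad/h)\n", 2 * pi / x$omega, x$omega))
  cat(sprintf("  A_prod = %g (phi %g), A_deg = %g (phi %g), A_eff = %g (phi %g)\n",
              x$A_prod, x$phi_prod, x$A_deg, x$phi_deg, x$A_eff, x$phi_eff))
  invisible(x)
}

#' Protein half-life from a first-order degradation rate
#'
#' @param gamma Degradation rate coefficient (h^-1), must be positive.
#' @return Half-life in hours, `log(2) / gamma`.
#' @examples
#' half_life(0.07)  # ~9.9 h, ELuc-like
#' half_life(0.23)  # ~3.0 h, ELuc-PEST-like
#' @export
half_life <- function(gamma) {
  if (!is.numeric(gamma) || any(!is.finite(gamma)) || any(gamma <= 0))
    stop("'gamma' must be positive", call. = FALSE)
  log(2) / gamma
}

#' Write / read model parameters as a flat key-value config
#'
#' The on-disk format is one `key = value` pair per line with keys exactly
#' `k, gamma, A_prod, A_deg, A_eff, phi_prod, phi_deg, phi_eff, omega, eff0,
#' x0`; phases are stored in radians. Lines starting with `#` are comments.
#'
#' @param params A [model_params] object.
#' @param path File to write to / read from.
#' @return `write_params_config()` returns `path` invisibly;
#'   `read_params_config()` returns a [model_params] object.
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  lines <- c("# biolumin model parameters (phases in radians)",
             sprintf("%s = %.15g", names(unclass(params)),
                     unlist(unclass(params))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  names(vals) <- keys
  do.call(model_params, as.list(vals))
}
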