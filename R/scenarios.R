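#' Parameter sets for the four simulation scenarios
#'
#' The standard in-silico experiment: a stable (`gamma = 0.07` h^-1) and an
#' unstable (`gamma = 0.23` h^-1) luciferase, `k = 1` h^-1, `x(0) = 0`,
#' 26-h period, phases zero, and exactly one rhythmic factor per scenario:
#'
#' * `SIM_B` — no rhythmic factor (all `A = 0`): baseline amounts.
#' * `SIM_C` — rhythmic luminescence efficiency (`A_eff = 0.25`).
#' * `SIM_D` — rhythmic production rate (`A_prod = 0.25`).
#' * `SIM_E` — rhythmic degradation rate (`A_deg = 0.25`).
#'
#' @param name Scenario name, one of `"SIM_B"`, `"SIM_C"`, `"SIM_D"`,
#'   `"SIM_E"`.
#' @param stability `"stable"` (gamma = 0.07) or `"unstable"`
#'   (gamma = 0.23).
#' @return A [model_params] object.
#' @examples
#' scenario_params("SIM_C", "stable")
#' @export
scenario_params <- function(name = c("SIM_B", "SIM_C", "SIM_D", "SIM_E"),
                            stability = c("stable", "unstable")) {
  name <- match.arg(name)
  stability <- match.arg(stability)
  gamma <- if (stability == "stable") 0.07 else 0.23
  A <- list(SIM_B = c(0, 0, 0), SIM_C = c(0, 0, 0.25),
            SIM_D = c(0.25, 0, 0), SIM_E = c(0, 0.25, 0))[[name]]
  model_params(k = 1, gamma = gamma,
               A_prod = A[1L], A_deg = A[2L], A_eff = A[3L],
               omega = 2 * pi / 26, eff0 = 1, x0 = 0)
}

#' Rhythm properties of the stable/unstable luciferase pair
#'
#' Simulates one scenario for both luciferase stabilities, analyses each
#' luminescence output with [rhythm_report()], and assembles the paired
#' comparison: window means with their St/Unst ratio, relative amplitudes
#' with their ratio, and phases with their difference. `SIM_B` has no
#' rhythm, so its amplitude and phase fields are `NA`.
#'
#' @inheritParams scenario_params
#' @param t_end Simulation horizon in hours.
#' @param t_ref Phase reference time in hours.
#' @param smooth_window_h Pre-extremum smoothing span in hours.
#' @return A `paired_result` list with elements `scenario`, `stable`,
#'   `unstable` (the two reports), `mean_ratio`, `amp_ratio`,
#'   `phase_diff`.
#' @export
run_scenario_pair <- function(name, t_end = 140, t_ref = 84,
                              smooth_window_h = 7) {
  name <- match.arg(name, c("SIM_B", "SIM_C", "SIM_D", "SIM_E"))
  analyse <- function(stability) {
    p <- scenario_params(name, stability)
    tr <- simulate_reporter(p, t_end = t_end)
    ts <- as_lum_series(tr, "L")
    if (name == "SIM_B") {
      list(window_mean = window_mean(ts),
           relative_amplitude = NA_real_, phase_at_ref = NA_real_)
    } else {
      rhythm_report(ts, t_ref = t_ref, smooth_window_h = smooth_window_h)
    }
  }
  st <- analyse("stable")
  un <- analyse("unstable")
  structure(list(
    scenario = name, stable = st, unstable = un,
    mean_ratio = st$window_mean / un$window_mean,
    amp_ratio = st$relative_amplitude / un$relative_amplitude,
    phase_diff = if (name == "SIM_B") NA_real_ else
      phase_difference(st$phase_at_ref, un$phase_at_ref)),
    class = "paired_result")
}

#' Rhythm-property table for all four scenarios
#'
#' Runs `SIM_B` through `SIM_E` with default settings and collects the nine
#' properties per scenario: raw-intensity window means (stable, unstable,
#' ratio), relative amplitudes (stable, unstable, ratio) and phases at the
#' reference time (stable, unstable, difference). Values are kept at full
#' precision; the print method displays them at the conventional precision
#' (means and phases to 1 decimal, amplitudes and ratios to 2).
#'
#' @inheritParams run_scenario_pair
#' @return A `sim_table` data frame with columns `analysis`, `mean_st`,
#'   `mean_unst`, `mean_ratio`, `amp_st`, `amp_unst`, `amp_ratio`,
#'   `phase_st`, `phase_unst`, `phase_diff`.
#' @examples
#' \donttest{
#' simulation_table()
#' }
#' @export
simulation_table <- function(t_end = 140, t_ref = 84, smooth_window_h = 7) {
  rows <- lapply(c("SIM_B", "SIM_C", "SIM_D", "SIM_E"), function(nm) {
    pr <- run_scenario_pair(nm, t_end = t_end, t_ref = t_ref,
                            smooth_window_h = smooth_window_h)
    data.frame(analysis = nm,
               mean_st = pr$stable$window_mean,
               mean_unst = pr$unstable$window_mean,
               mean_ratio = pr$mean_ratio,
               amp_st = pr$stable$relative_amplitude,
               amp_unst = pr$unstable$relative_amplitude,
               amp_ratio = pr$amp_ratio,
               phase_st = pr$stable$phase_at_ref,
               phase_unst = pr$unstable$phase_at_ref,
               phase_diff = pr$phase_diff)
  })
  structure(do.call(rbind, rows), class = c("sim_table", "data.frame"))
}

#' @export
print.sim_table <- function(x, ...) {
  d <- format_sim_table(x)
  cat("Circadian rhythm properties per scenario (StLUC gamma = 0.07, ",
      "UnstLUC gamma = 0.23)\n", sep = "")
  print.data.frame(d, row.names = FALSE)
  invisible(x)
}

#' Round a scenario table to its display precision
#'
#' Means, mean ratios and phases to 1 decimal; amplitudes and amplitude
#' ratios to 2 decimals.
#'
#' @param x A `sim_table`.
#' @return A plain data frame of rounded values.
#' @export
format_sim_table <- function(x) {
  d <- as.data.frame(x)
  for (cl in c("mean_st", "mean_unst", "mean_ratio",
               "phase_st", "phase_unst", "phase_diff"))
    d[[cl]] <- round(d[[cl]], 1)
  for (cl in c("amp_st", "amp_unst", "amp_ratio"))
    d[[cl]] <- round(d[[cl]], 2)
  d
}

#' Classify the rhythm-generating factor from paired rhythm properties
#'
#' An efficiency-generated rhythm leaves the relative values of stable and
#' unstable luciferases identical: amplitude ratio ~1 and phase difference
#' ~0. A rhythm mediated by luciferase amount (rhythmic production or
#' degradation) attenuates and delays the stable reporter: amplitude ratio
#' well below 1 and a phase delay of the stable luciferase. The thresholds
#' are tunable conventions, not measured constants.
#'
#' @param amplitude_ratio Stable/unstable relative-amplitude ratio (> 0).
#' @param phase_diff Stable-minus-unstable phase difference in hours.
#' @param ratio_threshold Minimum amplitude ratio for the efficiency call.
#' @param phase_threshold_h Maximum absolute phase difference (hours) for
#'   the efficiency call.
#' @return `"efficiency"`, `"amount-mediated"` or `"indeterminate"`.
#' @examples
#' classify_rhythm_factor(1.00, 0.0)   # efficiency
#' classify_rhythm_factor(0.41, -2.0)  # amount-mediated
#' @export
classify_rhythm_factor <- function(amplitude_ratio, phase_diff,
                                   ratio_threshold = 0.8,
                                   phase_threshold_h = 1.0) {
  if (!is.finite(amplitude_ratio) || amplitude_ratio <= 0)
    stop("'amplitude_ratio' must be positive", call. = FALSE)
  if (amplitude_ratio >= ratio_threshold &&
      abs(phase_diff) <= phase_threshold_h) {
    "efficiency"
  } else if (amplitude_ratio <= 0.6 && phase_diff <= -1.0) {
    "amount-mediated"
  } else {
    "indeterminate"
  }
}
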