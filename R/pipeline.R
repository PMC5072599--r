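#' Run the full estimation pipeline on one walking trial
#'
#' Sequences the stages end to end: stride segmentation from vertical GRF,
#' zero-lag low-pass filtering of kinematic (6 Hz) and kinetic (15 Hz)
#' channels, stride averaging onto a common grid, differentiation to angular
#' velocities and arch rate, inverse-dynamics ankle power, model calibration
#' (EMD, scaling, R^2), per-MTU decomposition, multiarticular FDHL power
#' accounting, Push-off metrics and the overestimation table, and optionally
#' the Monte Carlo sensitivity analysis. Deterministic for a given trial,
#' settings, and sensitivity seed.
#'
#' @param trial a `synthetic_trial` (from [simulate_trial()] or
#'   [read_trial()]).
#' @param muscles a `muscle_set`.
#' @param grid_points stride grid resolution (default 1000).
#' @param grf_threshold,min_stance stride-event detection settings
#'   ([detect_strides()]).
#' @param kinematic_cutoff,force_cutoff low-pass cutoffs, Hz, for kinematic
#'   and kinetic channels.
#' @param lag_grid optional EMD candidate lags, s.
#' @param sensitivity optional [sensitivity_config()]; `NULL` skips the Monte
#'   Carlo stage.
#' @param subject_id identifier carried into the report.
#' @param verbose print a line per stage.
#' @return object of class `run_report`: `fit`, `events`, `waveforms`,
#'   `decomposition`, `window`, `metrics`, `overestimates`, `sensitivity`,
#'   `provenance`.
#' @export
run_pipeline <- function(trial, muscles = make_muscle_set(),
                         grid_points = 1000L,
                         grf_threshold = 20, min_stance = 0.1,
                         kinematic_cutoff = 6, force_cutoff = 15,
                         lag_grid = NULL, sensitivity = NULL,
                         subject_id = "S1", verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  fs <- trial$sample_rate
  stage <- function(what, expr) tryCatch(expr, error = function(e)
    stop("pipeline stage [", what, "]: ", conditionMessage(e), call. = FALSE))

  events <- stage("segment", detect_strides(trial$grf_vertical, grf_threshold,
                                            min_stance, sample_rate = fs))
  Tstr <- stride_duration(events)
  to_pct <- 100 * toeoff_fraction(events)
  say("segment: %d strides, T = %.3f s, toe-off %.1f%%",
      n_complete_strides(events), Tstr, to_pct)

  lp <- function(v, fc) zero_lag_butterworth(v, fc, kind = "low", sample_rate = fs)
  avg <- function(v, units = "") stage("average",
    stride_average(v, events, grid_points, sample_rate = fs))
  env_wf <- lapply(trial$envelopes, avg)
  ank_wf <- avg(lp(trial$ankle_angle, kinematic_cutoff))
  mtp_wf <- avg(lp(trial$mtp_angle, kinematic_cutoff))
  arch_wf <- avg(lp(trial$arch_length, kinematic_cutoff))
  mom_wf <- avg(lp(trial$ankle_moment, force_cutoff))

  omega_ank <- differentiate(ank_wf, Tstr)
  omega_mtp <- differentiate(mtp_wf, Tstr)
  arch_rate <- differentiate(arch_wf, Tstr)
  p_ank <- stride_waveform(wf_values(mom_wf) * wf_values(omega_ank),
                           units = "W/kg")
  foot <- foot_kinematics(omega_mtp, arch_rate, omega_ank)

  fit <- stage("fit", fit_emg_model(env_wf, muscles, omega_ank, p_ank, Tstr,
                                    to_pct, lag_grid, speed = trial$speed,
                                    subject_id = subject_id))
  say("fit: EMD %.1f ms, C %.3f, R^2 %.4f", 1000 * fit$emd, fit$scaling,
      fit$r_squared)
  dec <- stage("decompose", decompose_ankle_power(fit, env_wf, muscles,
                                                  omega_ank, Tstr, p_ank = p_ank))
  d <- stage("compose", compose_decomposition(dec$pair, dec$forces, foot,
                                              muscles))
  window <- fit$window
  mass <- trial$subject_mass
  srcs <- list(inverse_dynamics = p_ank, p_ank_model = d$p_ank_model,
               p_mtu_min = d$p_mtu_min, p_mtu = d$p_mtu)
  metrics <- do.call(rbind, lapply(names(srcs), function(nm) {
    m <- pushoff_metrics(srcs[[nm]], window, Tstr, mass, nm)
    data.frame(source = nm, peak_power_W_per_kg = m$peak_power,
               work_J_per_kg = m$work, peak_power_W = m$peak_power_abs,
               work_J = m$work_abs, stringsAsFactors = FALSE)
  }))
  over <- stage("metrics", overestimate_report(d, window, Tstr, mass))
  sens <- NULL
  if (!is.null(sensitivity)) {
    say("sensitivity: %d iterations", sensitivity$n_iterations)
    sens <- stage("sensitivity", run_monte_carlo(
      env_wf, muscles, omega_ank, p_ank, foot, Tstr, to_pct,
      cfg = sensitivity, mass = mass))
  }
  structure(list(
    fit = fit, events = events,
    waveforms = list(envelopes = env_wf, omega_ank = omega_ank,
                     omega_mtp = omega_mtp, arch_rate = arch_rate,
                     p_ank = p_ank),
    decomposition = d, window = window, metrics = metrics,
    overestimates = over, sensitivity = sens,
    provenance = list(
      package = "mtupower",
      version = as.character(utils::packageVersion("mtupower")),
      subject_id = subject_id, speed = trial$speed,
      settings = list(grid_points = grid_points, grf_threshold = grf_threshold,
                      min_stance = min_stance,
                      kinematic_cutoff = kinematic_cutoff,
                      force_cutoff = force_cutoff,
                      sensitivity_seed = if (is.null(sensitivity)) NULL
                      else sensitivity$seed))
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$fit)
  cat(sprintf("  Push-off window %.1f-%.1f%% stride\n",
              x$window$start, x$window$end))
  ov <- x$overestimates
  for (r in seq_len(nrow(ov)))
    cat(sprintf("  P'_ank overestimates %s %s by %.2f%%\n",
                ov$target[r], ov$metric[r], ov$overestimate_pct[r]))
  if (!is.null(x$sensitivity)) print(x$sensitivity)
  invisible(x)
}
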