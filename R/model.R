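#' Unscaled MTU force from a normalized excitation envelope
#'
#' The force map evaluated with a unit scaling constant: the envelope is
#' delayed by `lag` on the periodic stride grid and multiplied by the muscle
#' gain `PCSA * cos(pennation)`. Multiplying by the trial scaling constant C
#' yields force in N/kg.
#'
#' @param envelope a [stride_waveform()] (normalized excitation).
#' @param muscle one row of a `muscle_set`.
#' @param lag electromechanical delay in seconds; must not exceed half a
#'   stride in magnitude.
#' @param stride_duration stride period, s.
#' @return a [stride_waveform()] in unscaled units (cm^2-weighted excitation).
#' @export
unscaled_force <- function(envelope, muscle, lag, stride_duration) {
  if (abs(lag) > stride_duration / 2)
    stop("parameter error: |lag| exceeds half a stride (", lag, " s)",
         call. = FALSE)
  shifted <- shift_waveform(envelope, lag, stride_duration)
  stride_waveform(muscle_gain(muscle) * wf_values(shifted),
                  units = "cm^2", n_strides = envelope$n_strides)
}

# internal: summed unscaled ankle moment, Sum_m gain_m * r_ankle_m * env_m(t),
# unshifted. One common lag applies to every muscle, so shifting this sum
# equals summing the shifted per-muscle moments.
summed_unscaled_moment <- function(envelopes, muscles) {
  v <- 0
  for (m in seq_len(nrow(muscles))) {
    nm <- muscles$name[m]
    e <- envelopes[[nm]]
    if (is.null(e)) stop("envelope missing for muscle '", nm, "'", call. = FALSE)
    v <- v + muscle_gain(muscles[m, ]) * muscles$r_ankle[m] * wf_values(e)
  }
  v
}

#' Model ankle power at unit scaling for a given lag
#'
#' `Sum_m gain_m * r_ankle_m * env_m(t - lag) * omega_ank(t)`; multiplying by
#' C gives the model ankle power in W/kg.
#'
#' @param envelopes named list of per-muscle [stride_waveform()]s.
#' @param muscles a `muscle_set`.
#' @param omega_ank ankle angular velocity [stride_waveform()], rad/s.
#' @param lag delay in seconds.
#' @param stride_duration stride period, s.
#' @return a [stride_waveform()].
#' @export
unscaled_model_power <- function(envelopes, muscles, omega_ank, lag,
                                 stride_duration) {
  u <- summed_unscaled_moment(envelopes, muscles)
  us <- shift_waveform(u, lag, stride_duration)
  stride_waveform(us * wf_values(omega_ank), units = "unscaled W/kg")
}

#' Estimate the electromechanical delay by cross-correlation
#'
#' Sequentially shifts the summed unscaled MTU moment waveform in time,
#' multiplies by the ankle angular velocity, and correlates the result with
#' the inverse-dynamics ankle power; the lag maximizing the Pearson
#' correlation is the electromechanical delay (EMD), common to all muscles.
#' Pearson correlation is location- and scale-free, so the estimate does not
#' depend on the (yet unknown) scaling constant.
#'
#' @param envelopes named list of per-muscle [stride_waveform()]s.
#' @param muscles a `muscle_set`.
#' @param omega_ank ankle angular velocity [stride_waveform()], rad/s.
#' @param p_ank inverse-dynamics ankle power [stride_waveform()], W/kg.
#' @param stride_duration stride period, s.
#' @param lag_grid candidate lags in seconds (non-negative, within
#'   `[0, emd_search_max()]`); default: every stride-grid step from 0 to
#'   `emd_search_max()`.
#' @return the EMD in seconds; attribute `"correlation"` holds the peak
#'   Pearson correlation.
#' @export
estimate_emd <- function(envelopes, muscles, omega_ank, p_ank,
                         stride_duration, lag_grid = NULL) {
  n <- omega_ank$grid_points
  check_same_grid(omega_ank, p_ank)
  if (is.null(lag_grid))
    lag_grid <- seq(0, emd_search_max(), by = stride_duration / n)
  if (!length(lag_grid) || any(lag_grid < 0) || any(lag_grid > 0.3))
    stop("lag_grid must be non-empty, non-negative and within [0, 0.3] s",
         call. = FALSE)
  y <- wf_values(p_ank)
  if (stats::sd(y) == 0)
    stop("undefined-correlation error: inverse-dynamics power has zero variance",
         call. = FALSE)
  u <- summed_unscaled_moment(envelopes, muscles)
  P <- shifted_power_matrix(u, wf_values(omega_ank), lag_grid, stride_duration)
  r <- as.vector(stats::cor(P, y))
  best <- which.max(r)
  structure(lag_grid[best], correlation = r[best])
}

# columns = candidate lags: shift u circularly by each lag, multiply by omega
shifted_power_matrix <- function(u, omega, lag_grid, stride_duration) {
  n <- length(u)
  k <- lag_grid / (stride_duration / n)
  k0 <- floor(k)
  frac <- k - k0
  base <- seq_len(n) - 1
  idx0 <- (outer(base, k0, `-`) %% n) + 1
  M <- matrix(u[idx0], n, length(k))
  if (any(frac > 1e-12)) {
    idx1 <- (outer(base, k0 + 1, `-`) %% n) + 1
    M1 <- matrix(u[idx1], n, length(k))
    M <- sweep(M, 2, 1 - frac, `*`) + sweep(M1, 2, frac, `*`)
  }
  M * omega
}

#' Fit the trial scaling constant by Push-off peak matching
#'
#' `C = max(P_ank in window) / max(unscaled power in window)`: after scaling,
#' the model's peak ankle power in the Push-off window equals the
#' inverse-dynamics peak exactly. Matching on the Push-off window rather than
#' the global maximum avoids locking onto early-stance negative-power
#' artifacts.
#'
#' @param unscaled_power output of [unscaled_model_power()] at the chosen EMD.
#' @param p_ank inverse-dynamics ankle power [stride_waveform()], W/kg.
#' @param window a [pushoff_window()].
#' @return scaling constant C, N/(kg cm^2).
#' @export
fit_scaling <- function(unscaled_power, p_ank, window) {
  check_same_grid(unscaled_power, p_ank)
  mask <- window_mask(unscaled_power, window)
  pk_u <- max(wf_values(unscaled_power)[mask])
  if (pk_u <= 0)
    stop("degenerate-trial error: unscaled model power has no positive peak ",
         "in the Push-off window", call. = FALSE)
  max(wf_values(p_ank)[mask]) / pk_u
}

#' Calibration results of the EMG-driven model
#'
#' @param emd electromechanical delay, s.
#' @param scaling scaling constant C, N/(kg cm^2).
#' @param r_squared coefficient of determination between model and
#'   inverse-dynamics ankle power.
#' @param speed gait speed, m/s.
#' @param subject_id identifier.
#' @param window the [pushoff_window()] used for peak matching.
#' @return object of class `model_fit`.
#' @export
model_fit <- function(emd, scaling, r_squared = NA_real_, speed = NA_real_,
                      subject_id = NA_character_, window = NULL) {
  if (emd < 0 || emd > emd_search_max())
    stop("emd outside the configured search range", call. = FALSE)
  if (scaling <= 0) stop("scaling must be positive", call. = FALSE)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  structure(list(emd = as.numeric(emd), scaling = scaling,
                 r_squared = r_squared, speed = speed,
                 subject_id = subject_id, window = window),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> EMD = %.1f ms, C = %.3f N/(kg cm^2), R^2 = %.4f (speed %s m/s)\n",
              1000 * x$emd, x$scaling, x$r_squared,
              format(x$speed)), sep = "")
  invisible(x)
}

#' Decompose model ankle power into per-MTU contributions
#'
#' Applies the fitted delay and scaling to every muscle: per-muscle force
#' `F'_m = C * gain_m * env_m(t - EMD)` (N/kg), ankle moment
#' `M'_m = F'_m * r_ankle_m` (N m/kg), per-muscle ankle power
#' `P'_m = M'_m * omega_ank`, and the model ankle power `P'_ank = Sum_m P'_m`.
#' The sum identity holds pointwise by construction.
#'
#' @param fit a [model_fit()].
#' @param envelopes named list of per-muscle [stride_waveform()]s.
#' @param muscles a `muscle_set`.
#' @param omega_ank ankle angular velocity [stride_waveform()], rad/s.
#' @param stride_duration stride period, s.
#' @param p_ank optional inverse-dynamics power, stored alongside the model
#'   power in the returned pair.
#' @return list with `pair` (class `ankle_power_pair`: `inverse_dynamics`,
#'   `model`, `angular_velocity`, `per_muscle_power`) and `forces` (class
#'   `mtu_force_set`: per-muscle `force` and `moment` waveforms).
#' @export
decompose_ankle_power <- function(fit, envelopes, muscles, omega_ank,
                                  stride_duration, p_ank = NULL) {
  stopifnot(inherits(fit, "model_fit"))
  omega <- wf_values(omega_ank)
  forces <- list(); moments <- list(); powers <- list()
  for (m in seq_len(nrow(muscles))) {
    nm <- muscles$name[m]
    e <- envelopes[[nm]]
    if (is.null(e)) stop("envelope missing for muscle '", nm, "'", call. = FALSE)
    check_same_grid(e, omega_ank)
    f <- fit$scaling * wf_values(unscaled_force(e, muscles[m, ], fit$emd,
                                                stride_duration))
    forces[[nm]] <- stride_waveform(f, units = "N/kg")
    moments[[nm]] <- stride_waveform(f * muscles$r_ankle[m], units = "N.m/kg")
    powers[[nm]] <- stride_waveform(f * muscles$r_ankle[m] * omega,
                                    units = "W/kg")
  }
  p_model <- stride_waveform(Reduce(`+`, lapply(powers, wf_values)),
                             units = "W/kg")
  pair <- structure(list(inverse_dynamics = p_ank, model = p_model,
                         angular_velocity = omega_ank,
                         per_muscle_power = powers),
                    class = "ankle_power_pair")
  force_set <- structure(list(force = forces, moment = moments),
                         class = "mtu_force_set")
  list(pair = pair, forces = force_set)
}

#' Model fidelity: squared Pearson correlation
#'
#' Coefficient of determination between the scaled model ankle power and the
#' inverse-dynamics ankle power over the full stride grid.
#'
#' @param pair an `ankle_power_pair` with both waveforms present.
#' @return R^2 in `[0, 1]`.
#' @export
evaluate_fit <- function(pair) {
  if (is.null(pair$inverse_dynamics))
    stop("pair carries no inverse-dynamics power", call. = FALSE)
  a <- wf_values(pair$model); b <- wf_values(pair$inverse_dynamics)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined-correlation error: zero-variance waveform", call. = FALSE)
  stats::cor(a, b)^2
}

#' Calibrate the full EMG-driven model on stride-averaged waveforms
#'
#' Convenience wrapper running the calibration sequence: EMD by
#' cross-correlation, Push-off window from the inverse-dynamics power, scaling
#' by peak matching, and fidelity (R^2) of the scaled model.
#'
#' @inheritParams estimate_emd
#' @param toeoff_pct toe-off position, % stride (used to locate Push-off).
#' @param lag_grid optional candidate lags, s.
#' @param speed,subject_id metadata carried into the fit.
#' @return a [model_fit()].
#' @export
fit_emg_model <- function(envelopes, muscles, omega_ank, p_ank,
                          stride_duration, toeoff_pct, lag_grid = NULL,
                          speed = NA_real_, subject_id = NA_character_) {
  emd <- estimate_emd(envelopes, muscles, omega_ank, p_ank, stride_duration,
                      lag_grid)
  window <- find_pushoff_window(p_ank, toeoff_pct)
  up <- unscaled_model_power(envelopes, muscles, omega_ank, emd, stride_duration)
  C <- fit_scaling(up, p_ank, window)
  fit <- model_fit(as.numeric(emd), C, speed = speed, subject_id = subject_id,
                   window = window)
  dec <- decompose_ankle_power(fit, envelopes, muscles, omega_ank,
                               stride_duration, p_ank = p_ank)
  fit$r_squared <- evaluate_fit(dec$pair)
  fit
}
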