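#' Foot kinematics needed for multiarticular FDHL power
#'
#' Sign conventions (fixed throughout the package):
#' \itemize{
#'   \item `omega_ank`: ankle angular velocity, plantarflexion-positive (rad/s);
#'   \item `omega_mtp`: MTP angular velocity, toe dorsiflexion-positive (rad/s);
#'   \item `arch_rate`: rate of change of longitudinal arch length,
#'     lengthening-positive (m/s).
#' }
#' Toe dorsiflexion and arch lengthening both lengthen the FDHL path, so with
#' positive FDHL force they yield negative MTU power at the foot.
#'
#' @param omega_mtp,arch_rate,omega_ank [stride_waveform()]s on one grid.
#' @return object of class `foot_kinematics`.
#' @export
foot_kinematics <- function(omega_mtp, arch_rate, omega_ank) {
  check_same_grid(omega_mtp, arch_rate)
  check_same_grid(omega_mtp, omega_ank)
  structure(list(omega_mtp = omega_mtp, arch_rate = arch_rate,
                 omega_ank = omega_ank),
            class = "foot_kinematics")
}

#' FDHL power attributed to ankle rotation
#'
#' `P'_fdhl,ank(t) = omega_ank(t) * r_ankle * F'_fdhl(t)` (W/kg): the part of
#' FDHL MTU length-change rate due to ankle rotation, times force.
#'
#' @param f_fdhl FDHL force [stride_waveform()], N/kg.
#' @param omega_ank ankle angular velocity [stride_waveform()], rad/s
#'   (plantarflexion-positive).
#' @param r_ankle FDHL ankle moment arm, m.
#' @return a [stride_waveform()], W/kg.
#' @export
fdhl_ankle_power <- function(f_fdhl, omega_ank, r_ankle) {
  check_same_grid(f_fdhl, omega_ank)
  stride_waveform(wf_values(omega_ank) * r_ankle * wf_values(f_fdhl),
                  units = "W/kg")
}

#' FDHL power attributed to motion within the foot
#'
#' The part of FDHL MTU power due to MTP rotation and longitudinal arch
#' length change: `-(omega_mtp * r_mtp + arch_rate) * F'_fdhl` under the
#' package conventions (dorsiflexion-positive `omega_mtp`,
#' lengthening-positive `arch_rate`; see [foot_kinematics()]). MTU lengthening
#' at the foot with positive force yields negative power.
#'
#' @param f_fdhl FDHL force [stride_waveform()], N/kg.
#' @param foot a [foot_kinematics()].
#' @param r_mtp FDHL moment arm about the MTP joint, m.
#' @return a [stride_waveform()], W/kg.
#' @export
fdhl_foot_power <- function(f_fdhl, foot, r_mtp) {
  stopifnot(inherits(foot, "foot_kinematics"))
  check_same_grid(f_fdhl, foot$omega_mtp)
  lengthening_rate <- wf_values(foot$omega_mtp) * r_mtp + wf_values(foot$arch_rate)
  stride_waveform(-lengthening_rate * wf_values(f_fdhl), units = "W/kg")
}

#' Assemble the full MTU power decomposition
#'
#' Fills all six power waveforms from a fitted decomposition:
#' \itemize{
#'   \item `p_ank_model`: model ankle power `P'_ank`;
#'   \item `p_fdhl_ank`: FDHL power about the ankle;
#'   \item `p_fdhl_foot`: FDHL power within the foot;
#'   \item `p_fdhl = p_fdhl_ank + p_fdhl_foot`: net FDHL MTU power;
#'   \item `p_mtu_min = p_ank_model - p_fdhl_ank`: net MTU power under the
#'     worst-case assumption that the FDHL acts isometrically (performs zero
#'     net power);
#'   \item `p_mtu = p_ank_model + p_fdhl_foot`: net plantarflexing MTU power,
#'     with every other MTU's power taken as its ankle power.
#' }
#' The bookkeeping identity `p_mtu - p_mtu_min = p_fdhl` holds pointwise.
#'
#' @param pair an `ankle_power_pair` from [decompose_ankle_power()].
#' @param forces the matching `mtu_force_set`.
#' @param foot a [foot_kinematics()].
#' @param muscles a `muscle_set` (must include the fdhl).
#' @return object of class `mtu_power_decomposition`.
#' @export
compose_decomposition <- function(pair, forces, foot, muscles) {
  fdhl <- muscle_row(muscles, "fdhl")
  f_fdhl <- forces$force[["fdhl"]]
  if (is.null(f_fdhl))
    stop("configuration error: no fdhl force in the force set", call. = FALSE)
  p_model <- pair$model
  p_fa <- fdhl_ankle_power(f_fdhl, pair$angular_velocity, fdhl$r_ankle)
  p_ff <- fdhl_foot_power(f_fdhl, foot, fdhl$r_mtp)
  mk <- function(v) stride_waveform(v, units = "W/kg")
  structure(list(
    p_ank_model = p_model,
    p_fdhl_ank = p_fa,
    p_fdhl_foot = p_ff,
    p_fdhl = mk(wf_values(p_fa) + wf_values(p_ff)),
    p_mtu_min = mk(wf_values(p_model) - wf_values(p_fa)),
    p_mtu = mk(wf_values(p_model) + wf_values(p_ff)),
    inverse_dynamics = pair$inverse_dynamics
  ), class = "mtu_power_decomposition")
}

#' Push-off window on the stride grid
#' @param start,end window bounds in % stride, `0 <= start < end <= 100`.
#' @return object of class `pushoff_window`.
#' @export
pushoff_window <- function(start, end) {
  if (!(start >= 0 && start < end && end <= 100))
    stop("require 0 <= start < end <= 100 (% stride)", call. = FALSE)
  structure(list(start = start, end = end), class = "pushoff_window")
}

# internal: logical mask of grid points inside a window
window_mask <- function(wf, window) {
  pct <- stride_pct(wf)
  pct >= window$start & pct <= window$end
}

#' Locate the Push-off window from an ankle power waveform
#'
#' Finds the last contiguous region of strictly positive ankle power ending at
#' or before toe-off (the late-stance positive burst). Two robustness rules
#' guard the bounds against measurement noise and zero-phase filter leakage at
#' the burst edges: samples are counted as positive only above
#' `min_height_frac` of the pre-toe-off maximum, and regions narrower than
#' `min_width_pct` are ignored.
#'
#' @param p_ank ankle power [stride_waveform()], W/kg.
#' @param toeoff_pct toe-off position, % stride.
#' @param min_width_pct minimum admissible region width, % stride (default 2).
#' @param min_height_frac positivity floor as a fraction of the maximum
#'   positive value before toe-off (default 0.01).
#' @return a [pushoff_window()].
#' @export
find_pushoff_window <- function(p_ank, toeoff_pct, min_width_pct = 2,
                                min_height_frac = 0.01) {
  pct <- stride_pct(p_ank)
  v <- wf_values(p_ank)
  pre_to <- pct <= toeoff_pct
  pk <- max(v[pre_to])
  if (pk <= 0)
    stop("no-pushoff error: no positive ankle power before toe-off", call. = FALSE)
  pos <- v > min_height_frac * pk & pre_to
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & (pct[ends] - pct[starts]) >= min_width_pct)
  if (!length(keep))
    stop("no-pushoff error: no positive region wider than ", min_width_pct,
         "% stride before toe-off", call. = FALSE)
  i <- keep[length(keep)]
  pushoff_window(pct[starts[i]], pct[ends[i]])
}

#' Peak power and work over the Push-off window
#'
#' Peak is the maximum of the waveform inside the window (floored at zero);
#' work is the trapezoidal integral of the positive part of the waveform over
#' the window, in time units (`% stride / 100 * stride_duration`). Both are
#' reported per kilogram and, when `mass` is supplied, in absolute units.
#'
#' @param p a power [stride_waveform()], W/kg.
#' @param window a [pushoff_window()].
#' @param stride_duration stride period, s.
#' @param mass subject mass, kg (optional; enables absolute W and J).
#' @param source_label which waveform the metrics describe.
#' @return object of class `pushoff_metrics`: `peak_power` (W/kg), `work`
#'   (J/kg), `peak_power_abs` (W), `work_abs` (J), `source_label`.
#' @export
pushoff_metrics <- function(p, window, stride_duration, mass = NA_real_,
                            source_label = "") {
  mask <- window_mask(p, window)
  if (!any(mask)) stop("parameter error: empty Push-off window", call. = FALSE)
  v <- wf_values(p)[mask]
  tsec <- stride_pct(p)[mask] / 100 * stride_duration
  peak <- max(max(v), 0)
  work <- pracma::trapz(tsec, pmax(v, 0))
  structure(list(peak_power = peak, work = work,
                 peak_power_abs = peak * mass, work_abs = work * mass,
                 source_label = source_label),
            class = "pushoff_metrics")
}

#' @export
print.pushoff_metrics <- function(x, ...) {
  cat(sprintf("<pushoff_metrics> %s: peak %.3f W/kg, work %.4f J/kg",
              x$source_label, x$peak_power, x$work))
  if (!is.na(x$peak_power_abs))
    cat(sprintf(" (%.1f W, %.2f J)", x$peak_power_abs, x$work_abs))
  cat("\n")
  invisible(x)
}

#' Percent overestimation of MTU power by model ankle power
#'
#' For peak Push-off power and Push-off work, computes
#' `100 * (X_ank - X_target) / X_target` with `X_ank` taken from the model
#' ankle power `P'_ank` and targets `P'_MTU,min` (isometric-FDHL worst case)
#' and `P'_MTU` (kinematic estimate).
#'
#' @param d an [compose_decomposition()] result.
#' @param window a [pushoff_window()].
#' @param stride_duration stride period, s.
#' @param mass subject mass, kg (optional).
#' @return data.frame with columns `target`, `metric`, `ankle_value`,
#'   `target_value`, `overestimate_pct` (values per kg).
#' @export
overestimate_report <- function(d, window, stride_duration, mass = NA_real_) {
  stopifnot(inherits(d, "mtu_power_decomposition"))
  m_ank <- pushoff_metrics(d$p_ank_model, window, stride_duration, mass, "p_ank_model")
  rows <- list()
  for (tgt in c("p_mtu_min", "p_mtu")) {
    m_t <- pushoff_metrics(d[[tgt]], window, stride_duration, mass, tgt)
    for (metric in c("peak_power", "work")) {
      xa <- m_ank[[metric]]; xt <- m_t[[metric]]
      if (xt == 0)
        stop("degenerate error: zero ", metric, " for target ", tgt, call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        target = tgt, metric = metric, ankle_value = xa, target_value = xt,
        overestimate_pct = 100 * (xa - xt) / xt, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
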