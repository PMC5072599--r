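#' Uniformly sampled time-domain signal
#'
#' Lightweight container for a uniformly sampled signal: a numeric vector plus
#' its sample rate, a unit label, and the time of the first sample. All
#' continuous-time inputs to the pipeline (EMG, joint angles, arch length,
#' ankle moment, ground reaction force) travel in this form.
#'
#' @param values numeric vector of samples; must be finite.
#' @param sample_rate sampling frequency in Hz (> 0).
#' @param units unit label for the samples (e.g. `"rad"`, `"N"`).
#' @param t0 time of the first sample in seconds.
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(values, sample_rate, units = "", t0 = 0) {
  values <- as.numeric(values)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  structure(list(values = values, sample_rate = sample_rate,
                 units = units, t0 = t0),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %g Hz [%s], t0 = %g s\n",
              length(x$values), x$sample_rate, x$units, x$t0))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$values)

#' Sample times of a sampled signal
#' @param x a [sampled_signal()].
#' @return numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "sampled_signal"))
  x$t0 + (seq_along(x$values) - 1) / x$sample_rate
}

#' Stride-normalized waveform
#'
#' A signal resampled onto a fixed grid spanning one gait cycle (0--100% of
#' stride, footstrike to ipsilateral footstrike). Grid point `j` sits at
#' stride fraction `(j-1)/N`, so the grid is periodic: the sample at 100%
#' coincides with the next stride's 0%. Carries the pointwise mean and
#' standard deviation across the strides that were averaged.
#'
#' @param mean numeric vector of length `N` (grid values).
#' @param units unit label.
#' @param sd pointwise standard deviation across strides (`NULL` for zeros).
#' @param n_strides number of strides averaged.
#' @return An object of class `stride_waveform`.
#' @export
stride_waveform <- function(mean, units = "", sd = NULL, n_strides = 1L) {
  mean <- as.numeric(mean)
  n <- length(mean)
  if (n < 3L) stop("a stride waveform needs at least 3 grid points", call. = FALSE)
  if (is.null(sd)) sd <- numeric(n)
  if (length(sd) != n) stop("`mean` and `sd` must have the same length", call. = FALSE)
  if (any(sd < 0)) stop("`sd` must be non-negative", call. = FALSE)
  structure(list(mean = mean, sd = as.numeric(sd),
                 n_strides = as.integer(n_strides), units = units,
                 grid_points = n),
            class = "stride_waveform")
}

#' @export
print.stride_waveform <- function(x, ...) {
  cat(sprintf("<stride_waveform> %d grid points [%s], %d stride(s), range [%.4g, %.4g]\n",
              x$grid_points, x$units, x$n_strides,
              min(x$mean), max(x$mean)))
  invisible(x)
}

#' Stride-percent positions of a waveform grid
#' @param x a [stride_waveform()] or an integer number of grid points.
#' @return numeric vector of grid positions in % stride, in `[0, 100)`.
#' @export
stride_pct <- function(x) {
  n <- if (inherits(x, "stride_waveform")) x$grid_points else as.integer(x)
  100 * (seq_len(n) - 1) / n
}

# internal: coerce numeric / stride_waveform to plain values
wf_values <- function(x) {
  if (inherits(x, "stride_waveform")) x$mean else as.numeric(x)
}

# internal: check two waveforms share a grid
check_same_grid <- function(a, b) {
  if (inherits(a, "stride_waveform") && inherits(b, "stride_waveform") &&
      a$grid_points != b$grid_points)
    stop("waveforms are on different stride grids (",
         a$grid_points, " vs ", b$grid_points, " points)", call. = FALSE)
  invisible(TRUE)
}

#' Numerical differentiation
#'
#' Differentiates a sampled signal or stride waveform with central differences
#' in the interior and one-sided differences at the two ends. Units are
#' divided by seconds. For a stride waveform the time step is
#' `stride_duration / grid_points`.
#'
#' @param x a [sampled_signal()] or [stride_waveform()].
#' @param stride_duration stride period in seconds (stride waveforms only).
#' @param ... unused.
#' @return object of the same class as `x`, in `<units>/s`.
#' @export
differentiate <- function(x, ...) UseMethod("differentiate")

#' @rdname differentiate
#' @export
differentiate.stride_waveform <- function(x, stride_duration, ...) {
  if (missing(stride_duration) || stride_duration <= 0)
    stop("`stride_duration` (s) is required to differentiate a stride waveform",
         call. = FALSE)
  dt <- stride_duration / x$grid_points
  stride_waveform(diff_central(x$mean, dt),
                  units = rate_units(x$units), n_strides = x$n_strides)
}

#' @rdname differentiate
#' @export
differentiate.sampled_signal <- function(x, ...) {
  dt <- 1 / x$sample_rate
  sampled_signal(diff_central(x$values, dt), x$sample_rate,
                 units = rate_units(x$units), t0 = x$t0)
}

#' @rdname differentiate
#' @export
differentiate.numeric <- function(x, stride_duration = NULL, dt = NULL, ...) {
  if (is.null(dt)) {
    if (is.null(stride_duration)) stop("supply `dt` or `stride_duration`", call. = FALSE)
    dt <- stride_duration / length(x)
  }
  diff_central(x, dt)
}

# central differences, one-sided at the ends
diff_central <- function(v, dt) {
  n <- length(v)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

rate_units <- function(u) if (nzchar(u)) paste0(u, "/s") else "1/s"

#' Circularly shift a stride waveform in time
#'
#' Shifts a periodic stride-normalized waveform by `lag` seconds, i.e. returns
#' `w(t - lag)` on the same grid. Integer-sample lags are exact index rolls;
#' fractional lags use linear interpolation between the two neighbouring
#' rolls, consistent with the periodic grid.
#'
#' @param x a [stride_waveform()] or numeric vector on the stride grid.
#' @param lag shift in seconds (positive delays the waveform).
#' @param stride_duration stride period in seconds.
#' @return same type as `x`.
#' @export
shift_waveform <- function(x, lag, stride_duration) {
  v <- wf_values(x)
  n <- length(v)
  k <- lag / (stride_duration / n)
  k0 <- floor(k)
  frac <- k - k0
  roll <- function(kk) v[((seq_len(n) - 1 - kk) %% n) + 1]
  out <- if (frac < 1e-12) roll(k0) else (1 - frac) * roll(k0) + frac * roll(k0 + 1)
  if (inherits(x, "stride_waveform"))
    stride_waveform(out, units = x$units, n_strides = x$n_strides)
  else out
}
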