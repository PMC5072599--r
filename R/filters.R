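#' Zero-lag Butterworth filter
#'
#' Applies an order-3 Butterworth filter forward and backward
#' ([signal::filtfilt()]), giving zero phase shift at every frequency and a
#' magnitude response equal to the square of the single-pass response:
#' for a low-pass design `|H(f)|^2 = 1 / (1 + (f/fc)^(2*order))`.
#'
#' @param x a [sampled_signal()] or numeric vector.
#' @param cutoff cutoff frequency in Hz; must lie below Nyquist.
#' @param order filter order of the single-pass design (default 3).
#' @param kind `"low"` or `"high"`.
#' @param sample_rate required when `x` is a bare numeric vector.
#' @return filtered signal, same type as `x`.
#' @export
zero_lag_butterworth <- function(x, cutoff, order = 3L,
                                 kind = c("low", "high"),
                                 sample_rate = NULL) {
  kind <- match.arg(kind)
  if (inherits(x, "sampled_signal")) {
    fs <- x$sample_rate
    v <- x$values
  } else {
    if (is.null(sample_rate))
      stop("`sample_rate` is required for numeric input", call. = FALSE)
    fs <- sample_rate
    v <- as.numeric(x)
  }
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("parameter error: cutoff must lie in (0, sample_rate/2); got ",
         cutoff, " Hz at fs = ", fs, " Hz", call. = FALSE)
  if (length(v) < 9L * order)
    stop("signal-length error: signal too short (", length(v),
         " samples) for a stable order-", order, " forward-backward filter",
         call. = FALSE)
  ba <- signal::butter(order, cutoff / (fs / 2), type = kind)
  out <- signal::filtfilt(ba, v)
  if (inherits(x, "sampled_signal"))
    sampled_signal(out, fs, units = x$units, t0 = x$t0)
  else out
}

#' EMG conditioning chain
#'
#' Converts a raw EMG recording to a linear envelope using the conventional
#' chain, in this exact order: demean, high-pass filter (150 Hz), full-wave
#' rectify, low-pass filter (10 Hz). All filters are order-3 zero-lag
#' Butterworth. Negative excursions left by the final low-pass transient are
#' clipped at zero so the envelope is non-negative.
#'
#' @param raw a [sampled_signal()] or numeric vector of raw EMG.
#' @param sample_rate required for numeric input; must be >= 1000 Hz.
#' @param highpass high-pass cutoff, Hz.
#' @param lowpass envelope low-pass cutoff, Hz.
#' @return envelope, same type as `raw`, non-negative.
#' @export
process_emg <- function(raw, sample_rate = NULL, highpass = 150, lowpass = 10) {
  fs <- if (inherits(raw, "sampled_signal")) raw$sample_rate else sample_rate
  if (is.null(fs)) stop("`sample_rate` is required for numeric input", call. = FALSE)
  if (fs < 1000)
    stop("raw EMG must be sampled at >= 1000 Hz (got ", fs, " Hz)", call. = FALSE)
  v <- if (inherits(raw, "sampled_signal")) raw$values else as.numeric(raw)
  v <- v - mean(v)
  v <- zero_lag_butterworth(v, highpass, kind = "high", sample_rate = fs)
  v <- abs(v)
  v <- zero_lag_butterworth(v, lowpass, kind = "low", sample_rate = fs)
  v <- pmax(v, 0)
  if (inherits(raw, "sampled_signal"))
    sampled_signal(v, fs, units = "mvc", t0 = raw$t0)
  else v
}

#' Normalize EMG envelopes by each muscle's global maximum
#'
#' Divides every envelope of a muscle by the maximum value that muscle reached
#' across all supplied trials (walking and maximum-voluntary-contraction
#' trials alike), so the union of a muscle's normalized envelopes peaks at
#' exactly 1.
#'
#' @param envelopes_by_trial named list (one element per muscle); each element
#'   is a list of numeric vectors or [sampled_signal()]s, one per trial.
#' @return same structure with normalized values; attribute `"maxima"` carries
#'   the per-muscle maxima that were divided out.
#' @export
normalize_emg <- function(envelopes_by_trial) {
  stopifnot(is.list(envelopes_by_trial), !is.null(names(envelopes_by_trial)))
  maxima <- vapply(envelopes_by_trial, function(trials) {
    max(vapply(trials, function(tr) max(wf_or_signal_values(tr)), numeric(1)))
  }, numeric(1))
  bad <- names(maxima)[maxima <= 0]
  if (length(bad))
    stop("degenerate-signal error: global maximum is zero for muscle(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- mapply(function(trials, m) {
    lapply(trials, function(tr) scale_signal(tr, 1 / m))
  }, envelopes_by_trial, maxima, SIMPLIFY = FALSE)
  attr(out, "maxima") <- maxima
  out
}

# internal helpers shared by normalize/perturb
wf_or_signal_values <- function(x) {
  if (inherits(x, "sampled_signal")) x$values
  else if (inherits(x, "stride_waveform")) x$mean
  else as.numeric(x)
}

scale_signal <- function(x, k) {
  if (inherits(x, "sampled_signal"))
    sampled_signal(x$values * k, x$sample_rate, units = x$units, t0 = x$t0)
  else if (inherits(x, "stride_waveform"))
    stride_waveform(x$mean * k, units = x$units, sd = x$sd * abs(k),
                    n_strides = x$n_strides)
  else as.numeric(x) * k
}
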