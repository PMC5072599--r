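# Shared fixtures, all generated in code.

quick_sim <- function(speed = 1.25, n_strides = 4L, aligned = FALSE,
                      noise_power = 0, noise_env = 0, seed = 7L, ...) {
  ms <- make_muscle_set()
  cfg <- trial_config(speed, n_strides = n_strides, aligned = aligned,
                      noise_sd_power = noise_power,
                      noise_sd_envelope = noise_env, seed = seed, ...)
  c(list(muscles = ms, cfg = cfg), simulate_trial(ms, cfg))
}

# one noiseless default-timing simulation + pipeline report, computed once
# and reused across test files
.cache <- new.env(parent = emptyenv())
cached_noiseless <- function() {
  if (is.null(.cache$noiseless)) {
    x <- quick_sim(n_strides = 6L, seed = 3L)
    x$report <- run_pipeline(x$trial, x$muscles)
    .cache$noiseless <- x
  }
  .cache$noiseless
}

# stride-grid waveform bundle built directly from generator ground truth
# (no pipeline stages involved)
truth_bundle <- function(sim) {
  tr <- sim$truth
  wf <- function(v, units = "") stride_waveform(v, units = units)
  list(
    omega_ank = wf(tr$omega_ank, "rad/s"),
    omega_mtp = wf(tr$omega_mtp, "rad/s"),
    arch_rate = wf(tr$arch_rate, "m/s"),
    p_ank = wf(tr$true_p_ank_model, "W/kg"),
    forces = lapply(tr$true_forces, wf, units = "N/kg"),
    foot = foot_kinematics(wf(tr$omega_mtp, "rad/s"), wf(tr$arch_rate, "m/s"),
                           wf(tr$omega_ank, "rad/s")),
    stride_duration = tr$stride_duration,
    toeoff_pct = tr$toeoff_pct
  )
}

# Gaussian-burst envelopes on the stride grid, built independently of the
# generator internals (wrapped distance, burst center/width in % stride)
grid_envelopes <- function(amps, centers, widths, n = 1000L) {
  sg <- (seq_len(n) - 1) / n
  out <- lapply(seq_along(amps), function(m) {
    d <- (sg - centers[m] / 100) %% 1
    d <- ifelse(d > 0.5, d - 1, d)
    stride_waveform(amps[m] * exp(-0.5 * (d / (widths[m] / 100))^2),
                    units = "mvc")
  })
  names(out) <- names(amps)
  out
}

# half-sine positive burst between start/end (% stride), zero elsewhere
half_sine_wf <- function(amplitude, start, end, n = 1000L) {
  pct <- 100 * (seq_len(n) - 1) / n
  v <- ifelse(pct > start & pct < end,
              amplitude * sin(pi * (pct - start) / (end - start)), 0)
  stride_waveform(v, units = "W/kg")
}
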