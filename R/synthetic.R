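#' Configuration for one synthetic treadmill walking trial
#'
#' Defaults emulate the study conditions: treadmill walking at 0.75, 1.00 or
#' 1.25 m/s with speed-matched stride durations (1.35, 1.20, 1.08 s), the
#' speed-average electromechanical delay and scaling constant (88/70/55 ms and
#' 2.30/2.37/1.98 N/(kg cm^2)), and per-MTU shares of peak model ankle power
#' of 89.0% triceps surae (split 54.4/23.2/11.4 among soleus and the two
#' gastrocnemius heads), 6.6% FDHL and 4.4% peroneus longus. Plantarflexor
#' excitation envelopes are Gaussian bursts; by default their centers are
#' staggered by a few percent of the stride around Push-off, the way the
#' muscles fire in walking. `aligned = TRUE` centers every burst at 53% stride
#' (used when realized power shares must equal the requested shares exactly).
#'
#' @param speed belt speed, m/s (one of 0.75, 1.00, 1.25 for the presets; any
#'   value is accepted if `stride_duration`, `true_emd`, `true_scaling` are
#'   given).
#' @param n_strides number of complete strides to generate.
#' @param aligned center all envelope bursts at the same stride percentage.
#' @param stride_duration,true_emd,true_scaling overrides of the speed presets
#'   (s, s, N/(kg cm^2)).
#' @param mtu_shares named per-muscle fractions of peak model ankle power;
#'   must sum to 1.
#' @param envelope_timing data.frame `name`, `center_pct`, `width_pct` (% stride;
#'   `width_pct` is the Gaussian burst sd).
#' @param envelope_peak peak of the largest normalized envelope, as a fraction
#'   of the across-trials (MVC-inclusive) maximum activation.
#' @param noise_sd_power additive Gaussian noise on the ankle moment channel,
#'   expressed on the power scale (W/kg) at peak plantarflexion velocity.
#' @param noise_sd_envelope additive Gaussian noise on the envelopes
#'   (normalized units).
#' @param sample_rate_kinematics,sample_rate_emg Hz; all trial channels share
#'   the kinematics clock, raw EMG is synthesized on its own clock.
#' @param subject_mass kg.
#' @param grid_points stride grid used for ground-truth waveforms.
#' @param seed integer seed; identical configs give bit-identical trials.
#' @return validated object of class `trial_config`.
#' @export
trial_config <- function(speed = 1.25,
                         n_strides = 10L,
                         aligned = FALSE,
                         stride_duration = NULL,
                         true_emd = NULL,
                         true_scaling = NULL,
                         mtu_shares = c(soleus = 0.544, gastroc_med = 0.232,
                                        gastroc_lat = 0.114, peroneus = 0.044,
                                        fdhl = 0.066),
                         envelope_timing = NULL,
                         envelope_peak = 0.2,
                         noise_sd_power = 0.05,
                         noise_sd_envelope = 0.005,
                         sample_rate_kinematics = 1000,
                         sample_rate_emg = 2000,
                         subject_mass = 88,
                         grid_points = 1000L,
                         seed = 1L) {
  presets <- data.frame(speed = c(0.75, 1.00, 1.25),
                        stride = c(1.35, 1.20, 1.08),
                        emd = c(0.088, 0.070, 0.055),
                        scal = c(2.30, 2.37, 1.98))
  i <- match(speed, presets$speed)
  if (is.null(stride_duration))
    stride_duration <- if (!is.na(i)) presets$stride[i] else
      stop("no stride_duration preset for speed ", speed, "; supply it", call. = FALSE)
  if (is.null(true_emd)) true_emd <- if (!is.na(i)) presets$emd[i] else 0.055
  if (is.null(true_scaling)) true_scaling <- if (!is.na(i)) presets$scal[i] else 2.0
  if (is.null(envelope_timing)) {
    envelope_timing <- data.frame(
      name = required_muscles,
      center_pct = if (aligned) rep(53, 5) else c(51, 50, 50.5, 48, 54),
      width_pct = if (aligned) rep(5, 5) else c(5, 5, 5, 6, 5),
      stringsAsFactors = FALSE
    )
  }
  cfg <- structure(list(
    speed = speed, stride_duration = stride_duration,
    n_strides = as.integer(n_strides),
    sample_rate_kinematics = sample_rate_kinematics,
    sample_rate_emg = sample_rate_emg,
    true_emd = true_emd, true_scaling = true_scaling,
    envelope_timing = envelope_timing, mtu_shares = mtu_shares,
    envelope_peak = envelope_peak,
    noise_sd_power = noise_sd_power, noise_sd_envelope = noise_sd_envelope,
    subject_mass = subject_mass, grid_points = as.integer(grid_points),
    seed = as.integer(seed)
  ), class = "trial_config")
  validate_trial_config(cfg)
  cfg
}

validate_trial_config <- function(cfg) {
  with(cfg, {
    if (sample_rate_kinematics <= 0 || sample_rate_emg <= 0)
      stop("sample rates must be positive", call. = FALSE)
    if (stride_duration <= 0 || n_strides < 1)
      stop("stride_duration must be positive and n_strides >= 1", call. = FALSE)
    if (abs(sum(mtu_shares) - 1) > 1e-9)
      stop("validation error: mtu_shares must sum to 1 (got ",
           format(sum(mtu_shares)), ")", call. = FALSE)
    if (any(mtu_shares < 0))
      stop("validation error: mtu_shares must be non-negative", call. = FALSE)
    if (true_emd < 0 || true_emd > emd_search_max())
      stop("true_emd must lie within the EMD search range [0, ",
           emd_search_max(), "] s", call. = FALSE)
    if (true_scaling <= 0) stop("true_scaling must be positive", call. = FALSE)
    if (envelope_peak <= 0 || envelope_peak > 1)
      stop("envelope_peak must lie in (0, 1]", call. = FALSE)
    if (noise_sd_power < 0 || noise_sd_envelope < 0)
      stop("noise standard deviations must be non-negative", call. = FALSE)
    if (subject_mass <= 0) stop("subject_mass must be positive", call. = FALSE)
  })
  invisible(cfg)
}

#' Upper bound of the electromechanical-delay search range
#' @return seconds (0.2).
#' @export
emd_search_max <- function() 0.2

# ---- deterministic gait shapes -------------------------------------------
# All shapes are functions of stride fraction s in [0, 1), C1-smooth, with
# closed-form derivatives (per stride fraction; divide by stride duration for
# rates). Events: stance 0-65% with toe-off at 65%; monotonic dorsiflexion
# through mid-stance reaching its extreme at 45%; monotonic plantarflexion
# 45-65% (Push-off) followed by a return to neutral in swing; MTP
# dorsiflexion and arch lengthen-then-recoil during Push-off. With a
# plantarflexion-positive moment this confines positive ankle power before
# toe-off to 45-65% of the stride and gives the usual eccentric (negative)
# plantarflexor power through mid-stance.

hann_bump <- function(s, a, b) {
  ifelse(s > a & s < b, sin(pi * (s - a) / (b - a))^2, 0)
}
hann_bump_d <- function(s, a, b) {
  ifelse(s > a & s < b, pi / (b - a) * sin(2 * pi * (s - a) / (b - a)), 0)
}

# raised-cosine step from 0 to 1 over [a, b] (zero slope at both ends)
rc_step <- function(s, a, b) {
  out <- numeric(length(s))
  out[s >= b] <- 1
  i <- s >= a & s < b
  out[i] <- 0.5 * (1 - cos(pi * (s[i] - a) / (b - a)))
  out
}
rc_step_d <- function(s, a, b) {
  out <- numeric(length(s))
  i <- s >= a & s < b
  out[i] <- 0.5 * pi / (b - a) * sin(pi * (s[i] - a) / (b - a))
  out
}

GAIT <- list(a_df = 0.17, a_pf = 0.35, a_mtp = 0.5,
             arch_l0 = 0.16, arch_amp = 0.01,
             stance_frac = 0.65, pushoff = c(0.45, 0.65))

gait_shapes <- function(s) {
  a_df <- GAIT$a_df; a_pf <- GAIT$a_pf
  # dorsiflex 5-45%, plantarflex 45-65%, return to neutral 65-95%
  theta <- -a_df * rc_step(s, 0.05, 0.45) +
    (a_df + a_pf) * rc_step(s, 0.45, 0.65) -
    a_pf * rc_step(s, 0.65, 0.95)
  dtheta <- -a_df * rc_step_d(s, 0.05, 0.45) +
    (a_df + a_pf) * rc_step_d(s, 0.45, 0.65) -
    a_pf * rc_step_d(s, 0.65, 0.95)
  list(
    theta_ank = theta,
    dtheta_ank = dtheta,
    theta_mtp = GAIT$a_mtp * hann_bump(s, 0.45, 0.70),
    dtheta_mtp = GAIT$a_mtp * hann_bump_d(s, 0.45, 0.70),
    arch = GAIT$arch_l0 * (1 + GAIT$arch_amp * hann_bump(s, 0.45, 0.65)),
    darch = GAIT$arch_l0 * GAIT$arch_amp * hann_bump_d(s, 0.45, 0.65)
  )
}

# periodic Gaussian burst centered at c (stride fraction) with sd w
periodic_gauss <- function(s, center, width) {
  d <- (s - center) %% 1
  d <- ifelse(d > 0.5, d - 1, d)
  exp(-0.5 * (d / width)^2)
}

# double-hump vertical GRF shape (body weights), stance only
grf_shape <- function(s) {
  u <- s / GAIT$stance_frac
  ifelse(s < GAIT$stance_frac,
         pmax(0, 1.1 * sin(pi * u) + 0.25 * sin(3 * pi * u)), 0)
}

# per-muscle envelope amplitudes realizing the requested peak-power shares:
# share_m  propto  gain_m * amp_m * r_ankle_m, largest amplitude scaled to
# `envelope_peak`.
envelope_amplitudes <- function(muscles, cfg) {
  sh <- cfg$mtu_shares[muscles$name]
  if (anyNA(sh))
    stop("mtu_shares must name every muscle in the set", call. = FALSE)
  raw <- sh / (muscle_gain(muscles) * muscles$r_ankle)
  amps <- cfg$envelope_peak * raw / max(raw)
  names(amps) <- muscles$name
  amps
}

#' Simulate a synthetic walking trial with known ground truth
#'
#' Generates one forward-consistent treadmill trial: Gaussian-burst excitation
#' envelopes per muscle, smooth sagittal ankle and MTP angles, longitudinal
#' arch length, a vertical ground reaction force with a double-hump stance
#' profile, and an ankle moment constructed directly from the model's own
#' force map -- the sum over muscles of
#' `PCSA * cos(pennation) * envelope(t - true_emd) * true_scaling * r_ankle` --
#' plus additive Gaussian noise. Running the estimation pipeline on a
#' noiseless trial therefore recovers `true_emd` and `true_scaling`.
#'
#' All trial channels share the kinematics clock. The returned ground truth
#' carries the noise-free per-MTU force and power waveforms on the stride
#' grid, anchored at the true footstrikes.
#'
#' @param muscles a `muscle_set` from [make_muscle_set()].
#' @param cfg a [trial_config()].
#' @return list with elements `trial` (class `synthetic_trial`) and `truth`
#'   (class `ground_truth`).
#' @export
simulate_trial <- function(muscles, cfg) {
  stopifnot(inherits(muscles, "muscle_set"))
  validate_trial_config(cfg)
  set.seed(cfg$seed)
  fs <- cfg$sample_rate_kinematics
  T <- cfg$stride_duration
  tt <- seq(0, cfg$n_strides * T + 0.25 * T, by = 1 / fs)
  s <- (tt / T) %% 1
  amps <- envelope_amplitudes(muscles, cfg)
  tim <- cfg$envelope_timing
  env_clean <- lapply(muscles$name, function(nm) {
    j <- match(nm, tim$name)
    amps[[nm]] * periodic_gauss(s, tim$center_pct[j] / 100, tim$width_pct[j] / 100)
  })
  names(env_clean) <- muscles$name
  # forward-consistent moment: delayed envelopes through the force map
  s_del <- ((tt - cfg$true_emd) / T) %% 1
  gains <- muscle_gain(muscles)
  moment_clean <- Reduce(`+`, lapply(seq_len(nrow(muscles)), function(m) {
    j <- match(muscles$name[m], tim$name)
    cfg$true_scaling * gains[m] * amps[[muscles$name[m]]] *
      periodic_gauss(s_del, tim$center_pct[j] / 100, tim$width_pct[j] / 100) *
      muscles$r_ankle[m]
  }))
  shapes <- gait_shapes(s)
  # peak plantarflexion velocity, used to express moment noise on the power scale
  omega_peak <- (GAIT$a_df + GAIT$a_pf) * 0.5 * pi / 0.20 / T
  moment <- moment_clean +
    stats::rnorm(length(tt), sd = cfg$noise_sd_power / omega_peak)
  envelopes <- lapply(env_clean, function(e)
    pmax(0, e + stats::rnorm(length(tt), sd = cfg$noise_sd_envelope)))
  grf <- cfg$subject_mass * 9.81 * grf_shape(s)
  trial <- structure(list(
    time = tt,
    envelopes = envelopes,
    ankle_angle = shapes$theta_ank,
    mtp_angle = shapes$theta_mtp,
    arch_length = shapes$arch,
    ankle_moment = moment,
    grf_vertical = grf,
    sample_rate = fs,
    subject_mass = cfg$subject_mass,
    speed = cfg$speed,
    stride_duration = T,
    units = c(time = "s", envelopes = "mvc", ankle_angle = "rad",
              mtp_angle = "rad", arch_length = "m",
              ankle_moment = "N.m/kg", grf_vertical = "N")
  ), class = "synthetic_trial")
  truth <- ground_truth_waveforms(muscles, cfg, amps)
  list(trial = trial, truth = truth)
}

# noise-free ground truth on the stride grid (anchored at true footstrike)
ground_truth_waveforms <- function(muscles, cfg, amps) {
  N <- cfg$grid_points
  T <- cfg$stride_duration
  sg <- (seq_len(N) - 1) / N
  tim <- cfg$envelope_timing
  sh <- gait_shapes(sg)
  omega_ank <- sh$dtheta_ank / T
  omega_mtp <- sh$dtheta_mtp / T
  arch_rate <- sh$darch / T
  gains <- muscle_gain(muscles)
  forces <- lapply(seq_len(nrow(muscles)), function(m) {
    j <- match(muscles$name[m], tim$name)
    cfg$true_scaling * gains[m] * amps[[muscles$name[m]]] *
      periodic_gauss((sg - cfg$true_emd / T) %% 1,
                     tim$center_pct[j] / 100, tim$width_pct[j] / 100)
  })
  names(forces) <- muscles$name
  p_ank_per <- mapply(function(f, r) f * r * omega_ank, forces,
                      muscles$r_ankle, SIMPLIFY = FALSE)
  r_mtp_f <- muscle_row(muscles, "fdhl")$r_mtp
  foot_power <- -(omega_mtp * r_mtp_f + arch_rate) * forces$fdhl
  mtu_power <- p_ank_per
  mtu_power$fdhl <- p_ank_per$fdhl + foot_power
  structure(list(
    true_emd = cfg$true_emd,
    true_scaling = cfg$true_scaling,
    grid_points = N,
    stride_duration = T,
    true_forces = forces,
    true_mtu_power = mtu_power,
    true_fdhl_foot_power = foot_power,
    true_p_ank_model = Reduce(`+`, p_ank_per),
    omega_ank = omega_ank, omega_mtp = omega_mtp, arch_rate = arch_rate,
    pushoff_bounds_pct = 100 * GAIT$pushoff,
    toeoff_pct = 100 * GAIT$stance_frac
  ), class = "ground_truth")
}

#' Synthesize a raw EMG signal from an envelope
#'
#' Amplitude-modulates a zero-mean, band-limited (150--500 Hz) noise carrier
#' by the given envelope, producing a surface-EMG-like interference signal.
#' Feeding the result through [process_emg()] recovers the envelope up to a
#' constant scale.
#'
#' @param envelope a [sampled_signal()] or numeric vector (non-negative); a
#'   numeric envelope is assumed to be sampled at `fs` already, a
#'   `sampled_signal` is resampled to `fs` by linear interpolation.
#' @param fs output sample rate, Hz; must be >= 1000 (twice the carrier band
#'   top).
#' @param seed integer seed for the carrier noise.
#' @return a [sampled_signal()] at `fs`.
#' @export
synthesize_raw_emg <- function(envelope, fs, seed = 1L) {
  if (fs < 1000)
    stop("sampling error: fs must be >= 1000 Hz (twice the 150-500 Hz carrier band)",
         call. = FALSE)
  if (inherits(envelope, "sampled_signal")) {
    tin <- signal_times(envelope)
    tout <- seq(envelope$t0, max(tin), by = 1 / fs)
    env <- stats::approx(tin, envelope$values, xout = tout, rule = 2)$y
  } else {
    env <- as.numeric(envelope)
  }
  if (any(env < 0)) stop("envelope must be non-negative", call. = FALSE)
  n <- length(env)
  if (all(env == 0)) return(sampled_signal(numeric(n), fs, units = "mV"))
  set.seed(as.integer(seed))
  carrier <- stats::rnorm(n)
  ba <- signal::butter(3, c(150, 500) / (fs / 2), type = "pass")
  carrier <- signal::filtfilt(ba, carrier)
  carrier <- carrier / stats::sd(carrier) * sqrt(pi / 2)  # E|carrier| = 1
  sampled_signal(carrier * env, fs, units = "mV")
}
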