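#' Configuration for the maximum-activation sensitivity analysis
#'
#' @param n_iterations Monte Carlo iterations (default 1000).
#' @param activation_range `(low, high)` multiplicative bounds on each
#'   muscle's assumed maximum activation, as fractions of nominal (default
#'   `c(0.5, 1.5)`); factors are drawn i.i.d. uniform within the range.
#' @param seed integer seed.
#' @param refit which calibration constants are refit each iteration:
#'   any subset of `c("emd", "scaling")` (default both, since both are solved
#'   from the empirical data and co-vary with re-normalized EMG).
#' @return object of class `sensitivity_config`.
#' @export
sensitivity_config <- function(n_iterations = 1000L,
                               activation_range = c(0.5, 1.5),
                               seed = 1L,
                               refit = c("emd", "scaling")) {
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (length(activation_range) != 2L || activation_range[1] <= 0 ||
      activation_range[1] > activation_range[2])
    stop("activation_range must be (low, high) with 0 < low <= high", call. = FALSE)
  refit <- match.arg(refit, c("emd", "scaling"), several.ok = TRUE)
  structure(list(n_iterations = as.integer(n_iterations),
                 activation_range = activation_range,
                 seed = as.integer(seed), refit = refit),
            class = "sensitivity_config")
}

#' Rescale envelopes for an altered assumed maximum activation
#'
#' Raising a muscle's assumed maximum activation by a factor shrinks its
#' normalized envelope by the same factor (the envelope is divided by the
#' factor), and vice versa; a factor of 0.5 doubles the envelope, which may
#' then exceed 1.
#'
#' @param envelopes named list of per-muscle envelopes ([stride_waveform()],
#'   [sampled_signal()] or numeric).
#' @param factors named per-muscle positive factors.
#' @return envelopes of the same structure.
#' @export
perturb_activations <- function(envelopes, factors) {
  if (any(factors <= 0))
    stop("parameter error: activation factors must be positive", call. = FALSE)
  out <- envelopes
  for (nm in names(envelopes)) {
    f <- factors[match(nm, names(factors))]
    if (is.na(f))
      stop("no activation factor supplied for muscle '", nm, "'", call. = FALSE)
    out[[nm]] <- scale_signal(envelopes[[nm]], 1 / f)
  }
  out
}

#' Monte Carlo sensitivity of net MTU Push-off work to maximum activations
#'
#' Each iteration draws an independent uniform factor per muscle within
#' `activation_range`, rescales the normalized envelopes accordingly, refits
#' the electromechanical delay and/or scaling constant per the refit policy,
#' recomputes the net plantarflexing MTU power `P'_MTU`, and integrates its
#' positive part over the Push-off window (located once, from the
#' inverse-dynamics power). Iterations whose fit degenerates are excluded and
#' counted, with a warning.
#'
#' @param envelopes named list of nominal per-muscle [stride_waveform()]s.
#' @param muscles a `muscle_set`.
#' @param omega_ank,p_ank [stride_waveform()]s: ankle angular velocity and
#'   inverse-dynamics ankle power.
#' @param foot a [foot_kinematics()].
#' @param stride_duration stride period, s.
#' @param toeoff_pct toe-off position, % stride.
#' @param cfg a [sensitivity_config()].
#' @param mass subject mass, kg; when supplied, work is reported in J rather
#'   than J/kg.
#' @return object of class `sensitivity_result`: `nominal_work`,
#'   `work_samples`, `min_work`, `max_work`, `max_relative_change` (%),
#'   `n_excluded`, `seed`, `units`.
#' @export
run_monte_carlo <- function(envelopes, muscles, omega_ank, p_ank, foot,
                            stride_duration, toeoff_pct,
                            cfg = sensitivity_config(), mass = NA_real_) {
  stopifnot(inherits(cfg, "sensitivity_config"))
  window <- find_pushoff_window(p_ank, toeoff_pct)
  nominal_fit <- fit_emg_model(envelopes, muscles, omega_ank, p_ank,
                               stride_duration, toeoff_pct)
  ctx <- mc_context(envelopes, muscles, omega_ank, p_ank, foot,
                    stride_duration, window, nominal_fit, cfg$refit)
  ones <- stats::setNames(rep(1, nrow(muscles)), muscles$name)
  nominal <- mc_work(ctx, ones)
  set.seed(cfg$seed)
  nm <- nrow(muscles)
  F <- matrix(stats::runif(cfg$n_iterations * nm, cfg$activation_range[1],
                           cfg$activation_range[2]),
              nrow = cfg$n_iterations, ncol = nm)
  colnames(F) <- muscles$name
  works <- rep(NA_real_, cfg$n_iterations)
  for (i in seq_len(cfg$n_iterations)) {
    works[i] <- tryCatch(mc_work(ctx, F[i, ]), error = function(e) NA_real_)
  }
  n_excl <- sum(is.na(works))
  if (n_excl > 0)
    warning(n_excl, " iteration(s) with a degenerate fit were excluded",
            call. = FALSE)
  ok <- works[!is.na(works)]
  scale <- if (is.na(mass)) 1 else mass
  structure(list(
    nominal_work = nominal * scale,
    work_samples = ok * scale,
    min_work = min(ok) * scale,
    max_work = max(ok) * scale,
    max_relative_change = 100 * max(abs(ok - nominal)) / nominal,
    n_excluded = n_excl,
    seed = cfg$seed,
    units = if (is.na(mass)) "J/kg" else "J"
  ), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(paste0("<sensitivity_result> nominal %.3f %s, range [%.3f, %.3f],",
                     " max change %.2f%% (%d sample(s), %d excluded)\n"),
              x$nominal_work, x$units, x$min_work, x$max_work,
              x$max_relative_change, length(x$work_samples), x$n_excluded))
  invisible(x)
}

# ---- vectorized fast path -------------------------------------------------
# Only per-muscle scalar weights change between iterations, so everything
# else (envelope vectors, lag index matrices, window mask) is precomputed.
# A test pins this path against the public per-operation route.

mc_context <- function(envelopes, muscles, omega_ank, p_ank, foot,
                       stride_duration, window, nominal_fit, refit) {
  env <- lapply(muscles$name, function(nm) wf_values(envelopes[[nm]]))
  names(env) <- muscles$name
  fdhl <- muscle_row(muscles, "fdhl")
  n <- length(env[[1]])
  list(
    env = env,
    w_moment = stats::setNames(muscle_gain(muscles) * muscles$r_ankle,
                               muscles$name),
    gain_fdhl = muscle_gain(fdhl),
    r_mtp_fdhl = fdhl$r_mtp,
    omega = wf_values(omega_ank),
    y = wf_values(p_ank),
    lengthening_rate = wf_values(foot$omega_mtp) * fdhl$r_mtp +
      wf_values(foot$arch_rate),
    lag_grid = seq(0, emd_search_max(), by = stride_duration / n),
    stride_duration = stride_duration,
    mask = window_mask(p_ank, window),
    tsec = stride_pct(p_ank)[window_mask(p_ank, window)] / 100 * stride_duration,
    nominal_emd = nominal_fit$emd,
    nominal_scaling = nominal_fit$scaling,
    refit = refit
  )
}

mc_work <- function(ctx, factors) {
  u <- 0
  for (nm in names(ctx$env)) u <- u + (ctx$w_moment[[nm]] / factors[[nm]]) * ctx$env[[nm]]
  if ("emd" %in% ctx$refit) {
    P <- shifted_power_matrix(u, ctx$omega, ctx$lag_grid, ctx$stride_duration)
    r <- as.vector(stats::cor(P, ctx$y))
    best <- which.max(r)
    tau <- ctx$lag_grid[best]
    p_unscaled <- P[, best]
  } else {
    tau <- ctx$nominal_emd
    p_unscaled <- shift_waveform(u, tau, ctx$stride_duration) * ctx$omega
  }
  C <- if ("scaling" %in% ctx$refit) {
    pk <- max(p_unscaled[ctx$mask])
    if (pk <= 0) stop("degenerate fit: no positive model peak in window")
    max(ctx$y[ctx$mask]) / pk
  } else ctx$nominal_scaling
  f_fdhl <- C * (ctx$gain_fdhl / factors[["fdhl"]]) *
    shift_waveform(ctx$env[["fdhl"]], tau, ctx$stride_duration)
  p_mtu <- C * p_unscaled - ctx$lengthening_rate * f_fdhl
  pracma::trapz(ctx$tsec, pmax(p_mtu[ctx$mask], 0))
}
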