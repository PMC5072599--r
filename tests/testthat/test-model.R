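test_that("unscaled force: arithmetic, shifting, and lag bounds", {
  n <- 100
  ms <- make_muscle_set()
  sol <- ms[ms$name == "soleus", ]
  zero <- unscaled_force(stride_waveform(numeric(n)), sol, 0.02, 1)
  expect_identical(zero$mean, numeric(n))

  m <- sol; m$pcsa <- 10; m$pennation <- 0
  const <- unscaled_force(stride_waveform(rep(0.5, n)), m, 0.13, 1)
  expect_equal(const$mean, rep(5, n))

  # unit impulse at 40% stride shifted by 5% of the stride lands at 45%
  imp <- numeric(n); imp[41] <- 1  # grid index for 40%
  shifted <- unscaled_force(stride_waveform(imp), m, lag = 0.05,
                            stride_duration = 1)
  expect_equal(which(shifted$mean != 0), 46)
  expect_equal(shifted$mean[46], 10)

  expect_error(unscaled_force(stride_waveform(imp), m, 0.6, 1), "half a stride")
})

test_that("EMD cross-correlation recovers the generator delay", {
  # true delay chosen as an exact multiple of the stride-grid step (1.08 ms)
  # so the undelayed envelopes can be reconstructed by an exact index roll
  tau <- 50 * 1.08 / 1000
  x <- quick_sim(seed = 21L, true_emd = tau)
  tb <- truth_bundle(x)
  env <- lapply(tb$forces, function(f)
    stride_waveform(shift_waveform(f, -tau, tb$stride_duration)$mean,
                    units = "mvc"))
  emd <- estimate_emd(env, x$muscles, tb$omega_ank, tb$p_ank,
                      tb$stride_duration)
  step <- tb$stride_duration / 1000
  expect_lte(abs(as.numeric(emd) - tau), step + 1e-12)
  expect_gt(attr(emd, "correlation"), 0.9999)

  # zero true delay returns zero
  emd0 <- estimate_emd(tb$forces, x$muscles, tb$omega_ank,
                       stride_waveform(tb$p_ank$mean, units = "W/kg"),
                       tb$stride_duration,
                       lag_grid = seq(0, 0.2, by = step))
  # p_ank built from the *delayed* forces: using them directly as envelopes
  # means the best lag is 0
  expect_equal(as.numeric(emd0), 0)

  expect_error(estimate_emd(env, x$muscles, tb$omega_ank,
                            stride_waveform(rep(2, 1000)), tb$stride_duration),
               "undefined-correlation")
  expect_error(estimate_emd(env, x$muscles, tb$omega_ank, tb$p_ank,
                            tb$stride_duration, lag_grid = numeric(0)),
               "lag_grid")
})

test_that("scaling fit matches in-window peaks", {
  up <- half_sine_wf(2, 45, 65)
  id <- half_sine_wf(4, 45, 65)
  w <- pushoff_window(45, 65)
  expect_equal(fit_scaling(up, id, w), 2)
  expect_error(fit_scaling(half_sine_wf(-1, 45, 65), id, w), "degenerate-trial")
})

test_that("noiseless trials recover (tau, C) across the study-like sweep", {
  for (tau in c(0.030, 0.080, 0.130)) {
    for (C in c(1.8, 2.9)) {
      x <- quick_sim(n_strides = 3L, seed = 31L, true_emd = tau,
                     true_scaling = C)
      rep <- run_pipeline(x$trial, x$muscles)
      step <- x$cfg$stride_duration / 1000
      expect_lte(abs(rep$fit$emd - tau), step + 1e-12)
      expect_lt(abs(rep$fit$scaling / C - 1), 0.02)
      expect_gt(rep$fit$r_squared, 0.999)
    }
  }
})

test_that("fitted EMD and scaling stay in the reported physiological bands", {
  # defaults are the speed-preset (tau*, C*) drawn from the study averages
  for (sp in c(0.75, 1.25)) {
    x <- quick_sim(speed = sp, n_strides = 3L, seed = 41L)
    rep <- run_pipeline(x$trial, x$muscles)
    expect_gte(rep$fit$emd, 0.030); expect_lte(rep$fit$emd, 0.130)
    expect_gte(rep$fit$scaling, 1.8); expect_lte(rep$fit$scaling, 2.9)
  }
})

test_that("scale equivariance: k-times envelopes give C/k and identical model power", {
  x <- quick_sim(seed = 22L)
  tb <- truth_bundle(x)
  env <- lapply(tb$forces, function(f) stride_waveform(f$mean, units = "mvc"))
  f1 <- fit_emg_model(env, x$muscles, tb$omega_ank, tb$p_ank,
                      tb$stride_duration, tb$toeoff_pct)
  env_k <- lapply(env, function(e) stride_waveform(2.5 * e$mean, units = "mvc"))
  f2 <- fit_emg_model(env_k, x$muscles, tb$omega_ank, tb$p_ank,
                      tb$stride_duration, tb$toeoff_pct)
  expect_equal(f2$emd, f1$emd)
  expect_equal(f2$scaling, f1$scaling / 2.5, tolerance = 1e-12)
  d1 <- decompose_ankle_power(f1, env, x$muscles, tb$omega_ank,
                              tb$stride_duration)
  d2 <- decompose_ankle_power(f2, env_k, x$muscles, tb$omega_ank,
                              tb$stride_duration)
  expect_equal(d2$pair$model$mean, d1$pair$model$mean, tolerance = 1e-12)
})

test_that("per-muscle powers sum to the model ankle power pointwise", {
  x <- cached_noiseless()
  rep <- x$report
  dec <- decompose_ankle_power(rep$fit, rep$waveforms$envelopes, x$muscles,
                               rep$waveforms$omega_ank,
                               stride_duration(rep$events),
                               p_ank = rep$waveforms$p_ank)
  total <- Reduce(`+`, lapply(dec$pair$per_muscle_power, function(w) w$mean))
  expect_equal(dec$pair$model$mean, total, tolerance = 1e-15)
  # single muscle: the sum is that muscle's power exactly
  one <- dec$pair$per_muscle_power[["soleus"]]$mean
  expect_identical(one, dec$pair$per_muscle_power$soleus$mean)
})

test_that("fit fidelity is the squared Pearson correlation", {
  n <- 1000
  tt <- 2 * pi * (0:(n - 1)) / n
  a <- stride_waveform(sin(3 * tt))
  pair_same <- structure(list(model = a, inverse_dynamics = a),
                         class = "ankle_power_pair")
  expect_equal(evaluate_fit(pair_same), 1)
  pair_orth <- structure(list(model = a,
                              inverse_dynamics = stride_waveform(cos(3 * tt))),
                         class = "ankle_power_pair")
  expect_lt(evaluate_fit(pair_orth), 1e-6)
  pair_flat <- structure(list(model = a,
                              inverse_dynamics = stride_waveform(rep(1, n))),
                         class = "ankle_power_pair")
  expect_error(evaluate_fit(pair_flat), "undefined-correlation")
})
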