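# stride-grid inputs for the Monte Carlo, built from generator truth
mc_inputs <- function(seed = 61L, ...) {
  x <- quick_sim(seed = seed, ...)
  tb <- truth_bundle(x)
  env <- lapply(tb$forces, function(f) stride_waveform(f$mean, units = "mvc"))
  list(x = x, tb = tb, env = env)
}

test_that("activation perturbation rescales envelopes reciprocally", {
  env <- list(soleus = stride_waveform(c(0, 0.5, 1, 0.5, 0.2)),
              fdhl = stride_waveform(c(0.1, 0.9, 0.4, 0, 0)))
  out <- perturb_activations(env, c(soleus = 1, fdhl = 2))
  expect_identical(out$soleus$mean, env$soleus$mean)
  expect_equal(out$fdhl$mean, env$fdhl$mean / 2)
  out2 <- perturb_activations(env, c(soleus = 0.5, fdhl = 0.5))
  expect_equal(out2$soleus$mean, env$soleus$mean * 2)
  expect_gt(max(out2$soleus$mean), 1)  # may exceed 1 by design
  expect_error(perturb_activations(env, c(soleus = 0, fdhl = 1)), "positive")
  expect_error(perturb_activations(env, c(soleus = 1)), "fdhl")
})

test_that("degenerate activation range reproduces the nominal work exactly", {
  z <- mc_inputs()
  res <- run_monte_carlo(z$env, z$x$muscles, z$tb$omega_ank, z$tb$p_ank,
                         z$tb$foot, z$tb$stride_duration, z$tb$toeoff_pct,
                         sensitivity_config(n_iterations = 5,
                                            activation_range = c(1, 1),
                                            seed = 1))
  expect_equal(res$work_samples, rep(res$nominal_work, 5))
  expect_equal(res$max_relative_change, 0)
  expect_equal(res$n_excluded, 0)
})

test_that("a single seeded iteration is reproducible and matches the public route", {
  z <- mc_inputs()
  cfg <- sensitivity_config(n_iterations = 1, seed = 99)
  res1 <- run_monte_carlo(z$env, z$x$muscles, z$tb$omega_ank, z$tb$p_ank,
                          z$tb$foot, z$tb$stride_duration, z$tb$toeoff_pct, cfg)
  res2 <- run_monte_carlo(z$env, z$x$muscles, z$tb$omega_ank, z$tb$p_ank,
                          z$tb$foot, z$tb$stride_duration, z$tb$toeoff_pct, cfg)
  expect_identical(res1$work_samples, res2$work_samples)

  # replicate the draw and walk the public per-operation route
  set.seed(99L)
  factors <- setNames(runif(5, 0.5, 1.5), z$x$muscles$name)
  envp <- perturb_activations(z$env, factors)
  fit <- fit_emg_model(envp, z$x$muscles, z$tb$omega_ank, z$tb$p_ank,
                       z$tb$stride_duration, z$tb$toeoff_pct)
  dec <- decompose_ankle_power(fit, envp, z$x$muscles, z$tb$omega_ank,
                               z$tb$stride_duration, p_ank = z$tb$p_ank)
  d <- compose_decomposition(dec$pair, dec$forces, z$tb$foot, z$x$muscles)
  w <- find_pushoff_window(z$tb$p_ank, z$tb$toeoff_pct)
  manual <- pushoff_metrics(d$p_mtu, w, z$tb$stride_duration)$work
  expect_equal(res1$work_samples, manual, tolerance = 1e-10)
})

test_that("a common activation factor leaves net MTU work unchanged (C absorbs scale)", {
  z <- mc_inputs()
  work_of <- function(env) {
    fit <- fit_emg_model(env, z$x$muscles, z$tb$omega_ank, z$tb$p_ank,
                         z$tb$stride_duration, z$tb$toeoff_pct)
    dec <- decompose_ankle_power(fit, env, z$x$muscles, z$tb$omega_ank,
                                 z$tb$stride_duration, p_ank = z$tb$p_ank)
    d <- compose_decomposition(dec$pair, dec$forces, z$tb$foot, z$x$muscles)
    w <- find_pushoff_window(z$tb$p_ank, z$tb$toeoff_pct)
    pushoff_metrics(d$p_mtu, w, z$tb$stride_duration)$work
  }
  common <- setNames(rep(1.7, 5), z$x$muscles$name)
  expect_equal(work_of(perturb_activations(z$env, common)), work_of(z$env),
               tolerance = 1e-12)
})

test_that("work-sample distribution is seed-invariant up to sampling error", {
  z <- mc_inputs()
  run <- function(seed) run_monte_carlo(
    z$env, z$x$muscles, z$tb$omega_ank, z$tb$p_ank, z$tb$foot,
    z$tb$stride_duration, z$tb$toeoff_pct,
    sensitivity_config(n_iterations = 150, seed = seed))
  a <- run(7); b <- run(1234)
  expect_gt(suppressWarnings(ks.test(a$work_samples, b$work_samples)$p.value),
            0.01)
  expect_equal(a$nominal_work, b$nominal_work)
})
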