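test_that("FDHL ankle power is the pointwise triple product", {
  n <- 500
  zero <- fdhl_ankle_power(stride_waveform(numeric(n)),
                           stride_waveform(rep(2, n)), 0.05)
  expect_identical(zero$mean, numeric(n))
  p <- fdhl_ankle_power(stride_waveform(rep(10, n)),
                        stride_waveform(rep(2, n)), 0.05)
  expect_equal(p$mean, rep(1, n))
  set.seed(1)
  f <- runif(n); w <- rnorm(n)
  got <- fdhl_ankle_power(stride_waveform(f), stride_waveform(w), 0.035)
  expect_equal(got$mean, w * 0.035 * f)  # elementwise oracle
})

test_that("FDHL foot power: lengthening under force absorbs energy", {
  n <- 400
  wf0 <- stride_waveform(numeric(n))
  f <- stride_waveform(rep(5, n))
  # zero MTP rotation, constant arch length -> zero foot power
  foot0 <- foot_kinematics(wf0, wf0, wf0)
  expect_identical(fdhl_foot_power(f, foot0, 0.008)$mean, numeric(n))
  # toe dorsiflexion (positive omega_mtp) with positive force -> negative power
  foot_d <- foot_kinematics(stride_waveform(rep(1, n)), wf0, wf0)
  expect_true(all(fdhl_foot_power(f, foot_d, 0.008)$mean < 0))
  # arch lengthening alone -> negative power as well
  foot_a <- foot_kinematics(wf0, stride_waveform(rep(0.01, n)), wf0)
  expect_true(all(fdhl_foot_power(f, foot_a, 0.008)$mean < 0))
})

test_that("pipeline FDHL foot power tracks the generator truth", {
  x <- cached_noiseless()
  d <- x$report$decomposition
  truth <- x$truth$true_fdhl_foot_power
  expect_gt(cor(d$p_fdhl_foot$mean, truth), 0.98)
  # the 6 Hz kinematic low-pass attenuates the MTP velocity peak slightly
  expect_equal(max(abs(d$p_fdhl_foot$mean)), max(abs(truth)), tolerance = 0.2)
})

# decomposition assembled directly from generator ground truth (no pipeline)
truth_decomposition <- function(x) {
  tb <- truth_bundle(x)
  pair <- structure(list(
    model = stride_waveform(x$truth$true_p_ank_model, units = "W/kg"),
    inverse_dynamics = NULL, angular_velocity = tb$omega_ank),
    class = "ankle_power_pair")
  forces <- structure(list(force = tb$forces), class = "mtu_force_set")
  compose_decomposition(pair, forces, tb$foot, x$muscles)
}

test_that("bookkeeping identities hold pointwise at machine precision", {
  x <- quick_sim(seed = 51L)
  d <- truth_decomposition(x)
  scale <- max(abs(d$p_ank_model$mean))
  expect_lt(max(abs(d$p_fdhl$mean - d$p_fdhl_ank$mean - d$p_fdhl_foot$mean)),
            1e-12 * scale)
  expect_lt(max(abs(d$p_mtu_min$mean - d$p_ank_model$mean + d$p_fdhl_ank$mean)),
            1e-12 * scale)
  expect_lt(max(abs((d$p_mtu$mean - d$p_mtu_min$mean) - d$p_fdhl$mean)),
            1e-12 * scale)
  # net MTU power equals the sum of the generator's true per-MTU powers
  expect_equal(d$p_mtu$mean, Reduce(`+`, x$truth$true_mtu_power),
               tolerance = 1e-9)
})

test_that("degenerate FDHL limits: no force, and isometric cancellation", {
  x <- quick_sim(seed = 52L)
  tb <- truth_bundle(x)
  n <- 1000
  # FDHL force identically zero -> no multiarticular effect at all
  forces0 <- tb$forces
  forces0$fdhl <- stride_waveform(numeric(n), units = "N/kg")
  pair <- structure(list(model = stride_waveform(x$truth$true_p_ank_model),
                         inverse_dynamics = NULL, angular_velocity = tb$omega_ank),
                    class = "ankle_power_pair")
  d0 <- compose_decomposition(pair, structure(list(force = forces0),
                                              class = "mtu_force_set"),
                              tb$foot, x$muscles)
  expect_identical(d0$p_mtu$mean, d0$p_ank_model$mean)
  expect_identical(d0$p_mtu_min$mean, d0$p_ank_model$mean)

  # isometric FDHL: foot-side lengthening exactly cancels the ankle side
  fdhl <- x$muscles[x$muscles$name == "fdhl", ]
  omega_mtp_iso <- stride_waveform(tb$omega_ank$mean * fdhl$r_ankle / fdhl$r_mtp)
  foot_iso <- foot_kinematics(omega_mtp_iso, stride_waveform(numeric(n)),
                              tb$omega_ank)
  d_iso <- compose_decomposition(pair, structure(list(force = tb$forces),
                                                 class = "mtu_force_set"),
                                 foot_iso, x$muscles)
  scale <- max(abs(d_iso$p_ank_model$mean))
  expect_lt(max(abs(d_iso$p_fdhl$mean)), 1e-12 * scale)
  expect_equal(d_iso$p_mtu$mean, d_iso$p_mtu_min$mean, tolerance = 1e-12)

  # missing FDHL force is a configuration error
  expect_error(compose_decomposition(
    pair, structure(list(force = tb$forces[c("soleus")]),
                    class = "mtu_force_set"), tb$foot, x$muscles),
    "fdhl")
})

test_that("Push-off window: half-sine construction and error cases", {
  w <- find_pushoff_window(half_sine_wf(3, 45, 65), toeoff_pct = 65)
  expect_equal(w$start, 45, tolerance = 0.3)
  expect_equal(w$end, 65, tolerance = 0.3)
  expect_error(find_pushoff_window(half_sine_wf(-3, 45, 65), 65), "no-pushoff")
  # positive power only after toe-off does not count
  expect_error(find_pushoff_window(half_sine_wf(3, 70, 90), 65), "no-pushoff")
})

test_that("detected Push-off window matches the generator burst bounds", {
  x <- cached_noiseless()
  w <- x$report$window
  expect_equal(w$start, x$truth$pushoff_bounds_pct[1], tolerance = 2)
  expect_equal(w$end, min(x$truth$pushoff_bounds_pct[2], x$truth$toeoff_pct),
               tolerance = 2)
})

test_that("Push-off metrics: half-sine closed form and mass scaling", {
  A <- 3; T <- 1.1
  p <- half_sine_wf(A, 45, 65)
  w <- pushoff_window(45, 65)
  m <- pushoff_metrics(p, w, stride_duration = T, mass = 70)
  d <- 0.2 * T
  expect_equal(m$peak_power, A, tolerance = 1e-4)
  expect_equal(m$work, 2 * A * d / pi, tolerance = 1e-3)
  expect_equal(m$peak_power_abs, m$peak_power * 70)
  expect_equal(m$work_abs, m$work * 70)
  m2 <- pushoff_metrics(p, w, stride_duration = T, mass = 140)
  expect_equal(m2$work_abs, 2 * m$work_abs)
  expect_equal(m2$work, m$work)
  z <- pushoff_metrics(stride_waveform(numeric(1000)), w, T)
  expect_equal(z$peak_power, 0); expect_equal(z$work, 0)
})

test_that("overestimate algebra: 100 f/(1-f), zero limit, monotonicity", {
  n <- 1000
  B <- half_sine_wf(5, 45, 65)$mean
  w <- pushoff_window(45, 65)
  over_for <- function(f) {
    d <- structure(list(
      p_ank_model = stride_waveform(B, units = "W/kg"),
      p_fdhl_ank = stride_waveform(f * B, units = "W/kg"),
      p_fdhl_foot = stride_waveform(numeric(n), units = "W/kg"),
      p_fdhl = stride_waveform(f * B, units = "W/kg"),
      p_mtu_min = stride_waveform((1 - f) * B, units = "W/kg"),
      p_mtu = stride_waveform(B, units = "W/kg")),
      class = "mtu_power_decomposition")
    overestimate_report(d, w, stride_duration = 1.08)
  }
  ov <- over_for(0.066)
  pk <- ov$overestimate_pct[ov$target == "p_mtu_min" & ov$metric == "peak_power"]
  expect_equal(pk, 100 * 0.066 / (1 - 0.066), tolerance = 1e-9)
  expect_equal(ov$overestimate_pct[ov$target == "p_mtu"], c(0, 0))
  ov0 <- over_for(0)
  expect_equal(ov0$overestimate_pct, rep(0, 4))
  peaks <- vapply(c(0.05, 0.10, 0.20), function(f) {
    o <- over_for(f)
    o$overestimate_pct[o$target == "p_mtu_min" & o$metric == "peak_power"]
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})
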