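test_that("square-root timing laws scale as advertised", {
  cfg <- firefly_config(k_synch = 0.5, k_desynch = 0.9, c_desynch = 0.05)
  expect_equal(synch_time(0, cfg), 0)
  expect_equal(synch_time(0.04, cfg), 0.1)
  periods <- c(0.01, 0.1, 1)
  expect_equal(synch_time(4 * periods, cfg), 2 * synch_time(periods, cfg))
  expect_true(all(diff(synch_time(periods, cfg)) > 0))
  expect_true(all(diff(desynch_time(periods, cfg)) > 0))
  # stage ordering holds across the whole default grid at 500 Hz
  st <- stage_times(cfg, suppressWarnings(frequency_grid(cfg, 500)))
  expect_true(all(cfg$t_start < st$t_synch & st$t_synch < st$t_desynch &
                    st$t_desynch < st$t_end))
})

test_that("phase trajectories are continuous, slow-only, and hit the target", {
  cfg <- firefly_config()
  tt <- seq(-2, 2, by = 1 / 500)
  for (f0 in c(2, 10, 40)) {
    for (dphi in c(-3, -0.5, 0.5, 3)) {
      traj <- phase_trajectory(f0, dphi, cfg, phi_target = 0.7)
      ph <- phase_at(traj, tt)
      # sampled increments never exceed the baseline slope plus the rebound
      # ramp (phase only advances faster during desynchronization)
      ramp <- traj$delta_phi_prime / (traj$t_end - traj$t_desynch)
      expect_lte(max(diff(ph)), (2 * pi * f0 + ramp) / 500 + 1e-9)
      # ... and slowing-only alignment: no increment above baseline before
      # the desynchronization stage
      pre_desynch <- tt < traj$t_desynch - 1 / 500
      expect_lte(max(diff(ph[pre_desynch])), 2 * pi * f0 / 500 + 1e-9)
      # at t_synch the phase equals the target oscillation phase (mod 2pi)
      target_phase <- 2 * pi * f0 * (traj$t_synch - cfg$t_start) + 0.7
      mismatch <- phase_at(traj, traj$t_synch) - target_phase
      expect_lt(abs(((mismatch + pi) %% (2 * pi)) - pi), 1e-8)
      # after t_end the baseline offset is restored exactly
      late <- tt[tt > traj$t_end]
      expect_equal(phase_at(traj, late),
                   2 * pi * f0 * (late - cfg$t_start) + 0.7 + dphi)
    }
  }
  # zero offset: trajectory indistinguishable from an unmodulated oscillation
  traj0 <- phase_trajectory(10, 0, cfg, phi_target = 0.2)
  expect_equal(phase_at(traj0, tt), 2 * pi * 10 * (tt - cfg$t_start) + 0.2)
})

test_that("model instantaneous frequency is the phase derivative", {
  cfg <- firefly_config(t_start = 0.08, k_synch = 0.5)
  # f0 = 10 Hz, delta_phi' = pi, t_synch - t_start = 0.2 -> 7.5 Hz while slowing
  traj <- phase_trajectory(10, pi, cfg)
  traj$t_synch <- traj$t_start + 0.2
  expect_equal(inst_frequency_model(traj, traj$t_start + 0.1), 7.5)
  # zero offset: constant frequency
  traj0 <- phase_trajectory(10, 0, cfg)
  expect_equal(inst_frequency_model(traj0, seq(-1, 1, by = 0.01)),
               rep(10, 201))
  # numerical derivative of phase_at matches inst_frequency_model off-boundary
  traj <- phase_trajectory(6.25, 2.2, cfg)
  h <- 1e-6
  for (t in c(-0.5, traj$t_start + 0.03, (traj$t_synch + traj$t_desynch) / 2,
              traj$t_desynch + 0.4, traj$t_end + 0.1)) {
    num <- (phase_at(traj, t + h) - phase_at(traj, t - h)) / (2 * h) / (2 * pi)
    expect_equal(num, inst_frequency_model(traj, t), tolerance = 1e-4)
  }
  # the frequency excursion integrates to zero over the modulated window
  tt <- seq(traj$t_start, traj$t_end, length.out = 20001)
  excursion <- inst_frequency_model(traj, tt) - traj$f0
  expect_equal(mean(excursion) * (traj$t_end - traj$t_start), 0,
               tolerance = 1e-3)
})

test_that("the synthetic spectrum is a 1/f power law with a normalized alpha bump", {
  grid <- seq(0.5, 45, by = 0.1)
  w0 <- synthetic_spectrum(grid, alpha_gain = 1)
  # power (weight^2) proportional to 1/f when the alpha bump is absent
  expect_equal(w0$weight^2, (1 / grid) / sum(1 / grid))
  w <- synthetic_spectrum(grid, alpha_peak_hz = 10, alpha_gain = 2)
  expect_equal(sum(w$weight^2), 1)
  sub <- w[w$frequency >= 6 & w$frequency <= 14, ]
  expect_lt(abs(sub$frequency[which.max(sub$weight)] - 10), 0.25)
  w5 <- synthetic_spectrum(grid, alpha_peak_hz = 10, alpha_gain = 5)
  sub5 <- w5[w5$frequency >= 6 & w5$frequency <= 14, ]
  expect_lt(abs(sub5$frequency[which.max(sub5$weight)] - 10), 0.15)
})

test_that("a single spectral line simulates as a pure locked oscillation", {
  sp <- sp_small()
  cfg <- firefly_config(f_min = 10, f_max = 10.4, f_step = 1,
                        responding_fraction = 1, n_trials = 5,
                        phi_target = 0.9, rng_seed = 5)
  grid <- frequency_grid(cfg, sp$rate)
  expect_equal(grid, 10)
  w <- tibble::tibble(frequency = 10, weight = 1)
  e <- simulate_firefly(cfg, w = w, sampling = sp)
  m <- epoch_matrix(e)
  tt <- time_points(sp)
  st <- stage_times(cfg, 10)
  # while phase-locked every trial equals the target oscillation exactly
  locked <- tt >= st$t_synch & tt <= st$t_desynch
  target <- cos(2 * pi * 10 * (tt - cfg$t_start) + 0.9)
  for (j in 1:5) expect_equal(m[locked, j], target[locked], tolerance = 1e-10)
  # in the baseline each trial is a unit sinusoid of unknown phase (sampled
  # peak can miss the true peak by up to half a sample)
  pre <- tt < cfg$t_start
  expect_true(all(apply(m[pre, ], 2, max) > 0.99))
  expect_true(all(apply(m[pre, ], 2, max) <= 1 + 1e-12))
})

test_that("simulation is deterministic under a seed and trials differ without one", {
  sp <- sp_small()
  e1 <- simulate_firefly(cfg_small(), sampling = sp)
  e2 <- simulate_firefly(cfg_small(), sampling = sp)
  expect_identical(e1$value, e2$value)
  m <- epoch_matrix(e1)
  expect_gt(sd(m[, 1] - m[, 2]), 0)   # independent draws per trial
})

test_that("total power is conserved once the modulation cycle completes", {
  # amplitudes never change, so per-trial variance over a pure-baseline
  # window before the stimulus must match one after every oscillation has
  # returned to baseline (t_end of the slowest grid frequency)
  cfg <- firefly_config(f_min = 0.5, f_max = 60, f_step = 0.25, n_trials = 100,
                        rng_seed = 11)
  t_end_max <- max(stage_times(cfg, frequency_grid(cfg, 500))$t_end)
  sp <- sampling_spec(500, -2, t_end_max + 1.1)
  e <- simulate_firefly(cfg, sampling = sp)
  m <- epoch_matrix(e)
  v_pre <- apply(m[window_mask(sp, -1, 0), ], 2, var)
  v_post <- apply(m[window_mask(sp, t_end_max, t_end_max + 1), ], 2, var)
  p <- t.test(log(v_pre), log(v_post), paired = TRUE)$p.value
  expect_gt(p, 0.01)
})

test_that("without phase alignment the trial average vanishes as 1/sqrt(n)", {
  sp <- sp_small()
  cfg <- cfg_small(responding_fraction = 0, n_trials = 100)
  e <- simulate_firefly(cfg, sampling = sp)
  m <- epoch_matrix(e)
  rms <- function(x) sqrt(mean(x^2))
  r100 <- rms(rowMeans(m))
  r25 <- rms(rowMeans(m[, 1:25]))
  expect_lt(r100, rms(m[, 1]))          # averaging shrinks amplitude
  expect_lt(r100, r25)                  # and keeps shrinking with n
  expect_lt(r100 / r25, 1 / sqrt(4) * 2.5)  # roughly 1/sqrt(n) scaling
})

test_that("the evoked simulator recovers its template by trial averaging", {
  sp <- sp_small()
  tt <- time_points(sp)
  template <- 0.6 * exp(-((tt - 0.3) / 0.12)^2) * sin(2 * pi * 6 * tt)
  cfg <- cfg_small(n_trials = 100)
  e <- simulate_evoked(cfg, template = template, sampling = sp)
  m <- epoch_matrix(e)
  err100 <- sqrt(mean((rowMeans(m) - template)^2))
  err25 <- sqrt(mean((rowMeans(m[, 1:25]) - template)^2))
  expect_lt(err100, err25)              # error falls with n (LLN)
  expect_gt(cor(rowMeans(m), template), 0.8)
  # zero template: pure stationary background averaging toward zero
  e0 <- simulate_evoked(cfg, template = rep(0, sp$n_samples), sampling = sp)
  m0 <- epoch_matrix(e0)
  expect_lt(sqrt(mean(rowMeans(m0)^2)), 0.5 * sqrt(mean(m0[, 1]^2)))
  expect_error(simulate_evoked(cfg, template = c(1, 2, 3), sampling = sp),
               "template")
})

test_that("grid frequencies at or above Nyquist are excluded with a warning", {
  cfg <- firefly_config(f_min = 100, f_max = 250, f_step = 10)
  expect_warning(g <- frequency_grid(cfg, 500), "Nyquist")
  expect_true(all(g < 250))
  cfg2 <- firefly_config(f_min = 200, f_max = 240, f_step = 10)
  expect_error(suppressWarnings(frequency_grid(cfg2, 100)), "empty")
})
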