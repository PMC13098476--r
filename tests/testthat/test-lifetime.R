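test_that("the breakpoint of an exact two-segment trace is recovered exactly", {
  # rise slope 1 from t = 15 to 40, flat at 25 after: the two fitted lines
  # are exact, so their intersection is t = 40 and tau = 25.0 min
  sig <- piecewise_trace(t_d = 15, t_b = 40, rise = 1, plateau = 0)
  res <- transient_lifetime(sig, 15, 60)
  expect_equal(res$tau, 25.0, tolerance = 1e-10)
  expect_equal(res$t_star, 40.0, tolerance = 1e-10)
  expect_gte(res$n_rise, 3L)
  expect_gte(res$n_plateau, 3L)
})

test_that("a sloped plateau still localizes the breakpoint within one sample", {
  sig <- piecewise_trace(t_d = 15, t_b = 40, rise = 1, plateau = 0.02)
  res <- transient_lifetime(sig, 15, 60)
  expect_lt(abs(res$t_star - 40), 0.5)
})

test_that("flat traces raise a classed no-activation error", {
  tt <- seq(0, 60, 0.5)
  flat <- signal_trace(tt, rep(3, length(tt)), dose_times = 15)
  expect_error(transient_lifetime(flat, 15, 60),
               class = "lifetime_no_activation")
  expect_error(transient_lifetime(flat, 15, 60), class = "lifetime_error")
})

test_that("too-short windows raise an insufficient-data error", {
  sig <- piecewise_trace()
  short <- signal_trace(sig$time[1:5], sig$value[1:5], dose_times = 0)
  expect_error(transient_lifetime(short, 0, 2),
               class = "lifetime_insufficient_data")
})

test_that("lifetime is scale- and shift-equivariant", {
  sig <- piecewise_trace(t_d = 15, t_b = 40, rise = 0.7, plateau = 0.01)
  tau0 <- transient_lifetime(sig, 15, 60)$tau
  for (c_scale in c(2, 0.25, 3.7)) {
    scaled <- signal_trace(sig$time, c_scale * sig$value,
                           dose_times = sig$dose_times)
    expect_equal(transient_lifetime(scaled, 15, 60)$tau, tau0,
                 tolerance = 1e-9)
  }
  for (dt_shift in c(32, -7.5)) {
    shifted <- signal_trace(sig$time + dt_shift, sig$value,
                            dose_times = sig$dose_times + dt_shift)
    expect_equal(transient_lifetime(shifted, 15 + dt_shift,
                                    60 + dt_shift)$tau,
                 tau0, tolerance = 1e-9)
  }
})

test_that("breakpoints on noiseless two-segment traces are within one interval for slope ratios >= 5", {
  for (rise in c(0.5, 1, 2)) {
    for (ratio in c(5, 10, 50)) {
      sig <- piecewise_trace(t_d = 10, t_b = 35, rise = rise,
                             plateau = rise / ratio, t_end = 70)
      res <- transient_lifetime(sig, 10, 70)
      expect_lt(abs(res$t_star - 35), 0.5)
    }
  }
})

test_that("cycle segmentation produces one window per dose with local baselines", {
  sig <- piecewise_trace(t_end = 250)
  times <- c(15, 45.5, 76, 106, 137, 167.5, 219)
  win <- segment_cycles(sig, times)
  expect_identical(nrow(win), 7L)
  expect_equal(win$t_d, times)
  expect_equal(win$window_end, c(times[-1], 250))
  expect_error(segment_cycles(sig, c(45.5, 15)), "sorted")
  expect_error(segment_cycles(sig, c(15, 15)), "sorted")
  expect_error(segment_cycles(sig, c(15, 400)), "span")
  single <- segment_cycles(sig, 15)
  expect_identical(nrow(single), 1L)
  expect_equal(single$window_end, 250)
})

test_that("fatigue report is null on self-comparison and detects waste inhibition", {
  p <- default_params("dnazyme_exoIII")
  cond <- dz_cond(enzymes = c(exoIII = 1.5))
  sch <- dose_schedule(c(15, 45.5, 76, 106, 137, 167.5, 219), eq = 1)
  # observed generated from the ideal model itself: indices ~ 0
  gi <- generate_trace(p, cond, sch, noise = noise_model(sigma = 0),
                       seed = 3, t_end = 250)
  fr0 <- fatigue_report(gi$signal, p, cond, sch)
  expect_true(all(abs(fr0$cycles$fatigue_index) <= 0.02, na.rm = TRUE))
  expect_false(fr0$fatigued)
  # waste inhibition in the generator: positive, non-decreasing indices
  pw <- update_params(p, K_W = 5)
  gw <- generate_trace(pw, cond, sch, noise = noise_model(sigma = 0),
                       seed = 3, t_end = 250)
  frw <- fatigue_report(gw$signal, p, cond, sch)
  f <- frw$cycles$fatigue_index
  expect_true(all(f > 0, na.rm = TRUE))
  expect_true(all(diff(f[!is.na(f)]) >= -1e-6))
  expect_true(frw$fatigued)
})

test_that("reporter depletion makes per-cycle amplitudes strictly decrease", {
  p <- default_params("dnazyme_exoIII")
  cond <- dz_cond(enzymes = c(exoIII = 1.5))
  sch <- dose_schedule(c(15, 45.5, 76, 106, 137, 167.5, 219), eq = 1)
  g <- generate_trace(p, cond, sch, noise = noise_model(sigma = 0),
                      seed = 1, t_end = 250)
  lt <- cycle_lifetimes(g$signal, c(15, 45.5, 76, 106, 137, 167.5, 219))
  expect_true(all(diff(lt$delta_signal) < 0))
})
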