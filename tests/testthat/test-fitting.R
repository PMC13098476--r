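test_that("a noiseless single-condition fit recovers the free parameter within 1%", {
  p <- default_params("dnazyme_exoIII")
  cond <- dz_cond()
  sch <- dose_schedule(15, eq = 1)
  g <- generate_trace(p, cond, sch, noise = noise_model(sigma = 0),
                      seed = 1, t_end = 120)
  fit <- fit_parameters(list(fit_experiment(g$signal, cond, sch)),
                        free = "c_exo",
                        lower = c(c_exo = 0.03), upper = c(c_exo = 3),
                        params_base = p, seed = 1, n_starts = 3)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["c_exo"]] - p$c_exo) / p$c_exo, 0.01)
  expect_true(fit$identifiable[["c_exo"]])
})

test_that("a flat trace is flagged structurally non-identifiable", {
  p <- default_params("dnazyme_exoIII")
  cond <- dz_cond()
  flat <- signal_trace(seq(0, 100, 0.5), rep(0, 201), "fluor520",
                       normalization = "delta", dose_times = 15)
  fit <- fit_parameters(list(fit_experiment(flat, cond,
                                            dose_schedule(15, eq = 1))),
                        free = "k_cat_rep",
                        lower = c(k_cat_rep = 0.01),
                        upper = c(k_cat_rep = 1),
                        params_base = p, seed = 1, n_starts = 2)
  expect_false(fit$identifiable[["k_cat_rep"]])
})

test_that("fitting validates its inputs", {
  p <- default_params("dnazyme_exoIII")
  expect_error(fit_parameters(list(), free = character(0),
                              lower = numeric(0), upper = numeric(0),
                              params_base = p), "non-empty")
  sig <- piecewise_trace()
  e <- fit_experiment(sig, dz_cond(), dose_schedule(15, eq = 1))
  expect_error(fit_parameters(list(e), free = "c_exo",
                              lower = c(c_exo = -1), upper = c(c_exo = 2),
                              params_base = p), "bounds")
  expect_error(fit_parameters(list(e), free = "c_exo",
                              lower = c(c_exo = 1), upper = c(c_exo = 0.5),
                              params_base = p), "bounds")
})

test_that("the fit is invariant to channel rescaling under inverse-variance weights", {
  p <- default_params("dnazyme_exoIII")
  cond <- dz_cond()
  sch <- dose_schedule(15, eq = 1)
  g <- generate_trace(p, cond, sch, noise = noise_model(sigma = 0.02),
                      seed = 4, t_end = 120)
  fit1 <- fit_parameters(list(fit_experiment(g$signal, cond, sch)),
                         free = "c_exo",
                         lower = c(c_exo = 0.03), upper = c(c_exo = 3),
                         params_base = p, seed = 2, n_starts = 2)
  # rescale the trace and the signal map consistently: same information
  scaled <- g$signal
  scaled$value <- 10 * scaled$value
  p_scaled <- update_params(p, alpha_F = 10 * p$alpha_F)
  fit2 <- fit_parameters(list(fit_experiment(scaled, cond, sch)),
                         free = "c_exo",
                         lower = c(c_exo = 0.03), upper = c(c_exo = 3),
                         params_base = p_scaled, seed = 2, n_starts = 2)
  expect_equal(fit2$estimates[["c_exo"]], fit1$estimates[["c_exo"]],
               tolerance = 1e-6)
})

test_that("predicted lifetime follows the zero-order closed form and its scalings", {
  # saturated digestion, fast hybridization: tau ~ Fuel0 / (c * U * phi(L))
  p <- update_params(default_params("dnazyme_exoIII"),
                     k_hyb_dz = 200, Km_exo = 0.002, k_cat_rep = 0.05)
  U <- 0.5
  fuel0 <- 7.5
  cond <- dz_cond(totals = c(S1 = 0.25, Rep = 2.5), enzymes = c(exoIII = U),
                  ref_conc = 2.5)
  sch <- list(dose_event(0, "Fuel", amount = fuel0))
  tau <- predict_lifetime(p, cond, sch, t_end = 120)
  expect_lt(abs(tau - fuel0 / (p$c_exo * U)) / (fuel0 / (p$c_exo * U)), 0.05)
  tau_2f <- predict_lifetime(p, cond,
                             list(dose_event(0, "Fuel", amount = 2 * fuel0)),
                             t_end = 220)
  expect_lt(abs(tau_2f / tau - 2), 0.05)
  cond_2u <- dz_cond(totals = c(S1 = 0.25, Rep = 2.5),
                     enzymes = c(exoIII = 2 * U), ref_conc = 2.5)
  tau_2u <- predict_lifetime(p, cond_2u, sch, t_end = 120)
  expect_lt(abs(tau_2u / tau - 0.5), 0.05)
})

test_that("a 3-nt toe-hold always lengthens the predicted lifetime", {
  p <- default_params("dnazyme_exoIII")
  sch <- dose_schedule(15, eq = 1)
  tau0 <- predict_lifetime(p, dz_cond(L_fuel = 0), sch, t_end = 400)
  tau3 <- predict_lifetime(p, dz_cond(L_fuel = 3), sch, t_end = 400)
  expect_gt(tau3, tau0)
})

test_that("noiseless recovery is exact to within 1% and intervals come from the bootstrap", {
  p <- default_params("dnazyme_exoIII")
  design <- list(list(cond = dz_cond(), schedule = dose_schedule(15, eq = 1),
                      t_end = 120))
  rec <- recovery_experiment(p, design, free = "c_exo",
                             lower = c(c_exo = 0.03), upper = c(c_exo = 3),
                             noise = noise_model(sigma = 0), n_reps = 2,
                             seed = 9, n_starts = 2, bootstrap = 10)
  expect_true(all(rec$summary$mare < 0.01))
  expect_true(all(rec$summary$coverage >= 0, na.rm = TRUE))
})
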