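test_that("toe-hold rate factor is 1 at zero overhang and decays monotonically", {
  p <- kinetic_params()
  expect_identical(toehold_rate_factor(0, "exoIII", p), 1)
  expect_identical(toehold_rate_factor(0, "t7", p), 1)
  phis <- toehold_rate_factor(0:3, "exoIII", p)
  expect_true(all(diff(phis) < 0))
  expect_true(all(phis > 0 & phis <= 1))
  # hard-cutoff mode zeroes beyond the enzyme's tolerated overhang
  expect_identical(toehold_rate_factor(5, "exoIII", p, mode = "cutoff"), 0)
  expect_gt(toehold_rate_factor(12, "t7", p, mode = "cutoff"), 0)
  expect_identical(toehold_rate_factor(13, "t7", p, mode = "cutoff"), 0)
  expect_error(toehold_rate_factor(-1, "exoIII", p), "non-negative")
})

test_that("refitting a synthetic toe-hold series recovers the generating rate factors", {
  # traces generated with imposed digestion-rate factors (1, 0.9, 0.7, 0.2)
  # (effective Vmax scaled per trace); refitting the unit conversion per
  # trace recovers each factor within 10%
  p <- default_params("dnazyme_exoIII")
  phi_true <- c(1, 0.9, 0.7, 0.2)
  sch <- dose_schedule(10, eq = 1)
  phi_hat <- vapply(phi_true, function(phi) {
    truth <- update_params(p, c_exo = p$c_exo * phi)
    g <- generate_trace(truth, dz_cond(), sch,
                        noise = noise_model(sigma = 0), seed = 1,
                        t_end = 200)
    fit <- fit_parameters(list(fit_experiment(g$signal, dz_cond(), sch)),
                          free = "c_exo",
                          lower = c(c_exo = 0.01), upper = c(c_exo = 3),
                          params_base = p, seed = 1, n_starts = 2)
    fit$estimates[["c_exo"]] / p$c_exo
  }, numeric(1))
  expect_true(all(abs(phi_hat - phi_true) / phi_true <= 0.10))
})

test_that("all five circuit variants have fixed structure and exact moiety vectors", {
  nets <- all_variant_networks()
  expect_identical(vapply(nets, function(n) length(n$species), integer(1)),
                   c(dnazyme_exoIII = 6L, dnazyme_t7 = 6L,
                     trypsin_exoIII = 8L, trypsin_t7 = 8L, coupled = 15L))
  expect_identical(vapply(nets, function(n) length(n$reactions), integer(1)),
                   c(dnazyme_exoIII = 3L, dnazyme_t7 = 3L,
                     trypsin_exoIII = 6L, trypsin_t7 = 6L, coupled = 11L))
  for (net in nets) {
    expect_identical(max(moiety_residuals(net)), 0)  # exact integer arithmetic
  }
})

test_that("declared moieties span directions confirmed by a numeric left-null-space oracle", {
  # independent check: project each moiety vector onto the numeric left null
  # space of N (via SVD) and verify it is reproduced to machine precision
  for (net in all_variant_networks()) {
    N <- net$stoich
    storage.mode(N) <- "double"
    sv <- svd(N, nu = nrow(N))
    r <- sum(sv$d > 1e-10)  # rank; remaining left-singular vectors span ker(N^T)
    null_basis <- sv$u[, (r + 1):nrow(N), drop = FALSE]
    for (v in net$moieties) {
      full <- stats::setNames(numeric(length(net$species)), net$species)
      full[names(v)] <- v
      proj <- null_basis %*% crossprod(null_basis, full)
      expect_lt(max(abs(proj - full)), 1e-10)
    }
  }
})

test_that("rate laws are non-negative on random non-negative states", {
  set.seed(42)
  for (net in all_variant_networks()) {
    p <- default_params(net$circuit_id)
    for (i in 1:20) {
      x <- stats::setNames(stats::runif(length(net$species), 0, 5),
                           net$species)
      expect_true(all(network_rates(net, x, p) >= 0))
    }
  }
})

test_that("builders reject mismatched circuits and missing enzyme loads", {
  p <- kinetic_params()
  expect_error(build_dnazyme_cycle(p, try_cond()), "circuit_id")
  expect_error(build_trypsin_cycle(p, dz_cond()), "circuit_id")
  expect_error(build_coupled_network(p, dz_cond()), "coupled")
  bad <- condition("coupled")
  bad$enzymes[["t7"]] <- NA_real_
  expect_error(build_coupled_network(p, bad), "missing enzyme load")
  bad2 <- dz_cond()
  bad2$ref_conc <- -1
  expect_error(build_dnazyme_cycle(p, bad2), "reference concentration")
})

test_that("without fuel the DNAzyme cycle never cleaves reporter", {
  p <- default_params("dnazyme_exoIII")
  net <- build_dnazyme_cycle(p, dz_cond())
  tr <- integrate_network(net, p, t_end = 100)
  expect_identical(max(tr$state[, "RepCleaved"]), 0)
})

test_that("fully sequestered trypsin with no release pathway never cleaves substrate", {
  p <- update_params(default_params("trypsin_exoIII"),
                     k_off_TA = 1e-12, k_disp = 0)
  net <- build_trypsin_cycle(p, try_cond())
  tr <- integrate_network(net, p,
                          schedule = dose_schedule(15, eq = 2,
                                                   species = "FuelTry"),
                          t_end = 150)
  expect_lt(max(tr$state[, "pNA"]), 1e-6)
})

test_that("trypsin-aptamer binding equilibrium matches the quadratic closed form", {
  p <- update_params(default_params("trypsin_exoIII"),
                     k_on_TA = 20, k_off_TA = 0.2, k_disp = 0)
  net <- build_trypsin_cycle(p, try_cond())
  # start fully dissociated with no fuel or enzyme: only binding acts
  init <- net$init
  init[] <- 0
  init["Try"] <- 0.1; init["Apt"] <- 1
  net$enzymes[] <- 0
  tr <- integrate_network(net, p, init = init, t_end = 2000, dt_out = 10)
  ta_sim <- tr$state[nrow(tr$state), "TryApt"]
  Kd <- p$k_off_TA / p$k_on_TA
  Ttot <- 0.1; Atot <- 1
  ta_exact <- ((Ttot + Atot + Kd) -
               sqrt((Ttot + Atot + Kd)^2 - 4 * Ttot * Atot)) / 2
  expect_lt(abs(ta_sim - ta_exact) / ta_exact, 0.001)
})

test_that("coupled network without T7 never releases trypsin fuel", {
  p <- default_params("coupled")
  cond <- condition("coupled", enzymes = c(t7 = 0), L_tryfuel = 2)
  net <- build_coupled_network(p, cond)
  tr <- integrate_network(net, p, schedule = dose_schedule(30, eq = 2),
                          t_end = 400)
  expect_identical(max(tr$state[, "FuelTry"]), 0)
  expect_identical(max(tr$state[, "AptFuel"]), 0)
  # only the tiny dissociation leak can produce any signal
  expect_lt(max(tr$state[, "pNA"]) / cond$totals[["LBAPNA"]], 0.02)
})

test_that("coupled network without Exo III drives both reporters to completion", {
  p <- default_params("coupled")
  cond <- condition("coupled", enzymes = c(exoIII = 0), L_tryfuel = 2)
  net <- build_coupled_network(p, cond)
  tr <- integrate_network(net, p, schedule = dose_schedule(30, eq = 2),
                          t_end = 6000, dt_out = 5)
  expect_gt(tr$state[nrow(tr$state), "RepCleaved"] / cond$totals[["Rep"]],
            0.95)
  expect_gt(tr$state[nrow(tr$state), "pNA"] / cond$totals[["LBAPNA"]], 0.9)
})
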