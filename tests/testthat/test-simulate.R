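test_that("dose events validate their fields", {
  expect_error(dose_event(-1, eq = 1), "time")
  expect_error(dose_event(0), "exactly one")
  expect_error(dose_event(0, amount = 1, eq = 1), "exactly one")
  expect_error(dose_event(0, amount = -1), "amount")
  expect_error(dose_event(0, eq = 1, dilution = 0), "dilution")
  expect_error(dose_event(0, eq = 1, dilution = 1.2), "dilution")
})

test_that("eq doses convert through the reference concentration", {
  p <- default_params("dnazyme_exoIII")
  net <- build_dnazyme_cycle(p, dz_cond())
  tr_eq <- integrate_network(net, p, schedule = dose_schedule(10, eq = 2),
                             t_end = 11)
  tr_um <- integrate_network(net, p,
                             schedule = list(dose_event(10, "Fuel",
                                                        amount = 5)),
                             t_end = 11)
  expect_equal(tr_eq$state, tr_um$state)
})

test_that("dilution factor scales every species at the dose time", {
  p <- default_params("dnazyme_exoIII")
  net <- build_dnazyme_cycle(p, dz_cond())
  # dilute with zero added amount: all totals shrink by the factor
  tr <- integrate_network(net, p,
                          schedule = list(dose_event(10, "Fuel", amount = 0,
                                                     dilution = 0.8)),
                          t_end = 20)
  i_post <- which(tr$time == 15)
  tot_rep <- tr$state[i_post, "Rep"] + tr$state[i_post, "RepCleaved"]
  expect_equal(unname(tot_rep), 0.8 * 2.5, tolerance = 1e-8)
})

test_that("conserved moieties hold to 1e-8 along trajectories of all five variants", {
  for (net in all_variant_networks()) {
    p <- default_params(net$circuit_id)
    fuel_sp <- if (grepl("^trypsin", net$circuit_id)) "FuelTry" else "Fuel"
    tr <- integrate_network(net, p,
                            schedule = dose_schedule(10, eq = 1,
                                                     species = fuel_sp),
                            t_end = 120)
    expect_lt(max(trace_conservation(tr)), 1e-8)
    expect_gt(min(tr$state), -1e-9)  # non-negativity up to ~10x atol
    expect_true(all(diff(tr$time) > 0))
  }
})

test_that("without dissipation the reporter is cleaved to completion", {
  p <- default_params("dnazyme_exoIII")
  cond <- dz_cond(enzymes = c(exoIII = 0))
  net <- build_dnazyme_cycle(p, cond)
  tr <- integrate_network(net, p, schedule = dose_schedule(0, eq = 1),
                          t_end = 4000, dt_out = 5)
  expect_gt(tr$state[nrow(tr$state), "RepCleaved"] / 2.5, 0.99)
})

test_that("a single fuel dose dissipates back to the initial state", {
  p <- default_params("dnazyme_exoIII")
  net <- build_dnazyme_cycle(p, dz_cond())
  tr <- integrate_network(net, p, schedule = dose_schedule(5, eq = 1),
                          t_end = 300)
  final <- tr$state[nrow(tr$state), ]
  expect_lt(final[["Dz"]] + final[["Fuel"]], 1e-3)      # fuel fully digested
  expect_equal(final[["S1"]], 2.5, tolerance = 1e-3)    # protected strand back
  expect_equal(final[["Waste"]], 2.5, tolerance = 1e-3) # lumped waste = fuel
})

test_that("repeated dosing yields one rise-plateau cycle per dose", {
  p <- default_params("dnazyme_exoIII")
  cond <- dz_cond(enzymes = c(exoIII = 1.5))
  net <- build_dnazyme_cycle(p, cond)
  times <- c(15, 45.5, 76, 106, 137, 167.5, 219)
  tr <- integrate_network(net, p, schedule = dose_schedule(times, eq = 1),
                          t_end = 250)
  sig <- observables(tr, p)
  lt <- cycle_lifetimes(sig, times)
  expect_identical(nrow(lt), 7L)
  expect_true(all(is.na(lt$error)))
  expect_true(all(lt$tau > 0))
  expect_true(all(lt$delta_signal > 0))
})

test_that("observables map concentrations linearly and normalize as declared", {
  p <- update_params(default_params("dnazyme_exoIII"), alpha_F = 2, F0 = 0.5)
  net <- build_dnazyme_cycle(p, dz_cond())
  tr <- integrate_network(net, p, schedule = dose_schedule(5, eq = 1),
                          t_end = 150)
  raw <- observables(tr, p, "fluor520", "raw")
  expect_equal(raw$value, 0.5 + 2 * unname(tr$state[, "RepCleaved"]))
  delta <- observables(tr, p, "fluor520", "delta")
  i_d <- which(tr$time == 5)
  expect_identical(delta$value[i_d], 0)
  mm <- observables(tr, p, "fluor520", "minmax")
  expect_identical(range(mm$value), c(0, 1))
  expect_error(observables(tr, p, "abs405"), "absent")
})

test_that("a trace with no cleavage gives identically zero delta fluorescence", {
  p <- default_params("dnazyme_exoIII")
  net <- build_dnazyme_cycle(p, dz_cond())
  tr <- integrate_network(net, p, t_end = 50)  # no fuel dose
  delta <- observables(tr, p, "fluor520", "delta")
  expect_identical(unique(delta$value), 0)
})

test_that("lifetimes are stable under grid refinement and tighter tolerances", {
  p <- default_params("dnazyme_exoIII")
  net <- build_dnazyme_cycle(p, dz_cond())
  sch <- dose_schedule(15, eq = 1)
  tau_of <- function(dt, rtol, atol) {
    tr <- integrate_network(net, p, schedule = sch, t_end = 150,
                            dt_out = dt, rtol = rtol, atol = atol)
    transient_lifetime(observables(tr, p), 15, 150)$tau
  }
  tau1 <- tau_of(0.5, 1e-8, 1e-10)
  tau2 <- tau_of(0.25, 1e-10, 1e-12)
  expect_lt(abs(tau2 - tau1) / tau1, 0.005)
})

test_that("integration rejects malformed inputs", {
  p <- default_params("dnazyme_exoIII")
  net <- build_dnazyme_cycle(p, dz_cond())
  expect_error(integrate_network(net, p, t_end = 10, dt_out = 0), "dt_out")
  bad_init <- net$init
  bad_init["S1"] <- -1
  expect_error(integrate_network(net, p, init = bad_init, t_end = 10),
               "non-negative")
  expect_error(integrate_network(net, p,
                                 schedule = dose_schedule(c(20, 10), eq = 1),
                                 t_end = 30), "sorted")
  expect_error(integrate_network(net, p,
                                 schedule = dose_schedule(50, eq = 1),
                                 t_end = 30), "dose times")
})
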