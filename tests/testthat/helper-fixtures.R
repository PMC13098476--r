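# Shared fixtures: canonical conditions, a two-segment piecewise-linear
# trace with a known breakpoint, and a minimal one-reaction network for
# analytic SSA checks.

dz_cond <- function(...) condition("dnazyme_exoIII", ...)

try_cond <- function(...) condition("trypsin_exoIII", ...)

# value 0 until t_d, slope `rise` on [t_d, t_b], then plateau with slope
# `plateau` from the breakpoint at t_b; exact two-line intersection at t_b
piecewise_trace <- function(t_d = 15, t_b = 40, rise = 1, plateau = 0,
                            t_end = 60, dt = 0.5, baseline = 0) {
  tt <- seq(0, t_end, by = dt)
  level_b <- baseline + rise * (t_b - t_d)
  v <- ifelse(tt < t_d, baseline,
              ifelse(tt <= t_b, baseline + rise * (tt - t_d),
                     level_b + plateau * (tt - t_b)))
  signal_trace(tt, v, channel = "fluor520", dose_times = t_d)
}

# a bare A -> B first-order network reusing the k_off_TA parameter slot
decay_network <- function(k = 0.1) {
  rx <- dissipCRN:::rxn("decay", "first_order", c(A = -1, B = 1),
                        species = "A", k = "k_off_TA")
  net <- dissipCRN:::new_reaction_network(
    "dnazyme_exoIII", c("A", "B"), list(rx),
    list(total = c(A = 1, B = 1)), c(A = 1, B = 0),
    dz_cond(), "exponential")
  list(net = net, params = update_params(kinetic_params(), k_off_TA = k))
}

all_variant_networks <- function(params_fn = default_params) {
  list(
    dnazyme_exoIII = build_dnazyme_cycle(params_fn("dnazyme_exoIII"),
                                         condition("dnazyme_exoIII")),
    dnazyme_t7 = build_dnazyme_cycle(params_fn("dnazyme_t7"),
                                     condition("dnazyme_t7")),
    trypsin_exoIII = build_trypsin_cycle(params_fn("trypsin_exoIII"),
                                         condition("trypsin_exoIII")),
    trypsin_t7 = build_trypsin_cycle(params_fn("trypsin_t7"),
                                     condition("trypsin_t7")),
    coupled = build_coupled_network(params_fn("coupled"),
                                    condition("coupled", L_tryfuel = 2))
  )
}
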