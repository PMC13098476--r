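# dissipCRN

Kinetic modeling and analysis of dissipative, fuel-driven DNA circuits
that control biocatalysis: a DNAzyme cycle and an aptamer-gated trypsin
cycle, each dissipated by a double-strand-specific exonuclease (Exo III or
T7), and the coupled unidirectional network in which transient DNAzyme
activity releases the trypsin fuel. The package is aimed at systems
chemists and modelers who want to simulate these circuits, extract
transient lifetimes from plate-reader traces, fit rate constants, and
quantify fatigue across repeated fuel additions.

## The model

Each circuit is an explicit reaction network. Activation is fast
hybridization (mass action): fuel + protected strand → active DNAzyme
duplex, or trypsin-fuel + aptamer → duplex, freeing trypsin from its
aptamer complex (`TryApt ⇌ Try + Apt`, optional direct displacement by
fuel). Catalysis and digestion are Michaelis–Menten; an enzyme with
several substrates uses a shared competitive denominator

&nbsp;&nbsp;&nbsp;&nbsp;v_i = E_eff · k_cat,i · (S_i/K_m,i) / (1 + Σ_j S_j/K_m,j),

with E_eff the catalyst concentration (DNAzyme, trypsin) or the converted
exonuclease load V_max = c · U · φ(L). The toe-hold factor
φ(L) = exp(−β·L) encodes how a single-stranded overhang of L nt slows
exonuclease initiation — the circuits' internal timing knob. States map to
observables linearly: fluorescence at 520 nm = F0 + α_F·[cleaved
reporter]; absorbance at 405 nm = A0 + ε_A·[p-nitroaniline].

The **transient lifetime** τ of a cycle is the time from fuel addition to
the intersection of straight-line fits of the initial signal rise and the
post-consumption plateau. Per-cycle lifetimes under repeated dosing,
compared against the ideal waste-free simulation, give the **fatigue
index** f_k = (τ_k − τ̂_k)/τ̂_k.

## Worked example

```r
library(dissipCRN)

p    <- default_params("dnazyme_exoIII")
cond <- condition("dnazyme_exoIII")        # 2.5 uM strand & reporter, 0.5 U/uL Exo III
net  <- build_dnazyme_cycle(p, cond)
sch  <- dose_schedule(15, eq = 1)          # 1 eq fuel dosed at t = 15 min

trace  <- integrate_network(net, p, schedule = sch, t_end = 250)
signal <- observables(trace, p, "fluor520", "delta")
transient_lifetime(signal, t_d = 15)
#> <lifetime_result> tau = 13.09 min (dose 15.0 -> breakpoint 28.09), amplitude 0.634

sapply(c(1, 2, 3), function(eq)
  predict_lifetime(p, cond, dose_schedule(15, eq = eq), t_end = 250))
#> [1] 13.1 25.8 39.2
```

The first call simulates one activation–deactivation cycle and extracts
its lifetime: fuel added at 15 min forms the active DNAzyme, fluorescence
rises while the reporter is cleaved, and Exo III digestion of the fuel
flattens the signal; the fitted rise and plateau lines intersect at
28.1 min, a 13.1-min transient. The second call shows the external control
knob: tripling the fuel roughly triples the lifetime (13 → 26 → 39 min),
because in the near-saturated digestion regime τ ≈ Fuel₀/(c·U·φ(L)).

Other entry points: `ssa_simulate()` (exact stochastic oracle),
`fit_parameters()` / `recovery_experiment()` (multi-start least-squares
estimation and validation), `cycle_lifetimes()` / `fatigue_report()`
(repeated dosing), `suite_design()` / `build_suite()` (synthetic
plate-reader suites on the published concentration grids), and the
`cli_*()` wrappers with a shell script in `inst/cli/dissipcrn`.

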