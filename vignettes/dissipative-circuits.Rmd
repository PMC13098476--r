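---
title: "Kinetic models of exonuclease-dissipated DNA circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models of exonuclease-dissipated DNA circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dissipCRN)
```

## The systems being modeled

dissipCRN models a family of fuel-driven, out-of-equilibrium DNA circuits in
which a DNA "fuel" strand transiently activates a catalyst and a
double-strand-specific exonuclease (Exo III or T7) digests the fuel,
returning the system to its resting state. Three circuit topologies are
covered:

* **DNAzyme cycle** (`dnazyme_exoIII`, `dnazyme_t7`). A protected strand S1
  is inactive alone; hybridization with the fuel forms the active
  two-strand DNAzyme (Dz), which cleaves a dye/quencher reporter strand at
  an internal RNA base (read out as fluorescence at 520 nm). The
  exonuclease digests the fuel out of the duplex, releasing S1 intact.
* **Trypsin cycle** (`trypsin_exoIII`, `trypsin_t7`). Trypsin is silenced
  by a ssDNA aptamer; the trypsin fuel strand sequesters the aptamer into a
  duplex, freeing active trypsin, whose cleavage of L-BAPNA is read out as
  p-nitroaniline absorbance at 405 nm. Digestion of the aptamer/fuel duplex
  releases the aptamer, which re-silences trypsin.
* **Coupled unidirectional network** (`coupled`). The trypsin fuel is held
  dormant in a duplex with an inhibitor strand. The active DNAzyme cleaves
  the inhibitor (competing with the fluorogenic reporter for the same
  active site), T7 digests the cleaved inhibitor and releases the trypsin
  fuel, and Exo III dissipates both fuels. Information flows one way:
  DNAzyme activity gates trypsin activity, never the reverse.

## Rate laws and their assumptions

Networks are explicit species/stoichiometry structures
(`build_dnazyme_cycle()`, `build_trypsin_cycle()`,
`build_coupled_network()`) with three rate-law families:

* **Mass action** for hybridizations (`S1 + Fuel -> Dz` with `k_hyb_dz`,
  `Apt + FuelTry -> AptFuel` with `k_hyb_apt`) and for trypsin-aptamer
  binding (`k_on_TA`, `k_off_TA`). Hybridizations are irreversible: the
  duplexes are designed long enough that spontaneous dissociation is
  negligible on the hours time scale.
* **Michaelis-Menten** for every enzymatic step. Where one enzyme has
  several substrates the rates share a competitive denominator,
  `v_i = E_eff * kcat_i * (S_i/Km_i) / (1 + sum_j S_j/Km_j)`. This is what
  lets reporter concentration modulate inhibitor cleavage in the coupled
  network (both compete for the DNAzyme) and what couples the two Exo III
  substrates (DNAzyme duplex and aptamer/fuel duplex).
* **Enzyme units.** Exonuclease loads are activity units (U/uL), not molar;
  they enter only through `Vmax = c * U * phi(L)` with fitted conversion
  constants `c_exo`, `c_t7` (uM min^-1 per U uL^-1).

The **toe-hold factor** `phi(L) = exp(-beta * L)` models how a
single-stranded overhang of L nucleotides slows exonuclease initiation;
`beta_exo` (default 0.5 nt^-1) is calibrated so that a 3-nt overhang slows
digestion about five-fold, and `beta_t7` (0.09 nt^-1) so the effect spreads
over the 0-12 nt range T7 tolerates. An optional hard-cutoff mode
multiplies by `1[L <= Lmax]` (Lmax 4 nt for Exo III, 12 nt for T7).

**Waste.** Digested fuel is lumped into a single Waste species. The ideal
model ignores it (`K_W = Inf`). The fatigue extension scales the effective
exonuclease load by `1/(1 + [Waste]/K_W)`, emulating the inhibition of the
enzyme by accumulating mononucleotide waste; it is used only by the
synthetic-data generator, never by the reference model a fatigue report
compares against.

## Calibrated defaults

`default_params()` returns per-circuit synthetic truth sets. They are
calibrated — once, before any data are generated — so that the default
suites reproduce the qualitative physics of the published panels:
first-cycle lifetimes of tens of minutes for the single cycles (fuel
titrations spanning roughly 10-50 min, enzyme titrations up to ~100 min)
and of hours for the coupled network. They are synthetic values, not
measurements. Non-obvious choices:

* `k_hyb_dz = 0.5 uM^-1 min^-1`. Activation must be much faster than
  dissipation (the cycles separate an activation phase from a deactivation
  phase) but still resolvable at the 0.5-min sampling cadence, otherwise
  the hybridization rate is structurally non-identifiable from plate-reader
  data. At 2.5 uM partners this gives an activation half-time under a
  minute against deactivation times of 15-100 min.
* `k_disp = 5 uM^-1 min^-1` in the trypsin and coupled truth sets (the
  constructor default is 0). With displacement disabled, trypsin activation
  is rate-limited by complex dissociation; at the higher exonuclease loads
  the fuel is digested before trypsin is released, which inverts the
  enzyme-titration lifetime ordering and contradicts the immediate
  absorbance rise seen experimentally. A fuel strand fully complementary to
  the aptamer can invade the protein-aptamer complex directly, so the
  displacement pathway is physically reasonable; it is switchable off.
* Coupled-network set (`k_cat_rep = 0.002`, `k_cat_inh = 0.008 min^-1`,
  `Km_exo = 1 uM`, totals Try 0.02 / Apt 0.5 / inhibitor duplex 1.5 uM).
  Because both Exo III substrates share one Km, the aptamer/fuel duplex is
  digested at most `phi * AF / Dz` as fast as the DNAzyme duplex while the
  DNAzyme dominates the shared denominator. The only regime in which the
  reporter-competition effect expresses itself as a lifetime ordering
  (trypsin lifetime decreasing in reporter concentration while the DNAzyme
  lifetime stays within 10%) is the one where inhibitor release is slow
  enough to be partially truncated by DNAzyme death. The defaults sit in
  that regime; reporter turnover is kept low so the fluorescence plateau
  reflects fuel dissipation, not reporter exhaustion.

## Simulation

`integrate_network()` uses deSolve's lsoda with rtol 1e-8 / atol 1e-10 uM,
splitting the integration at each dose event: the dose is an instantaneous
concentration jump (`species += amount`, optional global dilution factor,
default 1), after which integration restarts. The internal step is capped
at 20 output intervals — unbounded steps across the long flat plateaus can
break lsoda's dense-output interpolation. Non-negativity is enforced by
tolerance, not clipping; rate evaluation clips negative round-off at zero
so rate laws stay non-negative. Conserved moieties (e.g. `S1 + Dz`,
`Apt + TryApt + AptFuel`) are declared with each network and checked to a
relative 1e-8 along every trajectory between doses.

`ssa_simulate()` is an exact Gillespie direct-method oracle on the same
network. Michaelis-Menten laws are used as mean-field propensities
(deterministic rate at `n/volume` times volume) rather than expanding
enzyme-substrate intermediates; the deterministic model is the object under
test, and at ~1e4 copies its mean agrees with the ODE solution to within a
few percent.

## The transient-lifetime statistic

A cycle's lifetime is the time from fuel addition to the intersection of
two least-squares lines: one through the initial signal rise, one through
the plateau after fuel consumption. The construction fixes the
intersection; the fit windows are a robustness choice exposed in
`lifetime_opts()`:

* rise window: the samples whose baseline-subtracted value lies between
  10% and 60% of the cycle amplitude, taken up to the signal's first
  crossing of the 60% level (amplitude = mean of the trailing plateau
  window minus the local baseline, the signal value at the dose time).
  Cutting at the first upper crossing keeps samples that re-enter the band
  later — for instance on a drifting plateau — out of the rise fit, while
  isolated noise excursions inside the band merely add points to it;
* plateau window: the trailing 25% of the cycle window; a sample qualifying
  for both windows is assigned to the rise fit;
* activation guard: the amplitude must exceed 3 times a robust noise
  estimate (median absolute successive difference / sqrt(2)), which keeps
  the statistic exactly scale-equivariant.

Classed errors distinguish "no activation" (flat trace), "no breakpoint"
(parallel fits, or an intersection outside the window) and "insufficient
data" (< 3 points in a fit window). On noiseless two-segment traces the
breakpoint is recovered to within one sampling interval whenever the slope
ratio is at least ~5; per-cycle amplitudes are measured from local
baselines so reporter depletion across repeated doses is handled.

`fatigue_report()` simulates the ideal (`K_W = Inf`) model on the observed
dose schedule and reports per-cycle indices
`f_k = (tau_obs - tau_ideal)/tau_ideal`; waste-driven fatigue appears as
positive, non-decreasing `f_k`.

## Fitting

`fit_parameters()` minimizes the joint weighted residual sum of squares of
simulated versus observed signals over all conditions simultaneously — one
shared parameter set, mirroring the use of a single fitted set to predict
whole titration panels. Choices:

* optimization in log-parameter space (all parameters are positive scale
  parameters) with Levenberg-Marquardt (minpack.lm) under box bounds;
* multi-start (default 16) from log-uniform draws inside the bounds, all
  seeded. LM's clipped steps can stall against an active bound and trigger
  premature convergence; any start that ends pinned at a bound is rerun
  once from that estimate with the pinned coordinates moved to the
  log-midpoint of the bounds, and the better of the two results kept;
* weights: per-trace inverse noise standard deviations, estimated by the
  robust successive-difference estimator (floored at 1e-6 of the dynamic
  range so noiseless traces remain usable). This makes the fit invariant
  to channel rescaling;
* identifiability: at the optimum, a finite-difference Jacobian column with
  near-zero norm (locally flat objective) or an estimate pinned at a bound
  is reported as non-identifiable rather than silently returned;
* uncertainty: percentile residual bootstrap (refits from the optimum),
  rather than asymptotic covariance — residuals are small and serially
  correlated.

`recovery_experiment()` closes the loop: generate noisy synthetic data from
known truth, refit, and report per-parameter bias, median absolute relative
error and bootstrap coverage. With the three-condition fuel titration at 2%
noise, the median error for `{k_hyb_dz, k_cat_rep, c_exo}` is well under
15%, and errors shrink monotonically as noise decreases.

## The synthetic-data generator

`generate_trace()` and the `suite_design()` presets emulate plate-reader
traces: a monotone rise to plateau after each fuel dose, amplitude set by
reporter/substrate totals, i.i.d. additive Gaussian noise scaled to the
trace's dynamic range (default sigma 2%), optional linear baseline drift,
and an optional post-dose mixing dip `-a * exp(-(t - t_d)/tau_mix)`
(enabled in the coupled-panel preset, where glycerol-containing enzyme
stocks cause an initial dip). Suites use the published concentration grids:
fuel equivalents {1,2,3} and {2,3,4}, Exo III {0.1,0.25,0.5} and
{0.025,0.05,0.1} U/uL, toe-holds {0,1,2,3} nt (Exo III) and {0,5,7,10,12}
nt (T7), and the repeated-dosing time grids of the recyclability panels
(7 doses for the DNAzyme cycle, 25 for the trypsin cycle). Equivalents are
converted through the hybridization partner's total: the protected DNAzyme
strand (2.5 uM) for DNAzyme circuits and the aptamer (1 uM) for trypsin
cycles.

What the generator does **not** emulate: replicate-to-replicate variance
structure (real experiments used n = 3 wells; the i.i.d. Gaussian noise is
a stand-in), instrument export formats, photobleaching, temperature drift,
and sequence-level thermodynamics. Passing tests therefore demonstrate
internal consistency of model, statistic and fitting pipeline — not that
the rate laws are the true mechanism of any particular wet-lab system.

## Problem sizes

The test suite and the acceptance script run deliberately moderate problem
sizes: 0.5-min sampling over 150-400 min windows for single cycles and
1100 min for the coupled network; 200 stochastic runs at ~1e4 copies for
the oracle comparison; 20 seeded replicates (3 multi-starts each) for the
recovery study; 100 seeded replicates for the noise-robustness check of
the breakpoint statistic.

## Known limitations

* Free single-stranded fuel is not an exonuclease substrate in the model
  (the enzymes are double-strand-specific), so free fuel dissipates only
  through duplex cycling; with a saturated aptamer pool this is the
  rate-limiting step of trypsin deactivation.
* Product inhibition of the DNAzyme by cleaved inhibitor fragments is not
  modeled, and digestion releases the protected partner in one step (no
  per-nucleotide intermediates).
* One shared `Km` per exonuclease across its substrates; substrate-specific
  digestion speed differs only through the toe-hold factor.
* The SSA treats Michaelis-Menten rates as propensities; at low copy
  number (< ~1e3) this approximation, and the neglect of enzyme-substrate
  intermediates, would matter.
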