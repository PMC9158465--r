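---
title: "Modeling the hypotonic-shock calcium response of budding yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the hypotonic-shock calcium response of budding yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calshock)
```

## The model

When the growth medium of *Saccharomyces cerevisiae* is suddenly diluted
with water (a hypotonic shock, HTS), water flows into the cell, the cell
swells against its wall, turgor pressure rises, and stretch-activated
(mechanosensitive, MS) calcium channels in the plasma membrane open. The
result is a sharp, transient rise of cytosolic calcium that is cleared
within roughly two minutes. `calshock` implements a coupled ODE model of
this response with four state variables:

* `V_os` — the osmotically active (water) volume of the cell (L),
* `Ca_cyt` — cytosolic calcium (nM),
* `CaMb` — calcium-bound calmodulin (nM),
* `CaNb` — calmodulin-bound (activated) calcineurin (nM).

**Biophysical half.** Water flux follows the imbalance between turgor and
the van't Hoff osmotic pressure difference,

$$\frac{dV_{os}}{dt} = -L_p A(V)\,\bigl(P(V) + c_{PC} R T\,([Osm_e] - [Osm_i])\bigr),$$

with the cell treated as a sphere, internal non-permeable solutes diluted
by the water volume, internal glycerol held constant on this short
horizon, and the reflection coefficient fixed at 1. Turgor follows an
elastic wall law, $P = \varepsilon \ln (V/V_0)$ for $V \ge V_0$ and zero
below the relaxed volume $V_0$, with $V_0 = V(0)e^{-P_0/\varepsilon}$ so
that the resting cell sits exactly at the measured turgor $P_0$. Note the
sign: turgor *increases* as the cell swells past $V_0$, which is what
loads the MS channels — an integrated form of the elastic law with the
opposite sign would contradict the gating mechanism, so the increasing
convention is used throughout. The dilution stimulus relaxes the external
osmolarity (and external calcium) exponentially from its initial value
toward `initial/d` with time constant `t_m`, starting at `t_off`.

**Biochemical half.** Cytosolic calcium obeys a signed sum of fluxes:
gradient-driven influx through the Cch1/Mid1 channel
($j_{Cch1} = k_{Cch1}\,\Delta Ca$) and through the MS channel
($j_{MS} = P_{open}\,k_{MS}\,\Delta Ca$), and Michaelis–Menten efflux
through the Golgi pump Pmr1 and the vacuolar transporters Pmc1 and Vcx1.
MS gating is a Boltzmann function of turgor,
$P_{open} = 1 - 1/(1 + e^{(P - P_{MS})/g_{MS}})$, equal to one half at
$P_{MS}$. Calmodulin binds three calcium ions cooperatively by mass
action; activated calcineurin forms from bound calmodulin. Two feedback
inhibitions close the loop multiplicatively: bound calmodulin inhibits
the MS channel ($1/(1 + k_{I,MS}[CaMb])$) and activated calcineurin
inhibits Vcx1. A third influx ("IN") and a calcineurin feedback on Cch1
belong to the pre-simplification model; both are retained in code behind
default-zero parameters (`v_IN`, `kI_Cch1`) so the fuller model can be
reconstructed, and both are off by default.

The calcium balance does not subtract the calcium consumed by calmodulin
binding — that is how the source model is posed, and the binding flux is
orders of magnitude below the transporter fluxes. A `buffered = TRUE`
flag adds the stoichiometric term for exploration.

## Parameters that matter

All defaults are the fitted wild-type values; every one can be
overridden through `kinetic_params()` / `biophys_params()` or a YAML
config (`read_config()`/`write_config()`).

* `k_MS` (1/s, default 132184) and `k_Cch1` (0.37): channel rates. The
  MS rate is large but the channel is almost shut at rest
  ($P_{open}(P_0) \approx 0.021$) and strongly inhibited by calmodulin.
* `P_MS` (0.76 MPa) and `g_MS` (0.039 MPa): gating midpoint and slope.
  The resting turgor 0.61 MPa sits ~4 slope-widths below the midpoint,
  so modest swelling moves the gate steeply.
* `v_Pmc1`/`k_Pmc1` (280870 nM/s, 4300 nM): the dominant clearance
  route. `v_Vcx1`/`k_Vcx1` are nominally enormous (2.8e6 nM/s) but the
  calcineurin inhibition constant `kI_Vcx1` (9.3e6 1/nM) suppresses the
  flux by >10^5 at physiological activation.
* `km_plus` (1.8e-14 nM^-4 s^-1) with `km_minus = 9000·km_plus`:
  calmodulin binding is quasi-static over 160 s; the MS feedback acts
  through sub-nanomolar changes in `CaMb` amplified by
  `kI_MS` (26395 1/nM). The printed units of `km_plus` and `kn_plus`
  are inconsistent with the mass-action forms by one concentration
  power; the formulas are implemented as printed, with concentrations
  in nM.
* Strains (`strain_config()`): `cnb1` sets `CaN_t = 0` and
  `v_Pmc1 = 41079` (calcineurin-dependent Pmc1 expression), `cch1` sets
  `k_Cch1 = 0` with the same basal `v_Pmc1`, `flc2` raises `k_MS` to
  238519.

## The resting state and its calibration

The true joint equilibrium of the calmodulin equations is months away at
the printed rates, so a resting state is *defined* as: calcium balance
zero at turgor $P_0$, with `CaMb` frozen at a resting value `camb0` and
`CaNb` at its quasi-steady point (calcineurin unbinds at 1000/s, so it
tracks `CaMb` on millisecond timescales). The resting bound calmodulin
is not printed anywhere, and it behaves as a strain-specific quantity,
so `calibrate_resting_calmodulin()` solves for the `camb0` that
reproduces a target baseline: the map is monotone (more bound calmodulin
→ stronger MS inhibition → lower baseline) and inverts in closed form up
to the weak Vcx1 coupling, which a short fixed-point iteration resolves.

Baselines used by the analysis scripts: wild-type 215 nM (the model's
reported steady state); `cch1` and `flc2` also 215 nM; `cnb1` 300 nM.
The mutant values are inputs, not fitted outputs — the source figures
show the `cnb1` rest clearly elevated but print no number, and 300 nM is
within the range the model can reach for that strain (its ceiling with a
fully-shut MS channel is ~275 nM plus the MS leak contribution).

Because `CaMb` keeps creeping toward its mass-action stationary point,
an unstimulated (`d = 1`) run drifts ~1.7% below the calibrated baseline
over 160 s. This is a property of the printed kinetics, not a solver
artifact.

## Numerical choices

* Integrator: `lsoda` (deSolve) — the system is stiff through the
  fast calcineurin relaxation. The right-hand side is compiled C for
  speed; the plain-R `system_rhs()` is the reference implementation and
  tests hold the two equal (and both equal to an independent scalar
  transcription of the equations).
* Tolerances: relative 1e-8; absolute per state, each well below its
  scale — 1e-20 L for the volume (the state itself is ~3e-14 L, so a
  looser absolute tolerance would effectively uncontrol it), 1e-4 nM for
  calcium, 1e-8 nM for the bound proteins (the MS feedback responds to
  sub-nanomolar changes). Tightening everything 10× moves reported
  baselines and peaks by <0.1%.
* The stimulus is continuous but not smooth at `t_off`; integration is
  restarted there.
* Degenerate inputs: bound-protein states are clamped into
  `[0, total]` for RHS evaluation; Michaelis fluxes return 0 at 0/0;
  the Boltzmann exponent is clipped to avoid overflow; the mixing-time
  argmax breaks ties toward the smaller `t_m`.

## Estimation

`fit_traces()` wires a weighted sum-of-squares objective into a
global-best particle swarm. Scope rules mirror how the model was
originally fitted: reaction constants are shared across experiments;
bound-protein initial values (`camb0`) and expression-proxy rates
(`v_Pmc1`, `k_MS`) may vary per experiment. Parameters whose search
range spans ≥3 decades are searched in log10 space. The original
optimizer settings are not printed, so the package declares its own:
swarm 40, 300 iterations, inertia 0.729, cognitive = social = 1.494
(standard constriction values), velocity clamped to half the range,
absorbing bounds, and an early stop once the best loss reaches `ftol`
or stagnates for `patience` iterations. When a candidate parameter
vector cannot reproduce the observed baseline at any `camb0`, the
objective clamps the calibration to the nearest achievable extreme
rather than discarding the candidate, which keeps the loss surface
informative for the swarm. When `k_MS = 0` the resting calibration has
no leverage and `camb0` is flagged non-identifiable instead of being
silently fitted.

## What the synthetic generator does and does not emulate

`synth_dataset()` stands in for aequorin-luminescence recordings: a
pre-stimulus baseline of order 100–300 nM, a transient peak within ~2
minutes of the shock, several replicates per condition, strain- and
dilution-dependent baselines and peaks, sampled at 1 s by default. Noise
is additive-plus-multiplicative Gaussian
(`y = clean(1 + m·ε₁) + a·ε₂`, clamped at zero), with defaults of 10 nM
additive and 2% multiplicative — illustrative values, recorded in every
manifest, since the source data do not state replicate variability. Not
emulated: photon-counting statistics of the luminescence calibration,
cell-to-cell heterogeneity, drift in experimental clocks. Passing
recovery tests on these traces therefore shows the estimation machinery
is sound and the parameters identifiable from clean dynamics of this
shape — not that the pipeline is robust to every artifact of real
recordings.

## Worked example

```{r example, eval = FALSE}
wt <- simulate_strain(strain_config("wild-type", target_baseline = 215))
trace_metrics(wt)
# baseline ~214.6 nM, peak ~1032 nM, time-to-peak ~9 s

scan <- mixing_time_scan(1:40)
attr(scan, "t_m_opt")
# 17: the peak is maximal for an intermediate dilution speed
```

Problem sizes used throughout the package's own analyses: 160-s
simulations on 0.1–1 s output grids, a 40-point mixing-time scan, and
recovery fits of 2 parameters against 81-point traces with a 40-particle
swarm — all chosen to match the scales at which the underlying
quantities are reported.

## Known limitations

* The mixing-time argmax lands at 17 s under this package's resting
  calibration (baseline 215 nM); it is sensitive to the resting
  bound-calmodulin convention, which the source does not print, and
  values from 10–20 s arise for plausible alternatives.
* The stationary baseline with the MS channel off computes to
  ~163 nM against a reported 160 nM (≈2%), again reflecting the
  unprinted resting convention.
* Glycerol efflux (Fps1), longer-term osmoadaptation, transcriptional
  feedback (Crz1), and organelle calcium pools are out of scope; the
  model is only meaningful on the ~160-s horizon.
* `km_minus` is tied to `km_plus` (factor 9000); overriding `km_plus`
  retunes `km_minus` unless both are set explicitly.
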