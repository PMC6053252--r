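---
title: "Gain control by the A-type potassium current: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gain control by the A-type potassium current: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akgain)
```

## The question

Synaptic inhibition can act on a neuron's firing-rate input/output relation
in two qualitatively different ways.  *Divisive* inhibition rescales the
curve — the neuron still responds to arbitrarily weak excitation, but with
reduced gain.  *Subtractive* inhibition shifts the curve rightward, carving
out a dead zone of input rates that evoke no spikes.  This package
implements a biophysical account of what selects between the two modes: the
A-type potassium current (I_A), a fast-activating, slowly-inactivating
outward current that is de-inactivated ("primed") by hyperpolarisation.
When I_A is strong and fast it co-operates with inhibition to veto spike
initiation outright (subtractive); when it is weak or slow it merely thins
out spiking (divisive).

## Models

### Point neuron

The one-compartment model has leak, delayed-rectifier potassium, A-type
potassium and sodium currents,

$$C V' = -g_L(V-V_L) - g_K n^4 (V-V_K) - g_A a^3 b\,(V-V_K)
         - g_{Na} m_\infty(V)^3 (1-n)(V-V_{Na}) - I_{syn},$$

with sodium activation instantaneous and sodium inactivation slaved to the
potassium activation (`h = 1 - n`).  The gates `n`, `a`, `b` follow
first-order kinetics `X' = \phi_X (X_\infty(V) - X)/\tau_X` with logistic
steady states.  Defaults (`neuron_params()`):

| quantity | value | meaning |
|---|---|---|
| `C` | 1 uF/cm^2 | membrane capacitance |
| `g_L, g_K, g_Na` | 1, 45, 37 mS/cm^2 | fixed conductances |
| `g_A` | swept (default 20) | A-current conductance — the switch parameter |
| `V_L, V_K, V_Na` | -70, -80, 55 mV | reversal potentials |
| `theta_n, sigma_n, phi_n` | -32 mV, 8 mV, 0.75 | K activation sigmoid |
| `tau_n(V)` | `1 + 100/(1+e^{(V+80)/26})` ms | slow at rest (~41.5 ms), fast when depolarised |
| `theta_a, sigma_a, tau_a` | -50 mV, 20 mV, 2 ms | A activation (sweepable `tau_a`) |
| `theta_b, sigma_b, tau_b` | -70 mV, 6 mV, 150 ms | A inactivation (slow) |
| `g_SynE, g_SynI` | swept (0.5, 1) | synaptic strengths |
| `V_E, V_I` | 0, -85 mV | synaptic reversals |
| `beta_E, beta_I` | 0.2, 0.18 ms^-1 | synaptic gate decay |

Slopes are stored as magnitudes with the direction fixed by the physiology
of each gate: `n` and `a` are activation gates (increasing in `V`), `b` is
an inactivation gate (decreasing).  Where a printed source of such a model
uses signed slopes with inconsistent bookkeeping, this convention is the
one under which the package's quantitative results (the critical
conductance below) are reproduced; the directions also follow from the
narrative roles of the gates, e.g. hyperpolarisation must *raise* `b` for
inhibition to prime I_A.

The *reduced* variant sets `instantaneous_a = TRUE`, replacing `a` by
`a_inf(V)`.  It needs a much stronger excitatory drive for the same
phenomenology (`g_SynE` around 3 instead of 0.5) because a dynamic `a`
recruits extra A-current only during slowly-developing spikes.

### Soma-dendrite cable

The 10-compartment variant keeps all voltage-gated currents in compartment
1 (soma, leak 1 mS/cm^2) and attaches nine passive compartments (leak
0.1 mS/cm^2, same reversal) coupled by an axial conductance
`g_Ax = 10` mS/cm^2 with a discrete-divergence stencil.  Excitation enters
a dendritic compartment `cpt_in` (1 proximal … 9 distal, i.e. cable
compartment `cpt_in + 1`); inhibition targets the soma by default
(`cpt_inhib = 0`).  Moving excitation distally low-pass filters the somatic
EPSP — smaller, slower-rising, later — which delays spike initiation and
gives the A-current time to activate.

## Synthetic inputs

All inputs are generated internally; there is no external data.
Excitatory event times are a homogeneous Poisson process with rate `r_E`
(events/s); inhibitory event times are periodic with rate `r_I`
(`P_I = 1000/r_I` ms), matching optogenetic-style rhythmic inhibition, with
a Poisson mode available as a control (the classifications do not change).
Each event resets its conductance gate to 1; between events the gate decays
as an exact exponential.  The gate before the first event is 0 — the model
starts from rest with no synaptic history.  The phase of the periodic train
is not constrained by the science; the first event defaults to `t = 0` and
is exposed as a parameter.

What the generator does *not* emulate about real synaptic drive: amplitude
variability, short-term depression/facilitation, conductance rise times,
correlated input, channel noise.  Tests passing under these idealised
conditions show that the mechanism (I_A-dependent switching) is present and
quantitatively self-consistent in the model — not that a biological neuron
with noisy, adapting synapses would show identical boundaries.

## Numerical methods

* **Integration.**  An embedded Dormand-Prince 5(4) pair (compiled, in
  `src/sim.cpp`) with absolute tolerance 1e-8 and relative tolerance 1e-6.
  Integration restarts at every synaptic event so the gate reset
  discontinuity never sits inside a step; within a segment the gates are
  evaluated in closed form, so the ODE state is only `(V, n, a, b)` (or 13
  states for the cable).  Tests verify trajectories against `deSolve::lsoda`
  at tolerance 1e-10 and that halving the tolerance changes no spike count.
* **Spike criterion.**  Upward crossing of -20 mV with a 2 ms lockout,
  crossing times linearly interpolated.  Action potentials overshoot toward
  `V_Na = 55` mV, so any threshold in (-30, 0) gives identical counts;
  -20 mV stays clear of the subthreshold ramps seen with weak inputs.
* **Initial conditions.**  The resting equilibrium, found by root-finding
  on the input-free current balance with gates at steady state (the voltage
  is scanned for a sign change first; the near-cancelling window currents
  make the balance non-monotone).
* **Trace recording** uses cubic Hermite dense output between accepted
  steps, so recorded traces are solver-accurate even where steps are long.

## Rate curves and classification

`compute_rate_curve()` simulates each excitatory rate twice — inhibition
off and on — with matched input seeds.  The default grid is 2.5-20
events/s in steps of 2.5 then 25-100 in steps of 5: the threshold-linear
fit uses only points with inhibited rate below 5 spikes/s, and for divisive
parameter sets that window lives entirely at low rates, so a uniform step-5
grid frequently leaves fewer than three usable points.

Each point simulates 10 s of biological time by default (20 s in the
acceptance script), discarding a 500 ms transient; at the 5 spikes/s
fit-window cap this counts on the order of 50-100 spikes per point, i.e. a
~10-15% relative sampling error, which the classification threshold
tolerates.

`fit_threshold_linear()` minimises the squared error of
`y = [m (x - x0)]+` by Nelder-Mead simplex search (two starting points; the
fit is exact on noiseless data).  `classify_inhibition()` labels a
parameter set *subtractive* when the x-intercept shift strictly exceeds
2 spikes/s.  Right-shifted responses often also show slope reduction
("mixed" responses); both `m` and the shift are reported so this remains
visible — *subtractive* here includes mixed.  A degenerate fit (no firing
anywhere in the window) is labelled subtractive and flagged, with `x0`
reported as a lower bound.  `map_boundary()` scans `g_A` upward at each
`g_SynE` (default step 1 mS/cm^2) and records the first subtractive value.

## Reduction theory

With `a = a_inf(V)` the analysis proceeds by fast-slow dissection: `V` is
fast, `n` and `b` slow.

**Averaging `b`.**  The slow inactivation is replaced by its average.
Because `b` barely feels the spike-generating currents, the average is
computed from a scalar equation driven by the quasi-steady single-input
voltages `V_E(s_E(t))` and `V_I(s_I(t))` (conductance-weighted averages of
the reversal potentials), combined as
`b*_av(r_E) = b*_I + b*_E(r_E) - b*_E(0)`.  The inhibitory component is a
deterministic periodic limit-cycle average (10 `tau_b` transient); the
excitatory component uses a 100 s seeded Poisson drive; `b*_E(0) = 1/2`
exactly because `b_inf(V_L) = 1/2`.  Tests confirm the chain
`b*_av ≈ b̂_av ≈ b_av` (passive simulation, full simulation) to within
0.05 across 0-100 events/s; in practice the agreement is ~0.01-0.03.

**Knees.**  At fixed `b`, `s_E`, `s_I` the condition `V' = 0` is a quartic
in `n` with a unique relevant root, so the V-nullcline is a single-valued
curve `n(V)`.  Its *left knee* — the fold separating the left and middle
branches — is the interior local minimum of `n(V)`; a trajectory whose `n`
lies below the knee level when an excitatory event sets `s_E = 1` escapes
to the right branch and spikes, otherwise it relaxes back.  At large `g_A`
the two largest quartic roots collide and the branch terminates; the
root-collision fold is then the knee.  The knee level may be negative
(analytic continuation below `n = 0`), which is precisely the regime where
no recovery state allows firing.  `find_knee()` brackets the fold on a
0.25 mV grid and refines by golden-section search; a dense-grid oracle
(0.001 mV) confirms agreement to 1e-4 on random parameter draws.

**Critical conductance and `Gamma`.**  Between inhibitory events the gate
obeys `s_I' = -beta_I s_I`, so `s_I >= sigma* = exp(-beta_I P_I)` after the
first event.  `critical_gA()` bisects `g_A` until the left knee at
(`s_E = 1`, `s_I = sigma*`, `r_E = 0`, `b = b*_av(0)`) crosses `n = 0`
(tolerance 1e-3): below this `g_A^0` the neuron answers arbitrarily low
input rates (divisive regime), above it `gamma_curve()` root-finds the
minimum responsive rate `Gamma(g_A)` through the `r_E`-dependence of
`b*_av`.

**Dead-time-modified Poisson rates.**  Without inhibition, strong-drive
output thins the input Poisson stream by an effective refractory dead time:
`r_out = r_E/(1 + r_E R)`.  `fit_refractory_R()` estimates `R ≈ 9-10` ms
from simulated strong-drive curves (`g_SynE = 3`; this is the regime where
single events reliably trigger spikes — under the weak drive
`g_SynE = 0.5` the model is far more refractory, with an effective dead
time of ~40 ms, and the one-parameter law fits poorly).  Inhibition enters
through a firing threshold `theta`: an excitatory event fires only if
`s_I < theta`, so the responsive fraction of each period is
`rho = 1 + ln(theta)/(P_I beta_I)` (natural logarithm, forced by the
exponential gate; clipped to [0, 1]) and
`r_out = rho r_E/(1 + r_E R)`.

**The fixed point.**  `theta` solves `n = N(Theta(n))`, bisected on
[0, 1]: `Theta(n_av)` inverts the knee relation (the `s_I` at which the
knee equals the mean recovery level `n_av`, clamped with a flag when no
`s_I` in (0, 1] attains it), and `N(theta)` propagates the resulting rate
through the silent-phase decay `n_av = N_rk e^{-1000 phi_n/(tau_0 r_out)}`.
Two constants here are modelling choices, recorded in every output:
`tau_0`, the silent-phase time constant of `n`, is taken as
`tau_n(V_L) ≈ 41.5` ms (the gate spends the silent phase near rest), and
`N_rk`, the right-knee level from which `n` decays after a spike, is
evaluated once per `g_A` at the reference conditions `s_E = 1`,
`s_I = sigma*`, `b = b*_av(0)` (its dependence on the slow variables is
weak).

## Problem sizes and seeds

Test-suite simulations use 4-10 s of biological time per rate point and
the acceptance script 20 s, durations at which the classification
threshold exceeds the sampling error several-fold; the dense parameter
sweeps (boundary maps) use 5-6 s with coarser grids.  One top-level seed
drives everything: rate-curve point `i` uses `seed*1000 + i` so that
parameter sets share input realisations, and Poisson-timed inhibition uses
an offset sub-seed.  Seeded draws restore the caller's RNG state.

## Known limitations

* The dead-time law with `R ≈ 10` ms describes the strong-drive
  (reduced-analysis) regime; under weak drive the effective refractoriness
  is several-fold longer and input conversion is not one-to-one even at
  low rates.
* `Gamma(g_A)` is an averaged excitability bound.  Near the bound,
  observed onsets need long observation windows (rare spikes); well above
  `g_A^0` fluctuations of `b` and `V` let occasional spikes through below
  the predicted minimum rate.  The theory-simulation comparison is
  therefore sharpest on the rising branch of `Gamma` (minimum rates up to
  ~20-25 events/s).
* The firing-threshold approximation systematically overestimates
  simulated rates (it ignores within-period correlations between recovery
  and gate phase); it captures the divisive-to-subtractive transition and
  the shape of `theta(r_E)`.
* The divisive/subtractive dichotomy is a summary of a continuum; mixed
  responses are folded into "subtractive" by convention, and the reported
  slope keeps them identifiable.
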