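---
title: "Membrane biophysics in clampsim: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane biophysics in clampsim: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clampsim)
```

## The model

`clampsim` simulates one isopotential patch of excitable membrane — a
point neuron. The state is the membrane voltage $V$ (mV), a set of
dimensionless gating variables $x \in [0,1]$, and the free intracellular
calcium concentration (mM). Eleven channel mechanisms carry current
(outward positive, in nA):

| key | mechanism | gates | current law |
|-----|-----------|-------|-------------|
| `na` | voltage-gated sodium | $m^3 h$ | ohmic |
| `k` | delayed-rectifier potassium | $n^4$ | ohmic |
| `cl` | chloride | none (ohmic leak) | ohmic |
| `na_leak`, `k_leak` | background leaks | none | ohmic |
| `a` | A-type potassium | $0.6\,m_1h_1 + 0.4\,m_2h_2$ | ohmic |
| `m` | M-type potassium | $m$ (slow, non-inactivating) | ohmic |
| `ahp` | after-hyperpolarisation K | $q^2$, purely calcium-gated | ohmic |
| `kca` | calcium-activated K | $m \cdot \mathrm{ca}/(\mathrm{ca}+K_d)$ | ohmic |
| `ca_t` | T-type calcium | $m^2 h$ | GHK constant-field |
| `ca_l` | L-type calcium | $m^2$, non-inactivating | GHK constant-field |

Ohmic channels follow $I = g_{max} \prod_i x_i^{p_i}(V - E)$ with $E$
from the Nernst equation at the configured concentrations and
temperature. The calcium channels use the Goldman–Hodgkin–Katz
constant-field relation, which captures the strong rectification of
calcium currents at physiological concentration ratios; the permeability
scale `p_max` lumps membrane area and unit conversions so its units are
nA/mM. Under current clamp

$$\frac{dV}{dt} = \frac{1}{C}\Bigl(I_{applied} - \sum_n I_n\Bigr),$$

and under voltage clamp the voltage is pinned (ideal clamp — no series
resistance or settling dynamics) while the net current required to hold
it is recorded. The recorded clamp current defaults to the amplifier
convention $I_{net} = -\sum_n I_n$; `sim_config(clamp_sign = +1)`
switches to the summed membrane current, since both conventions appear
in practice.

## Gating kinetics

Every gate is a (steady state, time constant) pair in a canonical
parametric form:

$$x_\infty(V) = \frac{1}{1 + e^{-(V - V_h)/k}}, \qquad
  \tau(V) = \tau_{min} + \frac{\tau_{amp}}{\cosh((V - V_\tau)/k_\tau)},$$

a Boltzmann curve (negative $k$ for inactivation) and a bell-shaped,
strictly positive time constant. Calcium sensitivity enters in one of
two ways: the KCa activation multiplies its voltage-dependent steady
state by the Michaelis factor $\mathrm{ca}/(\mathrm{ca}+K_d)$ (the
minimal Yamada-style coupling), and the AHP gate is purely
calcium-gated — its steady state is the Michaelis factor alone with a
fixed slow time constant (80 ms), squared in the conductance so its
resting activation is negligible.

The concrete constants are this package's own: the channel families
(fast transient Na, generic delayed rectifier, two-time-constant A
current, slow M current, Yamada-style KCa/AHP, hippocampal-style CaL)
fix the qualitative shapes, and the constants were chosen once so that
the default cell is a plausible mammalian neuron at room temperature
(295 K): a stable resting potential near −71 mV inside the conventional
[−90, −40] mV search window, a firing threshold near −50 mV, and
repetitive spiking with spike-frequency adaptation under sustained
suprathreshold current. Every constant is exposed in the configuration
schema (`channels.<key>.gates.<gate>.<param>`), so any published
kinetics can be substituted without touching code. Because no two
implementations of these channel families share identical rate
equations, trace-level agreement with any particular published simulator
is not claimed; the test suite instead verifies structural and analytic
properties (bounds, closed forms, convergence) that any correct
implementation must satisfy.

The chloride channel is a plain ohmic conductance with $E_{Cl}$ from the
Nernst equation — the minimal model when no gating data are assumed; an
activation gate can be added through the roster API if desired.

## The calcium pool

A single well-mixed pool couples the calcium channels to KCa/AHP:

$$\frac{d[\mathrm{Ca}]}{dt} = -s\,I_{Ca} - \frac{[\mathrm{Ca}] -
[\mathrm{Ca}]_{rest}}{\tau_{Ca}},$$

with $[\mathrm{Ca}]_{rest} = 5\times10^{-5}$ mM, $\tau_{Ca} = 20$ ms and
influx scale $s = 5\times10^{-4}$ mM·nA⁻¹·ms⁻¹. These are invented,
config-overridable defaults (`calcium.*`), set so that a burst of spikes
raises the pool into the $K_d$ range of the KCa/AHP gates. Inward
(negative) calcium current raises the pool; the concentration is floored
at zero. Deliberately, the pool does not feed back on the GHK
concentration terms — the driving-force concentrations stay at their
configured values, a standard simplification in minimal models.

## Protocols

A protocol is three segments — pre-clamp, clamp, post-clamp, defaults
10/50/10 ms (70 ms total) — with the stimulus at `amplitude` inside the
clamp segment and `baseline` outside it. Total duration is capped at
1000 ms, which also bounds memory at the default step (≈ 100k samples;
recording is never decimated). Segment boundaries are half-open and
left-inclusive, so a step count of `duration/dt` is exact when `dt`
divides the durations. In voltage mode an unset baseline means "hold the
pre/post segments at the numerically located resting potential"
(`vc_baseline = "hold"`); the documented alternative `"free"` lets the
membrane run free (current clamp at 0 nA) outside the clamp segment,
since both behaviours are defensible for the unclamped epochs.

The resting potential itself is found by scanning [−90, −40] mV on a
1 mV grid for a *rising* zero of the net steady-state current — the
stable equilibrium — and refining it by bisection. An excitable membrane
has additional zeros (the firing threshold); scanning for the rising
crossing skips them.

## Numerics

Integration is forward Euler with every right-hand side evaluated at the
start of the step: the voltage update uses start-of-step gates, gates
and the calcium pool advance at the start-of-step voltage and currents.
The default step is `dt = 0.01` ms; fast Na activation (τ down to
0.04 ms) makes explicit steps above ~0.1 ms unreliable, so
`sim_config()` rejects `dt > 0.1` ms unless explicitly overridden. A
gate pushed outside $[0,1]$ by an overshooting step is clamped back; the
calcium pool is floored at zero. If the voltage becomes non-finite the
run aborts with an error naming the step and advising a smaller `dt`.

The GHK relation is evaluated as
$u\,(c_{in} - c_{out}e^{-u})/(1 - e^{-u})$ with $u = zFV/RT$ via
`expm1`, with a fourth-order series expansion for $|u| < 10^{-4}$ (the
direct form is 0/0 at $V = 0$) and the asymptote $u\,c_{out}$ for
$u < -700$ where $e^{-u}$ would overflow. The two branches agree to well
below 1e−9 nA at the switch, and the current is exactly zero at the
ion's Nernst potential.

`reference_run()` integrates the identical trajectory with the classical
4th-order Runge–Kutta scheme at a refined step (`dt/refine`, default
refine = 10), recording on the same sample grid. It exists for
verification only: the test suite checks that the Euler error against it
shrinks linearly in `dt` (ratio ≈ 2 when `dt` halves) and that spike
counts agree at the default step.

## What the tests do and do not show

The suite pins analytic oracles (the RC closed form for a leak-only
membrane, the geometric recursion for a gate at constant voltage, the
analytic steady state of the calcium pool, the GHK root at the Nernst
potential), conservation (the voltage-clamp Kirchhoff identity to
1e−12 nA), bounds (gates in $[0,1]$ over 200 randomized short protocols
at `dt = 0.02` ms), solver order, and behavioural properties (a
suprathreshold step on the Na+K+leak subset fires; spike count is
non-decreasing in clamp duration). Test problem sizes are kept small —
convergence studies use a 15 ms Na+K+leak protocol and the property
tests use protocols of a few ms — which is ample for first-order
asymptotics but means the tests exercise idealized, noise-free dynamics:
they say nothing about channel noise, space clamp artifacts, electrode
access resistance or temperature dependence, none of which the model
includes.

## Known limitations

* Deterministic Hodgkin–Huxley gating only — no Markov schemes or
  stochastic channel openings.
* Single compartment: no axial current, no cable effects.
* Ideal voltage clamp; no electrode or series-resistance model.
* Kinetics have no temperature dependence (no Q10 scaling); temperature
  enters only through the Nernst and GHK relations.
* The calcium pool is a one-time-constant shell; it does not alter the
  GHK concentration terms.
* Forward Euler is first order; halve `dt` (or compare against
  `reference_run()`) when in doubt about accuracy near spikes.
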