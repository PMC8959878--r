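# clampsim

Conductance-based simulation of a single-compartment excitable membrane,
built for exploring ion-channel biophysics: how individual channel types
shape the resting potential, the action potential and the currents an
amplifier records under clamp. It is aimed at students and instructors in
neurophysiology and pharmacology, and at anyone who wants a small,
scriptable Hodgkin–Huxley laboratory with CSV output they can open in a
spreadsheet.

## The model

One isopotential compartment with capacitance *C* (default 0.01 nF)
carries eleven Hodgkin–Huxley style channel mechanisms: voltage-gated Na,
delayed-rectifier K, Cl, Na and K leaks, a two-component A-type K
current, the slow M current, calcium-activated KCa and AHP currents, and
T-type and L-type calcium channels. Under current clamp the membrane
voltage obeys Kirchhoff's current law,

    dV/dt = (1/C) (I_applied − Σₙ Iₙ),

and under voltage clamp the voltage is pinned while the net current
needed to hold it, `I_net = −Σₙ Iₙ`, is recorded. Most channels are
ohmic, `Iₙ = gₙ · ∏ xᵢ^pᵢ · (V − Eₙ)` with reversal potentials from the
Nernst equation; the two calcium channels use the Goldman–Hodgkin–Katz
constant-field relation (CaL does not inactivate). Each gating variable
relaxes as `dx/dt = (x∞(V) − x)/τ(V)`. The A current inactivates with two
time constants: its first (m1, h1) component contributes 60% of the
gating value and the second (m2, h2) 40%. CaT/CaL influx feeds a
first-order intracellular calcium pool that activates the KCa and AHP
currents. Everything is integrated with forward Euler (default dt =
0.01 ms); a classical 4th-order reference integrator is included for
verification. Units throughout: mV, nA, ms, µS, nF, mM, K.

## Worked example

```r
library(clampsim)
mod <- membrane_model()                 # full 11-channel cell, C = 0.01 nF
find_rest(mod)                          # -71.17 mV
res <- run_simulation(mod, clamp_protocol("current", amplitude = 0.2),
                      sim_config())
summary(res)
```

```
current clamp, 7001 samples over 70 ms (dt = 0.01 ms)
voltage: [-81.45, 60.32] mV; spikes (0 mV threshold): 3
peak channel currents (nA):
        na          k         cl    na_leak     k_leak          a          m
-10.557672   5.800781   0.121278  -0.115839   0.602807   1.124012   0.279532
       ahp        kca       ca_t       ca_l
  0.026757   0.260263  -0.049233  -0.133166
```

A 0.2 nA depolarising step (10 ms pre-clamp, 50 ms clamp, 10 ms
post-clamp) drives three action potentials. The peak currents show the
classic division of labour: a large inward Na current (−10.6 nA) fires
the spike, the delayed-rectifier K current (+5.8 nA) repolarises it, the
A and M currents damp excitability, and calcium entry through CaT/CaL
(inward, negative) recruits the KCa and AHP currents that slow the
firing. `write_trace_csv(res, "trace.csv")` exports 25 columns — time,
voltage, net current, then per-channel current and conductance — and
`plot(res)` draws the three stacked panels.

The same pipeline is available from a shell:

```sh
Rscript exec/clampsim run --mode current --amplitude 0.2 --out trace.csv --plot trace.png
Rscript exec/clampsim rest
Rscript exec/clampsim channels
Rscript exec/clampsim validate-config my.yaml
```

Every default — conductances, permeabilities, concentrations, gating
constants, the calcium pool — can be overridden by a YAML config file
(`clampsim run --config my.yaml`) or flags such as `--g na=1.5`; flags
take precedence over the file.

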