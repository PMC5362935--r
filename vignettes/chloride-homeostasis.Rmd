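---
title: "Quantifying neuronal chloride homeostasis from voltage-clamp ramps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal chloride homeostasis from voltage-clamp ramps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clhomeo)
```

## The problem

Fast inhibitory transmission through GABA~A~ and glycine receptors is
carried largely by chloride, so its strength and even its sign depend on
the intracellular chloride concentration [Cl^-^]~i~. After a period of
intense inhibitory activity at depolarized potentials a neuron can
accumulate tens of millimolar chloride; how fast it returns to rest, and
where it settles, is set by two pathways: electroneutral K^+^-Cl^-^
cotransport (KCC2), driven by the summed K^+^ and Cl^-^ chemical
potentials, and passive conductive flux through whatever chloride
channels are open at rest. This package implements the measurement chain
and the model needed to separate and quantify these pathways from
voltage-clamp ramp recordings, together with a synthetic-data generator
so every stage can be validated against known ground truth.

## Measuring E~Cl~ and [Cl^-^]~i~ from ramps

In bicarbonate-free solutions the reversal potential of GABA~A~/glycine
currents equals the chloride Nernst potential,

$$E_\mathrm{Cl} = \frac{RT}{F}\,
  \ln\!\frac{[\mathrm{Cl}^-]_i}{[\mathrm{Cl}^-]_o},$$

so [Cl^-^]~i~ can be read from the reversal of an agonist-evoked current
(`nernst()`, `cl_from_potential()`). The reversal is extracted from I-V
relations built from fast zigzag voltage ramps (±1.6 V/s at a 20 Hz cycle
rate, i.e. 40 mV per half-cycle): samples are corrected for series
resistance offline (`correct_series_resistance()`, V~m~ = V~cmd~ − I·R~s~),
re-gridded onto 1 mV voltage bins, and the leak is removed with a fitted
model rather than by trace subtraction (`fit_leak_model()`,
`subtract_leak()`). The leak model I = A + B·e^{V/C} (or a line) is
evaluated at the agonist curve's *own* corrected voltages; this matters
because the series-resistance voltage error differs between ramps with and
without agonist current, so naive pointwise subtraction is biased.

## The relative resting chloride conductance

The package's central estimator uses the conductance form of the
Goldman-Hodgkin-Katz relation: the zero-current potential is the
conductance-weighted mean of the ionic equilibrium potentials. If the cell
is loaded with chloride so that only E~Cl~ changes while the total
conductance g~T~ and the Na^+^/K^+^ terms stay fixed, everything except
the chloride term cancels between the two conditions and

$$\frac{g_\mathrm{Cl}}{g_T} \;=\;
  \frac{E_\mathrm{rev,2}-E_\mathrm{rev,1}}{E_\mathrm{Cl,2}-E_\mathrm{Cl,1}}
  \;=\; \frac{\Delta E_\mathrm{rev}}{\Delta E_\mathrm{Cl}}.$$

`relative_gcl()` implements the ratio; `run_gcl_protocol()` orchestrates
the full measurement on a sweep recorded with the
`make_protocol("gcl_estimation")` sequence: baseline ramps around −74 mV
(g~T1~, E~rev1~, and a brief agonist probe for E~Cl,1~), a 20 s agonist
application at −14 mV that loads the cell to about 60 mM, a second −74 mV
train (g~T2~, E~rev2~), and a final probe around −34 mV. Because
[Cl^-^]~i~ keeps drifting after the load, E~Cl~ at the time of the second
reversal measurement is linearly interpolated between the two post-load
probes (`interpolate_ecl()`). The estimator's precondition is checked: a
cell whose paired total conductances differ by ≥ 30% is flagged and
excluded (`qc_total_conductance()`).

Two bases are always reported. The recording cocktail that isolates the
resting membrane (TEA, Cd^2+^, TTX and a KCC2 blocker) roughly halves the
total resting conductance, so the in-blockers ratio is multiplied by the
blocker attenuation factor (default 0.54, configurable) to express g~Cl~
relative to the blocker-free membrane (`blocker_correction()`);
`absolute_gcl()` converts either ratio into picosiemens.

### Numerical choices

* Voltage re-gridding: 1 mV bins; up- and down-limbs are averaged with
  equal weight inside each bin, so capacitive (direction-antisymmetric)
  components cancel even where the limbs contribute unequal counts.
* 2 ms blanking around ramp turning points drops capacitive transients.
* Zero crossings: linear interpolation between the bracketing grid
  points; with multiple crossings a ±5 mV local regression around the
  crossing nearest the median is used and a warning emitted.
* Exponential leak fits are initialized from a linear pre-fit and run
  from starts with C of both signs, with |C| constrained to 2-200 mV for
  stability; failures fall back to the linear form, flagged.
* Leak models are fitted separately for the pre-load and post-load
  epochs. The chloride component of the leak reverses at E~Cl~, so the
  leak curve itself shifts with the load; a single pooled fit would leak
  part of the signal into the baseline and bias E~Cl,1~ by more than a
  millivolt at large g~Cl~/g~T~.
* Conductance windows: ordinary least-squares slope over ±10 mV about the
  holding potential (configurable; the window is reported).
* Measurement times: midpoints of the evaluation windows; the second
  conductance time is the midpoint of its ramp train.
* Out-of-range estimates (possible under noise) are reported as-is with a
  flag, never truncated, so group means stay unbiased.

## The single-compartment chloride model

`simulate_cl()` integrates, with a fixed 50 ms forward-Euler step,

$$[\mathrm{Cl}^-]_i(t+\Delta t) = [\mathrm{Cl}^-]_i(t)
  + \Delta[\mathrm{Cl}^-]_{i,\mathrm{KCC2}}
  + \Delta[\mathrm{Cl}^-]_{i,\mathrm{cond}},$$

with the KCC2 term −Δt·Δµ~K,Cl~·g~KCC2~/v~equ~ driven by
Δµ~K,Cl~ = RT(ln([Cl]~i~/[Cl]~o~) + ln([K]~i~/[K]~o~)) (voltage
independent), and the conductive term I·Δt/(F·v~equ~) with
I = g~Cl~(V~m~ − E~Cl~). The fixed step mirrors the original formulation
of the model; tests verify the 50 ms trajectory against a 1 ms reference
and against an independent adaptive ODE solution (both within 1% of the
dynamic range), and per-step component bookkeeping is exact by
construction. Positivity of [Cl^-^]~i~ is guarded; a violation aborts
with a suggestion to reduce the step.

Closed-form fixed points anchor the simulations (`steady_state_cl()`):
KCC2 alone drives [Cl^-^]~i~ to [Cl]~o~[K]~o~/[K]~i~ (≈ 5.05 mM at the
default solutions) regardless of voltage; the leak alone drives E~Cl~ to
V~m~ ([Cl]~o~·e^{V_mF/RT}); with both, the steady state is the root of
the summed fluxes, bracketed by the two closed forms - E~Cl~ settles
between V~m~ and the potassium equilibrium potential according to the
relative strengths of g~Cl~ and g~KCC2~. This yields the model's central
trade-off, reproduced in `analysis/03_model_recovery.R`: raising g~Cl~
accelerates recovery but raises the final [Cl^-^]~i~, weakly at −74 mV
and prominently at depolarized potentials.

Default parameters, all configurable through `cell_state()`:
[Cl^-^]~o~ = 146.4 mM (the stoichiometric chloride of the standard
recording solution, via `solution_chloride()`), [K^+^]~i~ = 145 mM,
[K^+^]~o~ = 5 mM, T = 295 K (room temperature), v~equ~ = 5.0·10^−13^ L
(half the volume of a 6.2 µm-radius sphere, `cytosol_volume_L()`; the
"equivalent volume" in which measured charge transfer accounts for
observed concentration changes, `equivalent_volume()`),
g~KCC2~ = 6.7·10^−21^ mol^2^V^−1^C^−1^s^−1^ (the transporter
proportionality factor that matches KCC2-only recovery to experimental
control recoveries), g~Cl~ = 54 pS (the measured-scale resting value),
baseline [Cl^-^]~i~ = 9 mM.

## Recovery kinetics

Experimental recoveries are summarized by single-exponential fits
(`fit_single_exponential()`), initialized from a log-linear pre-fit, with
free asymptote and unweighted least squares (the underlying trajectories
are not exactly exponential - the KCC2 flux is logarithmic in
concentration - so the fitted asymptote converges to the analytic steady
state only as the fitted span grows; tests verify 5% agreement at spans
several times the fitted time constant). `recovery_fraction()` exposes
both normalization conventions in use: the level relative to the loading
peak, and the fraction of the load eliminated; `interpolate_at()`
supports comparisons at common times across cells whose probes fall at
slightly different times, and `probe_perturbation_bound()` checks that a
probe's integrated charge would move [Cl^-^]~i~ by less than 1 mM. A
double-exponential is deliberately not fitted by default: recoveries are
sometimes bi-exponential or near-linear, and the single exponential is
retained as the common cross-condition summary.

## What the generator emulates - and what it does not

`simulate_sweep()` produces ground-truth-labelled sweeps with: the zigzag
command waveform; a membrane solved self-consistently against series
resistance at every sample (direct solve for linear membranes, damped
fixed point otherwise, verified to 10^−9^ mV); agonist conductances
filtered by first-order solution exchange (τ = 50 ms by default);
additive i.i.d. Gaussian current noise (5 pA SD by default, on the
measurement only - recording noise neither flows through R~s~ nor loads
the cell); and, when coupled, per-sample advancement of [Cl^-^]~i~ by the
chloride channel flux (plus KCC2 if enabled). The default loading
conductance (8 nS) was chosen so the 20 s application at −14 mV loads a
default cell to ≈ 60 mM, the condition under which the estimator is
meant to operate; a prescribed [Cl^-^]~i~ schedule can replace the
coupled dynamics when an exactly known E~Cl~ history is needed.
`simulate_mini_train()` adds Poisson trains of difference-of-exponentials
conductance events (defaults 1 ms rise, 20 ms decay - exploratory
placeholders, as no reference values are asserted for this preparation).

The generator is deliberately idealized: no stochastic channel gating, no
desensitization, no capacitive transients (the analysis still blanks
turning points), no membrane-potential dynamics (voltage clamp is
imposed), no HCO~3~^−^ permeability or NKCC1 term, and no multicompartment
geometry. Passing tests therefore demonstrate correctness of the analysis
chain under these assumptions, not robustness to every artefact of real
recordings; in particular the estimator's accuracy against real capacitive
and access-resistance drift is untested by construction.

## Design choices where the procedure was open

* Up/down ramp limbs are averaged by default (configurable to one
  direction); which the original procedure used is not stated.
* E~rev~ at rest is read from the agonist-free I-V of the corresponding
  ramp train; the exact instants for g~T~/E~rev~ within each train are
  taken as window midpoints.
* The liquid-junction potential is applied only as a fixed configurable
  offset in `nernst_context()`; the generator applies none.
* Probe holdings in recovery experiments track a preliminary model run of
  the expected E~Cl~ (`analysis/04_recovery_probes.R`), mirroring the
  experimental use of test runs to keep probes near E~Cl~.
* [K^+^]~i~ = 145 mM and baseline [Cl^-^]~i~ = 9 mM are declared
  defaults, not asserted measurements.

## Problem sizes

The bundled analyses and tests use: 60 s estimation sweeps sampled at
10 kHz (600k samples); a 12-cell cohort for the estimator summary; a
5×3 noiseless parameter grid (g~Cl~/g~T~ ∈ {0, 0.02, 0.06, 0.1, 0.2},
ΔE~Cl~ ∈ {10, 30, 50} mV) and 50 noisy seeds for calibration; model runs
of 1500 s at 50 ms (30k steps) with 600-6000 s runs for steady-state and
step-size checks; and a ~21 min probe recording sampled at 2 kHz. These
sizes keep every stage's sampling error well below the tolerances being
tested.

## Known limitations

* The estimator assumes an ohmic membrane over the ramp span between the
  two measurement conditions; strongly rectifying non-chloride
  conductances violate the cancellation and are only partially captured
  by the exponential leak form.
* Single-exponential summaries under-determine the asymptote on short
  recovery windows (see above); reported asymptotes from sparse probe
  series should be read with that in mind.
* Group statistics are thin plumbing (means ± SEM, rank-based tests
  through base R); the package makes no claims about reproducing any
  specific experimental group comparison, which would require the raw
  recordings.
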