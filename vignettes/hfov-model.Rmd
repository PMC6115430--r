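---
title: "A reduced-order model of high-frequency oscillatory ventilation in the preterm lung"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of high-frequency oscillatory ventilation in the preterm lung}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

High-frequency oscillatory ventilation (HFOV) ventilates preterm infants at
around 10 Hz with tidal volumes at or below the anatomical dead space,
superimposed on a constant distending pressure (PEEP). That it oxygenates at
all is non-obvious — bulk convection alone cannot carry fresh gas past the
dead space in a single breath — and the mechanisms behind it (turbulent and
asymmetric transport in large airways, laminar convection in small ones,
pendelluft between regions of unequal mechanics, direct ventilation of
proximal acini) are hard to measure in vulnerable patients. `neovent`
implements a desk-scale, fully reproducible surrogate of this setting: a
morphometric conducting-airway tree closed by lumped tissue units, driven by
an HFOV ventilator model with an endotracheal-tube leak, coupled one-way to
a one-dimensional oxygen transport solve, with diagnostics for the
observable signatures of the mechanisms above.

All internal units are kPa, ml, s, mm and kg; clinical units (cmH2O) are
converted once at the configuration boundary (1 cmH2O = 0.0980665 kPa).

## The airway tree

The resolved conducting tree spans generations 0 (trachea) to 7 and is a
regular dichotomous branching structure: child lengths and diameters shrink
by fixed per-generation homothety ratios (default 0.79 for both, the
classic value close to $2^{-1/3}$). An asymmetry factor $a$ splits the two
children unevenly (ratios scaled by $1 \pm a$) and a seeded log-normal
jitter adds per-segment variability; both default to zero, giving a
symmetric tree of $2^8 - 1 = 255$ segments with 128 terminals.

Absolute scale is set by a single calibration: all linear dimensions are
multiplied by the unique global factor that makes the anatomical dead space
(the sum of cylindrical segment volumes $\pi (d/2)^2 L$, per kilogram)
equal the target, 2.2 ml/kg for the 0.76 kg reference patient. Because
volume scales with the cube of a uniform linear factor, that factor is the
cube root of the volume ratio. The default trachea (30 mm × 4 mm before
calibration, 25.0 mm × 3.34 mm after) has the aspect ratio of reported
neonatal morphometry; the dead-space target, not the trachea, is the
binding constraint.

```{r}
library(neovent)
tree <- generate_tree(body_mass = 0.76, target_deadspace_per_kg = 2.2)
dead_space(tree, 0.76)   # 2.2
```

Lobe labels (RUL, RML, RLL, LUL, LLL) are assigned by subtree at
generation 2, with the right-lower subtree split at generation 3; they are
reporting metadata only.

## Terminal mechanics

Each generation-7 outlet $i$ is closed by a lumped unit obeying

$$P^i = R_\mathrm{eq}^i\, Q^i + \Delta V^i / C_\mathrm{eq}^i,$$

where $\Delta V^i$ is the time integral of the inflow $Q^i$: the airways
beyond the resolved tree act as an equivalent resistance, the subtended
tissue as a regional compliance. Pressures are stored relative to the PEEP
baseline, so $\Delta V^i$ is volume above the PEEP-equilibrated FRC and a
unit at rest reads zero.

* $R_\mathrm{eq}^i$ continues the homothety for nine further generations
  (8–16) as a virtual symmetric subtree of Poiseuille resistances, reduced
  by series/parallel composition — for the symmetric case
  $\sum_{k=1}^{9} R_\mathrm{seg}(k)/2^k$. Per-segment resistance is
  laminar, $R = 128 \mu L / (\pi d^4)$ with $\mu = \rho \nu$
  ($\nu = 17$ mm²/s, $\rho = 1.27$ kg/m³); an optional nonlinearity factor
  (default 1) scales generations 0–1 for sensitivity studies, since the
  reduced model cannot represent turbulent losses mechanistically.
* $C_\mathrm{eq}^i = w_i\, C_\mathrm{rs}$ partitions the measured total
  compliance by positive weights summing to one, so the parallel sum is
  conserved exactly. Weights default to uniform; the `bpd_patchy` profile
  emulates bronchopulmonary dysplasia by down-weighting a seeded contiguous
  block of terminals (25% of them by default) by $1 - \mathrm{severity}$
  (severity default 0.5) and renormalising. The patch size is a package
  choice: the source data establish that regional compliance differs
  between healthy and BPD-affected regions but publish no map.

$C_\mathrm{rs}$ itself comes from the single-occlusion technique (SOT) of
infant lung function testing: after a brief end-inspiratory occlusion, the
respiratory system empties passively, so flow decays exponentially with
$\tau = R_\mathrm{rs} C_\mathrm{rs}$ and the flow–volume plot is a line of
slope $-1/\tau$. The estimator takes compliance as exhaled volume over
plateau pressure, $\tau$ from the least-squares flow–volume slope, and
$R_\mathrm{rs} = \tau / C_\mathrm{rs}$. The synthetic SOT generator is the
exact single-compartment inverse of this estimator plus optional Gaussian
flow noise, so estimator recovery is testable to arbitrary precision; it
does not emulate glottic braking, muscle activity or multi-compartment
emptying, so passing recovery tests says nothing about those confounders in
real traces. The reference value is 20.93 ml/kPa; the representative
resistance used when generating maneuvers is 0.006 kPa s/ml
(≈ 60 cmH2O/L/s, a typical intubated-preterm value; no measured resistance
is available for the reference patient).

## Ventilator, tube and leak

One cycle at frequency $f$ splits into inspiration and expiration by the
I:E ratio: at 10 Hz and 1:2, $t_\mathrm{insp} = 33.3$ ms. During
inspiration the ventilator prescribes a half-sine source flow
$Q(t) = Q_\mathrm{peak} \sin(\pi t / t_\mathrm{insp})$ with
$Q_\mathrm{peak} = \pi V_T / (2 t_\mathrm{insp})$, so the inspiratory
integral is exactly $V_T$ (2.0 ml/kg × body mass). During expiration the
prescribed source is zero: the opening node is clamped at PEEP
(8 cmH2O = 0.7845 kPa) and flow develops freely from regional mechanics.
The switch is instantaneous at $t_\mathrm{insp}$, with no blending.

The uncuffed 3.0 mm endotracheal tube (default length 100 mm — not
specified by the source data; a declared default) is a Poiseuille resistor
between the opening node and the trachea. The leak between pharynx and tube
wall attaches at the opening node and flows whenever the opening pressure
differs from ambient — PEEP keeps it positive in both phases. Two regimes
exist: `linear` ($Q = p/R_\mathrm{leak}$, the default) and `orifice`
($Q = A \sqrt{2p/\rho}$, solved by Picard iteration). Because the
patient-specific leak area is image-derived and unpublished, the linear
resistance is calibrated instead: bisection on $R_\mathrm{leak}$ until the
leaked volume over one steady-state cycle divided by the supplied tidal
volume hits the clinically reported 16% within ±0.5 percentage points. The
packaged default, 0.362 kPa s/ml, achieves 16.0%. Leak fraction is monotone
decreasing in leak resistance, which guarantees the bisection.

## The network flow solver

The tree is an electrical analogue: one pressure node per segment's distal
end plus the opening and tube–trachea nodes, segment resistors between
them, terminal units as conductances to state-dependent source pressures,
and the leak as a conductance to ambient. Each time step solves the full
linear nodal system implicitly. The terminal closure is discretised with
the trapezoidal (Crank–Nicolson) rule, which is A-stable and second-order:
a unit contributes conductance $1/(R_\mathrm{eq} + \Delta t / 2C)$ towards
$\Delta V^n/C + (\Delta t/2C) Q^n$. A pure implicit-Euler closure is
available (`scheme = "implicit_euler"`); it is first-order and, at the
default step, leaves a discretisation error just above the package's own
accuracy bound for the single-compartment oracle, which is why the
trapezoidal rule is the default. Because flows jump at the phase switches,
the first step of every phase uses implicit Euler, so the two-level
trapezoidal memory never straddles a discontinuity.

Numerical choices, all configurable:

* time step $\Delta t = t_\mathrm{insp}/200$ (the expiratory step is
  matched to divide $t_\mathrm{exp}$ evenly); a warning is issued above
  $t_\mathrm{insp}/50$;
* the two phase systems are assembled and factorised once and reused every
  step (the matrices are constant within a phase);
* segment gas inertance $\rho L / A$ is available (backward difference) but
  off by default, matching the terminal closure, which has none;
* all $\Delta V$ start at zero: the lung begins at the PEEP-equilibrated
  FRC;
* sign convention: distal-ward flow positive, leak positive out of the
  circuit;
* cumulative volumes use the same quadrature as the state update, so the
  closure `cum_source − cum_leak − Σ ΔV = 0` holds to machine precision at
  every step (this is an identity of the discretisation, not an accuracy
  statement);
* a non-positive compliance makes the nodal system singular and is rejected
  at assembly with an error naming the terminal closure.

The solver is verified against the closed-form single-compartment response
(known-flow inspiration, exponential expiration): maximum relative error
6 × 10⁻⁵ at the default step, against a bound of 10⁻³.

### Steady-state onset and its sensitivity

`detect_steady_state()` returns the first cycle whose end-expiratory volume
(EEV) differs from the previous cycle's by less than 2% of $V_T$ (the
tolerance is an argument). EEV accumulates towards its asymptote with the
per-cycle contraction factor $\exp(-t_\mathrm{exp}/\tau)$, where
$\tau = R_\mathrm{rs} C_\mathrm{rs}$ is the expiratory time constant. The
default model's laminar resistances give
$R_\mathrm{rs} = 4.5 \times 10^{-3}$ kPa s/ml (≈ 45 cmH2O/L/s) and
$\tau = 0.093$ s, so the 2% criterion first fires at cycle 6, although the
EEV is within 3% of its asymptote — visually stationary — by cycle 4. The
detected cycle is sensitive to $\tau$ (a 2%-of-$V_T$ detection at cycle 4
corresponds to $\tau \approx 0.05$–$0.07$ s): reports of clinical or
simulated onset-by-cycle-$k$ statements should always be read together with
the criterion and the effective time constant. The same EEV sequence is
reproduced to ~1% by an independent lumped two-phase ODE, so the number is
a property of the model's mechanics, not of the network discretisation.

## Oxygen transport

Oxygen volume fraction $\Phi$ obeys the advection–diffusion equation
$\partial\Phi/\partial t + u\,\partial\Phi/\partial x -
\partial_x(D\,\partial_x\Phi) = 0$ on every segment, with $u = Q/A$ the
per-segment mean velocity from the flow solution (one-way coupling) and
$D = 0.219$ cm²/s the molecular diffusivity of oxygen in air. The scheme is
finite-volume: first-order upwind advective fluxes, central diffusive
fluxes, 20 cells per segment by default, explicit stepping sub-cycled
within each flow step to keep the Courant number at 0.9 (a direct call with
an excessive step and sub-cycling disabled errors, naming the limiting
segment). Junctions are zero-volume perfect mixers: the node concentration
is the flow-weighted average of the entering streams and every leaving
stream carries it — a declared 1D surrogate for the radial mixing that is a
genuinely three-dimensional mechanism. The ventilator supplies gas at the
inspired fraction (0.35) whenever its boundary flow is into the circuit;
the leak stream leaves from the opening node at that node's mixed
concentration; generation-7 outlets are zero-gradient, so oxygen crossing
them is taken up by the subtended region, and gas returning on expiration
carries the boundary cell's concentration (the initial field is room air,
0.21; both choices are configurable, as the source setting specifies
neither). Taylor-type augmented dispersion is deliberately off: the printed
equation uses molecular diffusivity, and the 1D reduction stays with it.

The scheme is conservative by construction: the per-cycle budget
(ventilator influx − ventilator return − leak efflux − outlet efflux −
storage change) closes to rounding error, far below the 1% audit bound.
Upwinding under CFL gives a discrete maximum principle, so $\Phi$ stays
within the initial/boundary extremes. First-arrival diagnostics classify
each terminal as `direct` (distal cell exceeds the 0.25 threshold within
the first inflation), `delayed`, or `unreached`. On a perfectly symmetric
tree all 128 terminals are equivalent and arrive together; path-length
heterogeneity (asymmetry or jitter) separates proximal-path terminals
(direct) from distal-path ones (delayed), reproducing the qualitative
pattern of interest. Threshold-crossing times are well-behaved for clean
fronts but can jump by a whole cycle between grids when a terminal's peak
concentration grazes the threshold; the grid-convergence test therefore
asserts sub-cell agreement on a monotone front, and marginal crossings
should be interpreted with that caveat.

## Flow-regime diagnostics

Per-segment peak-cycle Reynolds numbers, $Re = 4|Q|/(\pi d \nu)$, are
classified against declared surrogate thresholds (turbulence-prone ≥ 2000,
transitional 500–2000, laminar < 500 — the classic pipe band; the source
identifies turbulence by a 3D vortex criterion and prints no Reynolds
values, so any threshold here is a surrogate and is echoed in the report).
At the default prescription the trachea reaches $Re \approx 1540$
(transitional) and everything beyond generation 2 is laminar, consistent
with the qualitative localisation of turbulence to large airways and
laminar flow beyond generation 6. The Womersley number
$\alpha = (d/2)\sqrt{2\pi f/\nu}$ (≈ 3.2 in the trachea at 10 Hz) is
reported alongside as the oscillatory-flow regime indicator.

## What the synthetic data do and do not establish

Every input is generated: the patient fixture (a 0.76 kg, 27.3-week infant
with BPD grade 3 and $C_\mathrm{rs}$ = 20.93 ml/kPa), SOT maneuvers,
compliance heterogeneity and the tree itself. The generators reproduce the
statistical structure the pipeline assumes — exponential passive expiration,
parallel-compliance partitioning, self-similar morphometry at a fixed dead
space — so green tests demonstrate internal consistency, estimator
correctness and the qualitative mechanisms (pendelluft requires
heterogeneity; direct ventilation requires path heterogeneity; leak
fraction is monotone in leak conductance). They do not demonstrate fidelity
to any individual anatomy: real airway trees are irregular, real BPD is not
a contiguous block, and real SOT traces contain artefacts the generator
omits.

## Problem sizes

The default study runs 6 cycles at 600 steps/cycle on the 255-segment tree
(≈ 2 s), oxygen transport over the same history (≈ 7 s), and leak
calibration about six simulations. The test suite uses 15-segment trees
and 2–4 cycles for solver and transport properties, and the full default
configuration for the headline end-to-end checks.

## Known limitations

* No 3D flow features: vortices, asymmetric velocity profiles and radial
  mixing are represented only by their 1D surrogates (regime labels,
  junction mixing), and event times tied to a specific imaged anatomy are
  reproduced qualitatively, not numerically.
* Rigid resolved airways; no tissue viscoelasticity; no inertance in the
  terminal closure.
* No CO₂ transport or blood-side gas exchange; oxygen leaving a terminal is
  simply consumed.
* The leak model is a calibrated lumped element, not an image-derived
  geometry; the 16% fraction is an anchor, not a prediction.
* Steady-state onset in cycles depends on the effective time constant (see
  above) and on the detection tolerance.
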