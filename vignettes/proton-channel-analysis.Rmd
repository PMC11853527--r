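---
title: "Methods: proton-channel gating analysis with hv1kit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proton-channel gating analysis with hv1kit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hv1kit)
```

## The gating model

hv1kit treats the voltage-gated proton channel as a two-state (closed/open)
system. The steady-state open probability is a single Boltzmann of the total
gating charge $q$,

$$P_{o,\infty}(V) = \frac{1}{1 + e^{(V_{1/2} - V)/k}}, \qquad
  k = \frac{RT}{qF},$$

and relaxation toward it is exponential with voltage-dependent time
constants $\tau_{act}(V) = \tau_{act,0}\,e^{-V/U_{act}}$ and
$\tau_{deact}(V) = \tau_{deact,0}\,e^{+V/U_{deact}}$. The current is ohmic
in the driving force relative to the proton Nernst potential,

$$I(t) = \left[g_{leak} + g_{max} P_o(t)\right](V - E_H), \qquad
  E_H = -\frac{\ln 10\,RT}{F}\,\Delta\mathrm{pH},$$

with $\Delta\mathrm{pH} = \mathrm{pH}_o - \mathrm{pH}_i$. Two deliberate
simplifications depart from the full biology of the dimeric channel:

* **Cooperativity appears only as a delay.** Real proton-channel activation
  is sigmoid because the two protomers gate cooperatively. The generator
  represents this with a single explicit delay parameter before the
  exponential rise, because the fitting convention on the analysis side
  likewise disregards the initial delay and fits the remaining
  single-exponential rise. Round-trip tests are therefore exact by
  construction for the exponential part, and say nothing about how well a
  delayed exponential approximates true sigmoid activation in real cells.
* **Two-component tails are imposed, not emergent.** All variant channels
  of interest deactivate with a fast and a slow tail component; the
  generator splits the tail amplitude by `tail_fast_fraction` with a fast
  time constant `tail_fast_ratio` times the slow one. The analysis reports
  the slow component, which is the component carrying
  $\tau_{deact}(V_{repol})$ in the generator.

### ΔpH-dependent gating

The half-activation voltage shifts along the voltage axis with the pH
gradient: $V_{1/2} = V_{1/2,ref} + s\,\Delta\mathrm{pH}$ with the shift
slope $s = -40$ mV per unit by default. Alkalinizing the bath (raising
$\Delta\mathrm{pH}$) therefore moves gating toward negative potentials, the
canonical behaviour of proton channels. The magnitude 40 mV/unit is the
textbook "rule of forty" scale for this channel family; it is configurable
because individual variants deviate from it.

A practical consequence, reproduced by the simulator: a channel held at
−40 mV under symmetric pH is closed, but after a one-unit bath
alkalinization the foot of the activation curve reaches the holding
potential and a genuine (gate-carried, not leak) holding current appears.
Closed-state leak experiments therefore hold at −80 mV, as is standard
practice when the bath pH will be raised.

## Generator defaults (the simulated "wild-type cell")

| parameter | default | unit | rationale |
|---|---|---|---|
| `g_max` | 32 | nS | 1.6 nS/pF on a 20 pF cell, a typical well-expressing wild-type conductance density |
| `q_total` | 6.2 | e₀ | limiting-slope charge scale of the dimeric channel |
| `V_half_ref` | +21 | mV | wild-type half-activation at symmetric pH |
| `pH_shift_slope` | −40 | mV/ΔpH unit | canonical ΔpH shift |
| `tau_act0`, `U_act_true` | 2 s, 40 mV | | seconds-scale activation at 0 mV, e-fold per 40 mV |
| `tau_deact0`, `U_deact_true` | 0.6·e s, 40 mV | | anchored so τ_deact(−40 mV) = 0.6 s |
| `delay` | 0.05 | s | short activation delay |
| `tail_fast_fraction`, `tail_fast_ratio` | 0.3, 0.1 | | two-component tails, fast component 10× faster |
| `g_leak` | 0 | nS | no closed-state leak unless requested |
| `C_m` | 20 | pF | small HEK-like cell |
| `noise_sd` | 0.5 | pA | RMS current noise of a quiet GΩ-seal whole-cell recording after filtering |
| `T_K` | 294 | K | ≈21 °C, the midpoint of room-temperature recording; RT/F = 25.33 mV, ln10·RT/F = 58.33 mV |

All temperature factors funnel through `thermal_voltage()` and
`nernst_slope()`, so the temperature enters each computation exactly once.

What the generator does **not** emulate: proton depletion/accumulation
during large currents (the reason real protocols shorten pulses at positive
potentials), series-resistance and capacitance-transient artifacts, 1/f and
seal-drift noise, and genuinely sigmoid (multi-state) activation. Passing
round-trip tests demonstrates correctness of the estimators under the
stated model, not robustness to these artifacts.

## Estimators and their numerical choices

**Exponential fits** (`fit_exponential`) are nonlinear least squares
(Levenberg–Marquardt via minpack.lm) on the decaying basis
$I = C + A e^{-(t-t_0)/\tau}$, so rising fits have $A<0$ and $\tau$ stays
positive; for rising fits the extrapolated steady state is $C$. Starting
values come from a log-linear regression of the detrended decay; $\tau$ is
bounded in [2 sample intervals, 10× window length]; a small multi-start
over $\tau$ guards against the near-linear local minimum (τ at its upper
bound) that shallow noisy relaxations can fall into. The activation delay
is disregarded by starting the window where the current first crosses 10%
(configurable) of its final excursion. A two-component fit is demoted to
one component when $\tau_{fast}/\tau_{slow} > 0.8$ or either amplitude is
below twice the residual noise SD — a screening rule chosen here, since no
standard criterion exists. Flat traces (SD below a noise floor) and
windows of fewer than 10 samples are rejected explicitly rather than
returning NaN.

**Conductance** uses the extrapolated steady state and the driving force;
points within 1 mV of the reversal potential are dropped because the
division is unstable there.

**The Boltzmann fit** runs on unnormalized conductances with $g_{max}$
free; normalization is derived, never imposed. Curves sampled on one side
of the inflection are fitted but flagged wide-confidence (shallow variants
genuinely produce such curves).

**Limiting-slope charge** regresses $\ln g$ on $V$ and converts with
RT/F in mV. The default window is the most negative contiguous "decade"
(points within a factor 10 of the smallest positive conductance); an
explicit window supports 2 mV-step protocols near threshold. The window
must sit at low open probability: on a pure Boltzmann the apparent charge
at the midpoint is exactly $q/2$ and converges to $q$ only as
$P_o \to 0$ — the package tests assert this convergence monotonically.
Boltzmann slope factors are never converted to gating charge.

**Voltage dependence of kinetics** is fitted on semilog axes
($\ln\tau$ vs $V$), since the quantity of interest is mV per e-fold; an
iterative r² screen (default threshold 0.98) trims edge points where
linearity is lost, emulating the practice of restricting the fit to the
linear range near the reversal potential. A slope of zero returns an `Inf`
sentinel ("voltage independent") that propagates into θ with a warning
rather than an error.

**Standardized comparisons** interpolate $\tau_{act}$ at each channel's own
$V_{1/2}$ (equal open probability) by log-linear interpolation, and take
$\tau_{deact}$ at −40 mV (equal driving force). Perturbation energies use
$R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹ at 294 K; the ratio convention is
$\Delta\Delta G = -RT\ln(\tau_{ref}/\tau_{mut})$, so negative values mean
the mutant lowered the kinetic barrier. Side-chain-volume corrections for
bulky substitutions are deliberately out of scope.

**Leak detection** compares mean holding current over quiet windows
(default 10 s) before and after each bath exchange, excluding test pulses
with a ±0.5 s guard band (1 s pulses at 30 s intervals leave ample quiet
segments). The predicted shift sign is the sign of the change in driving
force $V_{hold} - E_H$; a leak is declared only when **every** exchange
exceeds $k\,\sigma_{noise}$ (default $k=3$) with the predicted sign. At
least 5 s of clean baseline is required per exchange.

**The GHK permeability bound** treats TMA⁺ as the sole competing cation
(the anion is assumed impermeant, matching methanesulfonate-based
solutions) at equal concentration on both sides. The bound is the smallest
$P_H/P_{TMA}$ whose bi-ionic GHK reversal potential lies within a
user-supplied ε of $E_H$, solved by bisection on $\log_{10}$ ratio; ε is an
argument, not a hard-coded assumption, because the admissible deviation
depends on each experiment's V_rev precision. The bound is flagged
uninformative when it falls below 1.

## Mutation hotspot scan

Records are merged across databases at the protein-change level
(position, reference, alternate): the primary database keeps all records,
including recurrent ones (the same change observed in several patients),
and a secondary record enters only when its change is absent from the
primary — the only reconstructable deduplication rule at protein level.
The window profile sums per-residue counts over a centered 7-residue
window (three residues up- and downstream), clipping at the termini
without renormalizing: the profile reports counts, not densities, and
coordinates are 1-based inclusive throughout. Candidate hotspots are
flagged where the windowed count reaches twice the protein-wide mean — an
adjustable screening default, explicitly not a calibrated significance
rule.

## Structural geometry

Ensembles are multi-model PDB files (read and written via bio3d), with the
membrane normal assumed to be the z axis — standard for membrane-builder
output; no automatic axis inference is attempted. The hydrophobic-gasket
plane (mean Cα of V109, F150, V178, V179) defines $z=0$ and the pore axis
position; all axial geometry is relative to it.

Superposition is the Kabsch algorithm (SVD with the proper-rotation
determinant correction); the test suite cross-checks it against an
independent Horn quaternion implementation to 10⁻⁶ Å. RMSF superposes
frames onto an iteratively refined mean structure and supports a separate
fit selection so a mobile region does not leak into the alignment.

Salt bridges use a 4.0 Å cutoff between basic side-chain nitrogens
(Arg NE/NH1/NH2, Lys NZ, His ND1/NE2 — both ring nitrogens regardless of
protonation) and carboxylate oxygens (Asp OD1/OD2, Glu OE1/OE2), with
occupancy thresholds 0.65 (strong) and 0.25 (weak). All three numbers are
configuration keys: they are conventional screening values, and the
packaged classification table ships as a fixture precisely because the
original contact criteria are not recomputable from public information.

Water profiles count water oxygens inside an 8 Å cylinder about the pore
axis in 1 Å axial bins (0.5 Å in the tests), averaged over frames. The
dewetted width is the contiguous interval around the lowest minimum where
the mean count stays below 1 molecule per bin, endpoints by linear
interpolation. The one-molecule level is only meaningful when bin
occupancy outside the dewetted region is of order a few molecules; the toy
generator places waters at that density for width-recovery tests.

## Problem sizes used by the test suite

Chosen as the package's own balance of resolution against runtime:
noiseless round-trip families use 9–11 voltage steps at 1 kHz with 6–8 s
pulses; limiting-slope work uses 2 mV steps over a 10 mV low-P₀ window
(30 s pulses; 1 kHz when noisy, 200 Hz when noiseless); noisy
charge-recovery uses 20 seeds at 1 pA noise; leak operating
characteristics use 200 seeded 150 s recordings at 100 Hz with two
opposite-sign exchanges; geometry oracles use 100 random atom pairs, 80
frames for hydration profiles, and 500 frames for RMSF closed forms.

## Known limitations

* The two-state model cannot produce Cole–Moore shifts, sigmoid activation
  beyond a fixed delay, or state-dependent selectivity; conclusions about
  those phenomena are outside its reach.
* The limiting-slope estimator is bias-limited by the highest open
  probability in its window (relative bias ≈ −P₀); noisy low-P₀ points
  trade that bias against variance, and the default "decade" heuristic can
  select very noisy points on real data — the explicit window argument is
  preferred when the protocol was designed for it.
* Leak detection assumes an ohmic, proton-selective leak and instantaneous
  bath exchange; slow perfusion will smear the step and lower sensitivity.
* The hotspot threshold is a screening default; region boundaries must be
  supplied by the user, and no multiple-testing control is applied.
* Geometry routines assume identical atom ordering across frames and do
  not repair broken topologies.
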