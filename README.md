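# hv1kit

Biophysical analysis of the human voltage-gated proton channel (hHV1) and
its variants: patch-clamp gating analysis, proton selectivity, closed-state
leak detection, somatic-mutation hotspot scanning, and geometry statistics
on structural ensembles.

## Who this is for

Electrophysiologists characterizing proton-channel variants from whole-cell
voltage-clamp families, and computational biophysicists relating those
measurements to mutation databases and molecular-dynamics ensembles. hHV1 is
a 273-residue, proton-selective channel gated by both voltage and the
transmembrane pH gradient (ΔpH = pH_o − pH_i); its S4 helix carries the
voltage-sensing arginine triad R1 (R205), R2 (R208), R3 (R211).

## The model and statistics at the core

- **Trace kinetics.** Current relaxations are fitted with
  `I(t) = C + A·e^(−(t−t0)/τ)` (one or two components); rising fits carry
  A < 0 and extrapolate the steady state as C, disregarding the initial
  activation delay. Tail (deactivation) fits report the slow component.
- **Conductance and gating.** Chord conductance `g_H = I_ss/(V − V_rev)`,
  conductance density `g_H,max/C_m`, and the Boltzmann relation
  `g_H(V) = g_max·[1 + e^((V½−V)/k)]⁻¹`. The gating charge is estimated by
  the limiting-slope method, `e0 = (RT/F)·d ln g/dV` over a low-open-
  probability window — never from Boltzmann slope factors, which halve the
  apparent charge near the midpoint.
- **Kinetic standardization.** Perturbation energies
  `ΔΔG = −RT·ln(τ_ref/τ_mut)` (kcal/mol) at matched open probability
  (τ_act at each channel's V½) and matched driving force (τ_deact at
  −40 mV); voltage dependence `U_τ` in mV per e-fold from ln τ–V slopes;
  their ratio `θ = U_τ,deact/U_τ,act`.
- **Selectivity and leak.** The proton Nernst potential
  `E_H = −(ln10·RT/F)·ΔpH`, a GHK-based lower bound on P_H/P_TMA from the
  measured V_rev−E_H deviation, and closed-state proton-leak detection from
  driving-force-directed holding-current shifts during bath pH exchanges.
- **Mutations.** Multi-database merging at the protein-change level, a
  7-residue sliding-window missense profile, and per-region affected
  fractions and mutation densities.
- **Structure.** Kabsch superposition (RMSD/RMSF), salt-bridge occupancy
  with strong/weak classification, axial shifts relative to the
  hydrophobic-gasket plane (V109/F150/V178/V179, z = 0), and pore-hydration
  profiles with dewetted-width measurement.

A deterministic two-state gating simulator (Boltzmann steady state,
exponential relaxation, two-component tails, ΔpH-shifted gating, optional
ohmic proton leak) generates synthetic families, mutation tables and toy
structural ensembles, so every stage is testable without raw recordings.

## Worked example

```r
library(hv1kit)

params <- channel_params(noise_sd = 0)          # wild-type-like cell
fam <- simulate_family(params, voltage_protocol(
  steps = data.frame(V = seq(0, 100, 10), dur = 8), tail_duration = 4))
tails <- simulate_family(params, voltage_protocol(
  steps = data.frame(V = 80, dur = 6, V_repol = seq(-100, -20, 20)),
  tail_duration = 8))

fit <- fit_channel(fam, tails = tails)
summary(fit)
#> Proton-channel gating fit
#>   pH 6.5//6.5, V_rev = 0.0 mV, C_m = 20 pF
#>   g_max = 32 nS (1.6 nS/pF), V_half = 21.0 mV, k = 4.09 mV
#>   V_thres = 0 mV
#>   U_act = 40.0 mV/e-fold
#>   U_deact = 40.0 mV/e-fold
#>   theta = 1.00
```

The fit recovers the generating parameters exactly: a 1.6 nS/pF conductance
density, half-activation at +21 mV with slope factor RT/(q·F) = 4.09 mV for
q = 6.2 charges, symmetric 40 mV/e-fold kinetics (θ = 1), and an activation
threshold at 0 mV under symmetric pH.

Comparing kinetics between channels: a variant that activates with
τ = 0.09 s where the reference takes 2.0 s has lowered its activation
barrier by

```r
perturbation_energy(2.0, 0.09)   # kcal/mol at 294 K
#> [1] -1.81
```

The packaged salt-bridge classification table for wild type and five S4
variants in both gating configurations:

```r
tab <- parse_salt_bridge_table(
  system.file("extdata", "salt_bridge_table_hv1.tsv", package = "hv1kit"))
tab
#> Salt-bridge table: 33 pairs x 12 conditions
#>   column n_strong n_weak
#>     WT.d        7      5
#>     WT.a        9      2
#>  R205W.d        4      2
#>  ...
```

Per-column counts of strong (✓) and weak (∨) interactions are always
recomputed from the cells; the activated G215E column, for example, sums to
12 strong and 7 weak interactions.

## Command line

A thin wrapper over the same functions lives in `inst/exec/hv1`:

```sh
Rscript inst/exec/hv1 simulate-family --out out/ --seed 5
Rscript inst/exec/hv1 gating --input out/family.csv --out out/
Rscript inst/exec/hv1 hotspot --input mutations.csv --out out/
```

## Documentation

The methods vignette (`vignettes/proton-channel-analysis.Rmd`) describes
the gating model, the estimators and their assumptions, all tunable
parameters with units and defaults, and known limitations.
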