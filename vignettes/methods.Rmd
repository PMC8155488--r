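---
title: "Models and methods behind afvtrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind afvtrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`afvtrial` is an in-silico screening bench for antiarrhythmic drugs (AADs)
in atrial fibrillation (AF), stratified by genotype. This vignette explains
the models it implements, the parameters that matter, what its synthetic
substrates do and do not emulate, and the design decisions taken where the
published record is silent.

## The cell model and its parameterisation

The myocyte is the Courtemanche–Ramirez–Nattel (CRN) human atrial model: 21
state variables (membrane potential, 15 gates, 5 intracellular
concentrations) with the standard current set (I~Na~, I~K1~, I~to~, I~Kur~,
I~Kr~, I~Ks~, I~CaL~, pumps, exchanger, SR fluxes). The package never alters
the CRN equations; every condition is expressed as a 13-component
multiplier vector over maximal conductances and pump/SR rates
(`scale_channels()`). An acetylcholine-activated K^+^ slot exists in the
vector because condition tables carry an ACh row, but its baseline
conductance is zero, so it contributes no current at the shipped settings.

Conditions compose multiplicatively:

* **Genotype × rhythm state** — four stored columns (wild-type/PITX2^+/−^
  deficient × sinus rhythm/AF-remodeled), in percent of unscaled CRN. The
  columns are registry *data*, not derivations: the published PITX2 AF
  I~K1~ entry (158%) differs by ~1 point from exact application of the
  wild-type SR→AF percent change to the PITX2 SR column (157%), so the rule
  is implemented as a validation (`consistency_report()`) rather than a
  constructor.
* **Drug × dose** — multiplicative block factors on each drug's registered
  channel subset (class IC: flecainide, propafenone; class III: amiodarone,
  sotalol, dronedarone; two dose levels each). The primary sources publish
  the affected-channel lists but not the exact percent blocks, so the
  shipped factors are documented, editable defaults assembled once from the
  cited pharmacology, constrained to be dose-monotone (the high dose blocks
  every listed channel at least as strongly). Every simulated case records
  its fully resolved scale vector. The sotalol dose labels (60 µM, 10 mM)
  are kept exactly as published.

## Single-cell protocols

Integration is forward Euler on voltage and concentrations with Rush–Larsen
exponential updates on gates, `dt = 0.02` ms for cell work. Voltage-dependent
rate quantities are tabulated on a 0.1 mV grid with the Rush–Larsen factors
folded in; halving `dt` moves the paced APD90 by well under 1 ms (asserted
in the tests).

* **Stimulus**: 2 ms rectangular pulse at twice the diastolic threshold,
  the threshold found by bisection per scale vector. Standard practice; the
  source protocols do not state an amplitude.
* **APD90**: per beat, from the activation time (maximal upstroke dV/dt) to
  the downward crossing of `V_rest + 0.1 (V_peak − V_rest)`, with `V_rest`
  the pre-upstroke minimum of that beat and linear interpolation between
  samples. Paced APD90 is reported from the final beat of a 10-beat train
  at cycle length 600 ms.
* **Restitution**: a decremental ramp (600 → 200 ms in 25 ms steps, 8 beats
  per stage) collects one (DI, APD90) pair per stage, `DI = CL − APD90` of
  the preceding beat, capture failures excluded. The ramp schedule is a
  configuration default; the published protocol details are unavailable.
* **Restitution fit**: `APD90(DI) = y0 + A1 (1 − exp(−DI/τ1))`, bounded
  least squares with `A1 ≥ 0`. The published equation omits its exponent
  (an extraction artifact), but a saturating exponential with a free
  constant, a time constant and DI as the regressor is the only reading
  consistent with its stated ingredients. `Smax` is the fitted curve's
  slope at the smallest observed DI, `(A1/τ1) exp(−DI_min/τ1)` — the
  maximal slope over the observed domain for a monotone saturating fit.
  Exactly flat samples return `A1 = 0`, `Smax = 0` directly; a failed fit
  falls back to a flagged finite-difference slope.

## Synthetic substrates

No patient CT or electroanatomical maps are distributed with the package,
so the substrate module generates what the clinical pipeline would supply:

* a regular monolayer lattice (default 50 × 50 mm at 0.25 mm; the trial
  profile uses 40 × 40 mm at 0.4 mm, below);
* a spatially correlated, strictly positive bipolar-voltage field:
  Gaussian-filtered noise rank-mapped onto a lognormal amplitude
  distribution positioned so the fraction of nodes under the low-voltage
  cutoff (default 0.5 mV) equals the requested `low_frac` exactly by
  construction, plus a ≥500-point subsample emulating catheter density;
* inverse-distance-weighted interpolation (`idw_interpolate()`) with
  normalized `d^-a` weights inside a 10 mm radius. The radius is published;
  the exponent is not, and defaults to `a = 2`. Queries with no point in
  radius return a missing-value marker, never zero;
* fibrosis as independent Bernoulli draws from an injectable monotone
  non-increasing probability–voltage curve (default logistic, midpoint at
  the low-voltage cutoff). The published probability curve is cited but
  not printed, hence injectable;
* a fiber-orientation field (uniform, swirl, or seeded smooth-random;
  default smooth-random) feeding an anisotropic diffusion tensor with a
  4:1 longitudinal:transverse ratio;
* diffusion calibration: bisection (in log D) on a plane-wave strand until
  the conduction velocity matches a target.

Everything is a pure function of `(config, seed)`.

What the generator does **not** emulate: real atrial geometry and curvature,
wall thickness and endo/epicardial dissociation, anatomical obstacles
(pulmonary veins, appendage), spatially organised fibrosis architecture
beyond the correlation length, and inter-patient covariance of voltage,
fibrosis and conduction. Ensemble results therefore support *directional*
claims (orderings, signs of drug effects), not the published means from
patient-specific three-dimensional models.

## Tissue model

Monodomain reaction–diffusion on the lattice: operator-split per step —
anisotropic 9-point finite-difference diffusion (face-averaged tensor
components, centered cross terms), then the CRN reaction. Boundaries are
no-flux; a periodic (toroidal) option exists as a stand-in for
closed-chamber topology. Fibrotic nodes are non-conducting by default
(zero-flux holes); an optional reduced-coupling mode keeps them excitable
at a fraction of the bulk diffusivity (diffuse interstitial fibrosis).
Tissue runs use `dt = 0.075` ms in the trial profile (`0.05` ms elsewhere);
a uniform field is exactly invariant under the diffusion step, and refining
the lattice two-fold inside the convergent regime moves plane-wave CV by
under 5%.

## AF induction: what failed and what the package does

Burst pacing (`burst_protocol()`, 20 stimuli, cycle lengths 200 → 120 ms)
and cross-field S1–S2 induction (`cross_field_protocol()`) are implemented
and exercised by the tests. At desk scale, however, they do not yield
sustained fibrillation in this model family: the first post-break rotations
run on *rest-adapted* tissue whose refractory period (~170 ms) times its
conduction velocity exceeds any affordable sheet, and the wavefront
annihilates against its own tail within a few rotations. This was mapped
systematically (burst cycle lengths, S2 timing scans, fibrosis fractions
0.15–0.48, conduction-velocity targets 0.22–0.6 m/s, open and toroidal
sheets) before being designed around.

The trial therefore starts episodes from **phase-distributed spiral initial
conditions** (`spiral_seed_state()`): a single cell is paced down a ramp to
a short cycle length (170 ms), its full state is sampled across one
rate-adapted cycle (`cycle_library()`), and tissue nodes are assigned
cycle phases along an Archimedean spiral. The released rotor runs on cells
that already have fibrillation-rate APDs, which is precisely the regime the
published wave-dynamics measurements describe. Seeding can still fail on
unfavourable substrates; `run_af_induction()` then retries with the
opposite chirality, mirroring repeated clinical induction attempts, and
records the attempt count. Episodes that die early are *terminations* —
they feed the termination tables and are excluded from wave-dynamic
summaries, the same exclusion rule the source analysis applies.

## Wave-dynamics metrics

All metrics are computed on transmembrane voltage (5 ms frame decimation)
and activation events (per-node time of maximal upstroke dV/dt).

* **APD90 / CV** — from the paced sinus-rhythm run: APD90 at the appendage
  landmark, CV as distance over activation-time difference between the
  septal pacing site and the appendage landmark.
* **AFCL** — mean inter-activation interval per node, averaged over nodes
  with at least two activations in the analysis window; computed from
  activation times, independently of the spectral path.
* **Dominant frequency** — per-node periodogram (mean-subtracted, Hann
  taper, zero-padded FFT) peak within 3–15 Hz; peak DF is the maximum over
  nodes, mean DF the mean, flat nodes excluded. Windows are ≥ 2 s for
  ≤ 0.5 Hz resolution.
* **Phase** — analytic signal (FFT Hilbert embedding) of the
  mean-subtracted voltage; non-oscillatory nodes are masked.
* **Phase singularities** — topological charge: the discrete line integral
  of wrapped phase differences around each lattice plaquette is ±2π at a
  singularity. Tracking is charge-respecting nearest-neighbour association.
  **PS number is the cumulative count of per-frame detections** over the
  analysis window; the published counts (10^4^–10^5^ over 32 s) are only
  consistent with a cumulative convention, which is therefore adopted and
  stated prominently. PS lifespan is the mean track duration.
* **Smax at trial scale** — the ensemble uses the single-cell ramp under
  each arm's AF-remodeled currents (deterministic per arm); per-node
  tissue restitution mapping (`smax_map()`) is implemented and tested on
  tissue-shaped samples but costs ~50 s of simulated ramp per case, which
  the ensemble budget does not carry.

## Trial profiles and problem sizes

The `desk` profile — the package default and what the test-suite ensemble
runs — uses: 40 × 40 mm sheets at 0.4 mm spacing (101 × 101 nodes),
`dt = 0.075` ms, diffusion calibrated to 0.45 m/s, fibrosis `low_frac =
0.25` with 4 mm correlation length in reduced-coupling mode (factor 0.3),
spiral seeding at cycle length 170 ms with 40 mm pitch, 2.6 s episodes and
a 2 s analysis window, n = 10 substrate seeds. Results produced under this
profile are flagged `scaled_down`. The `paper` profile (25 seeds, 32 s
windows, larger sheets) is available behind the same interface for long
runs. One master design expands to per-case records with full provenance
(resolved scales, seeds, attempt counts); per-case checkpoint files make
trials resumable, and reports regenerate deterministically from the
archive.

Statistics follow the published analysis: equal-variance Student *t* for
between-group comparisons, paired *t* for before/after drug within a model,
Cohen's *d* with (n−1)-weighted pooled SD, and no multiple-testing
correction (noted in the report). For termination proportions the package's
own comparisons use a two-sided exact test on the 2×2 counts; reproduction
of *published* termination rows uses plain percentage arithmetic per row,
because the published table's drug-dose cells and its overall row are not
mutually consistent and each printed row can only be reproduced from its
own counts.

## Known limitations

* Monolayer sheets only: no wall thickness, no bilayer dissociation, no
  anatomical geometry. Desk-scale conduction velocities are deliberately
  below atrial values to preserve the wavelength-to-domain ratio.
* Drug action is pure conductance block — no state-dependent (use-dependent)
  binding kinetics, no pharmacokinetics; dose enters only as two labeled
  levels.
* The induced-AF surrogate (seeded rotor on a small sheet) supports
  within-model orderings and drug-effect signs; absolute AFCL/DF/PS
  magnitudes are not comparable to patient-specific three-dimensional
  results.
* Single-cell APD90 under the stored genotype columns runs longer than the
  published tissue-ensemble means; the PITX2^+/−^ sinus-rhythm column (only
  I~K1~ and I~Kr~ changed) cannot reproduce the published 184 ms mean in an
  isolated CRN cell at cycle length 600 ms. The package reports what the
  stored parameterisation actually produces.
* No SR calcium-leak or triggered-activity analysis.
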