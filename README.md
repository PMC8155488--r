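# afvtrial

Virtual antiarrhythmic-drug (AAD) trials in genotype-aware atrial
fibrillation (AF) models.

## The problem

Antiarrhythmic drug response in AF varies between patients, and genotype —
in particular heterozygous deficiency at the *PITX2* locus, the strongest
AF-associated GWAS signal — shifts both atrial electrophysiology and drug
efficacy. Testing drugs in silico means: build an atrial substrate, endow
its myocytes with genotype- and drug-specific ion-channel behaviour, induce
fibrillation, and measure how the wave dynamics and termination rates
change with each drug and dose. `afvtrial` implements that pipeline for
researchers in computational cardiac electrophysiology who want a tested,
scriptable desk-scale bench rather than a clinical-scale cluster code.

## What is inside

* **Cell model** — the Courtemanche–Ramirez–Nattel (CRN) human atrial
  myocyte, with every condition expressed as a 13-component multiplier
  vector over maximal conductances and pump/SR rates
  (g_Na, g_K1, g_to, g_Kr, g_CaL, g_Kur, g_Ks, I_NaCa, I_NaK, I_up, k_rel,
  Ca_up,max, ACh). Pacing, APD90 measurement, dynamic restitution and the
  saturating-exponential restitution fit
  APD90(DI) = y0 + A1·(1 − e^(−DI/τ1)), with the maximal slope
  S_max = (A1/τ1)·e^(−DI_min/τ1).
* **Condition registry** — stored genotype × rhythm-state columns
  (wild-type / PITX2-deficient × sinus rhythm / AF-remodeled), validated
  against the same-percent-change construction rule, and per-drug
  dose-monotone block tables for amiodarone, sotalol, dronedarone
  (class III) and flecainide, propafenone (class IC).
* **Synthetic substrates** — correlated bipolar-voltage fields with
  catheter-style point subsamples, inverse-distance-weighted interpolation
  (normalized d^−a weights in a 10 mm radius), voltage-driven fibrosis,
  fiber-orientation fields, and diffusion calibration to a target
  conduction velocity.
* **Monodomain solver** — anisotropic reaction–diffusion over the lattice
  (Rcpp), no-flux or toroidal boundaries, zero-flux or reduced-coupling
  fibrosis, stimulus protocols (S1 trains, ramps, burst induction,
  cross-field S1–S2) and phase-distributed spiral seeding for sustained
  reentry.
* **Wave dynamics** — APD90, conduction velocity, AF cycle length,
  dominant frequency (3–15 Hz band), phase mapping via the analytic
  signal, phase-singularity detection (topological charge) and tracking,
  AF termination detection.
* **Trial layer** — seeded ensembles over substrate × genotype × drug ×
  dose, the terminated-case exclusion rule, Student and paired t tests,
  Cohen's d, and termination-rate tables with exact-test comparisons.

## A worked example

Paced single-cell electrophysiology by genotype — the core genotype
comparison:

```r
library(afvtrial)

apd <- function(scales) {
  tr <- pace_cell(scales, cycle_length = 600, n_beats = 10)
  a <- measure_apd90(tr)
  tail(a[!is.na(a)], 1)
}
apd(genotype_baseline("wild_type", "SR"))        # 287.9 ms
apd(genotype_baseline("pitx2_deficient", "SR"))  # 230.7 ms

rc  <- restitution_protocol(genotype_baseline("wild_type", "AF"))
fit_restitution(rc)
#> <restitution_fit> y0 = 79.1, A1 = 62.2, tau1 = 162.4 ms, Smax = 0.216
```

The PITX2-deficient cell repolarises ~57 ms earlier than wild-type at a
600 ms cycle length (the doubled I_Kr dominates), and the AF-remodeled
wild-type cell has a shallow restitution curve whose maximal slope is well
below the alternans threshold of 1 — both orderings match the published
genotype contrast.

The numbered scripts under `analysis/` run the full workflow: substrate
construction and calibration (`01`), cell-level electrophysiology and drug
dose–response (`02`), the seeded AF ensemble with Table-style outputs
(`03`, writes `results/table3_ephys.csv`, `table4_deltas.csv`,
`table5_termination.csv`), and report regeneration plus published-count
reproduction (`04`).

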