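---
title: "Separating intrinsic dynamical transitions from resolution effects in elastic neutron scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating intrinsic dynamical transitions from resolution effects in elastic neutron scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynonset)
```

## The measurement model

An elastic fixed-window scan records the elastic intensity S(q, Δt) of a
powder while it is heated at ~1 K/min. The resolution time Δt of the
spectrometer acts, to a good approximation, as a sharp cutoff: the
elastic intensity is the value of the intermediate scattering function at
t = Δt, so motions slower than Δt contribute as if frozen. The package
works at the level of this aggregate intermediate scattering function;
per-atom scattering lengths and trajectories are outside its scope.

Two forward models span the competing explanations of an intensity
onset, and everything else in the package is machinery for telling their
fingerprints apart.

**Resolution-limited relaxation (`water_model()`).** A single thermally
activated process with Arrhenius relaxation time
τ(T) = τ₀·exp(ΔU/(R·T)) under a q-independent elastic incoherent
structure factor (EISF) plateau A₀:

I(q, T) = exp(−q²·c·T/6) · [A₀ + (1 − A₀)·exp(−Δt/τ(T))]

The first factor is the harmonic Debye–Waller envelope with vibrational
MSD slope c; the bracket interpolates between fully elastic (τ ≫ Δt) and
the EISF plateau (τ ≪ Δt). Nothing in this kernel is a transition: the
apparent onset is created where τ(T) crosses Δt, at
T = (ΔU/R)/ln(Δt/τ₀), and therefore moves with the instrument.

**Intrinsic transition (`protein_model()`).** A harmonic MSD that gains
an anharmonic contribution above a hydration-dependent kink temperature:

MSD(T) = c·T + a·max(0, T − T_g(h)),  I(q, T) = exp(−q²·MSD(T)/6)

with T_g(h) interpolated linearly between anchor points. This kernel is
independent of Δt by construction; the onset moves with hydration, not
with the instrument.

The dry companions carry only the harmonic part of each model. The onset
statistic is always computed on the hydrated-minus-dry difference, which
removes hydration-independent anharmonicity (methyl rotations and the
like) — that is the reason the dry protein is simulated *without* a
methyl-activation term: the statistic is designed to cancel it exactly,
so modelling it would only test the subtraction, not the detection.

## Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| ΔU | 38 kJ/mol | activation energy of the water relaxation |
| τ₀ | solves τ(250 K) = 10 ps | Arrhenius prefactor anchored to the fastest window |
| A₀ | 0.7 | EISF plateau; sets the maximal relaxational drop 1 − A₀ |
| c (vib_slope) | 1.5·10⁻³ Å²/K | harmonic MSD slope of both components |
| a (anh_slope) | 5·10⁻³ Å²/K | anharmonic MSD slope above T_g |
| T_g anchors | (0.2, 248 K), (0.4, 228 K) | kink temperatures of a CYP-like protein |
| noise_sigma | 0.005 | relative multiplicative intensity noise |
| T grid | 10–300 K, step 2 K | scan range; base window for normalization ≤ 20 K |
| q grid | 0.3–1.8 Å⁻¹, step 0.05 | q-sum over [0.45, 1.75], Gaussian fit over [0.45, 0.9] |
| resolutions | 1000, 40, 10 ps | 1, 25.4, 100 µeV backscattering windows |

The relaxation map (ΔU, τ₀) and the T_g anchors are the measured study
conditions; A₀ and the anharmonic slope have no published value at this
level of description, so they were fixed once at values giving the
familiar magnitude of hydration-induced intensity drops (tens of percent
of the normalized intensity by 300 K) and are not tuned thereafter.
The energy→time mapping of the four canonical resolutions (1 µeV ↔ 1 ns,
13 µeV ↔ 80 ps, 25.4 µeV ↔ 40 ps, 100 µeV ↔ 10 ps) is a lookup table of
the published correspondences; they are not ħ/ΔE (resolution functions
are not pure Lorentzians), so the α·ħ/ΔE formula is only a fallback for
non-canonical energies, with α left to the user rather than guessed.
The relaxation map itself (10 ps at 250 K, 40 ps at 234 K, 1 ns at
200 K) is the measured input the Arrhenius analysis is anchored to.

## Estimators and numerical choices

**Normalization and q-sum.** Each q column is divided by its mean over
the base window (default 0–20 K); "summed over q" is implemented as the
mean of the normalized columns, which differs from the sum by a constant
the normalization makes irrelevant and keeps series comparable across
instruments with different q grids. The q-sum is unweighted: measured
uncertainties are not propagated into the sum, matching how these scans
are conventionally reduced. Values in the base window itself may exceed
1 by up to the Debye–Waller decay across the window (~10⁻³); this is a
property of the mean-window convention, not an error.

**Gaussian MSD.** Per temperature, OLS of ln S on q² over
q ∈ [0.45, 0.9] Å⁻¹, with ⟨x²⟩ = −6·slope. The intercept is left free so
EISF curvature biases the intercept, not the slope. Temperatures with
non-positive intensities in the fit range are flagged NA rather than
failing the whole series.

**Onset detection.** Common practice in fixed-window studies marks
onsets visually on the plotted curves; an explicit estimator is required
for reproducibility, so two are provided.
The primary estimator fits a continuous two-segment linear model, with
the breakpoint located in two stages: an exhaustive grid search over
interior sample points (each candidate needs ≥ 30 K of data and ≥ 3
points on both sides; ties break to the lower temperature), then a local
refit inside a ±40 K window around the grid optimum with continuous
refinement (Brent search between the neighbouring grid points, tolerance
10⁻⁶ K). The local stage exists because the post-onset difference curve
is only locally linear: a global second segment is tilted by the mild
concavity far above the onset, dragging the breakpoint 1–2 K low and —
worse — quantizing it to the temperature grid, which collapses the
residual-resampling bootstrap onto a single grid point and ruins its
coverage. With the local refit the estimator has ~0.3 K bias and ~0.7 K
replicate scatter at the default noise, and the percentile bootstrap
interval covers the generator breakpoint at its nominal rate (92% of 50
replicates in the calibration run; problem size: 146 temperatures × 31 q
per scan, 199 bootstrap draws). The secondary (threshold) estimator
reports the first temperature where the difference exceeds 3× the
baseline noise (sd over the lowest-quartile temperature window) for 3
consecutive points; it is cheap and intuitive but degenerates on
noiseless input, where the baseline sd reflects numerical residue rather
than a noise floor.

**Which onset feeds the Arrhenius step.** For a resolution-limited
process the deviation onset necessarily *precedes* the τ(T) = Δt
crossing (the hydrated curve starts bending as soon as exp(−Δt/τ)
departs from 1). The pipeline therefore reports both the detected onsets
and the model crossings, and feeds the threshold onsets — which sit
closer to the crossing — into the τ(T_on) = Δt identification, falling
back to the bilinear breakpoints when threshold detection degenerates.
The identification itself is flagged as an assumption in the output, and
the recovered ΔU is expected to be biased relative to the generator
value; the onset-vs-ln Δt slope diagnostic (< 2 K per e-fold ⇒ not
resolution-limited) prevents the identification from being applied to an
intrinsic transition, where it would be meaningless.

**Arrhenius fits.** Unweighted OLS of ln τ on 1/T (the reference
(T, τ) pairs carry no uncertainties to weight by), exact for two points;
ΔU = R·slope with R = 8.314462 J/(mol·K), reported per mole. The
three-point fit and the fit through the extreme two points both give
≈38 kJ/mol; the three-point OLS is used for reporting.

**DSC midpoint.** T_DSC is where the heat-flow curve crosses the mean of
the two extrapolated linear baselines (default windows 160–190 K and
260–290 K — conventions sized to clear the step, configurable where a
thermogram needs different ones). For a symmetric step this
midline crossing is exactly the equal-area construction; for asymmetric
steps it is an approximation. A transition is only reported when the
baselines separate by more than 3× the baseline residual sd (with a
machine-precision floor on the heat-flow scale, so two fits of the same
line never count as a step). The crossing is interpolated linearly
between bracketing samples. Heating rate is carried as metadata but
unused: both the scans and the thermograms assume the same 1 K/min ramp.

## What the synthetic study shows — and what it cannot

The generator reproduces the *statistical structure* the analysis
assumes: a rectangular T × q grid, multiplicative Gaussian noise with a
per-scan seed, dry companions sharing the harmonic envelope, a step-like
DSC transition on drifting baselines. Passing tests on it demonstrate
that the estimator chain recovers known inputs (T_g(h) within 3 K, ΔU
within 20% through the full pipeline, exact inversions on noiseless
kernels) and that the decoupling verdict follows from the two kernels'
fingerprints, not from tuning. It does not demonstrate anything about
multiple scattering, coherent contamination, instrument-dependent
resolution lineshapes (the sharp-cutoff Δt picture replaces the true
Gaussian/Lorentzian convolution), non-Gaussian MSD corrections,
enthalpy-relaxation overshoots in DSC, or non-Arrhenius (VFT) water
dynamics — all deliberately out of scope, and the first things to
suspect when applying the pipeline to measured data.

## Degenerate inputs and edge behaviour

Scans must be strictly rectangular with increasing grids; missing cells
are a read error, not an imputation. Zero base-window means abort
normalization. Onset detection refuses series without an admissible
breakpoint ("no onset detected"), and the verdict degrades to
"inconclusive" rather than guessing when fewer than two resolutions are
available for either component. `crossing_temperature()` refuses
Δt ≤ τ₀ (no crossing exists). Noise without a seed is an error
everywhere: reproducibility is a contract, not a convention.
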