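# dynonset

Tools for deciding whether the ~200 K "dynamical transition" seen in
elastic neutron scattering of hydrated protein powders is an intrinsic
property of the biomolecule or an artifact of the instrument's finite
resolution window — and for showing that the protein and its hydration
water answer that question differently.

## The problem

An elastic fixed-window scan (EFWS) records the elastic intensity
S(q, Δt) while the sample is heated, where Δt is the resolution time of
the spectrometer: motions slower than Δt look frozen. Hydrated proteins
show an onset temperature T_on where the hydrated sample's intensity
drops away from the dry sample's harmonic trend. Two very different
mechanisms produce such an onset:

* **An intrinsic transition.** Structural relaxation of the protein
  unfreezes at a temperature set by the sample itself (a glass-transition
  analogue). The onset does not move when measured with a different
  instrument, but it does move with hydration level h (g water/g protein).
* **A resolution effect.** A thermally activated relaxation with
  Arrhenius time τ(T) = τ₀·exp(ΔU/RT) simply crosses the instrument
  window at the temperature where τ(T) = Δt. The apparent onset then
  moves with the instrument (T = (ΔU/R)/ln(Δt/τ₀)) but not with h.

By isotope labelling (H-protein in D₂O vs perdeuterated protein in H₂O),
EFWS can separate the protein and hydration-water signals. This package
implements the full analysis chain on either measured CSV exports or
synthetic studies generated from the two mechanisms above:

1. normalization of S(q, Δt) to the ~10 K baseline and summation over
   q ∈ [0.45, 1.75] Å⁻¹ (`normalize_to_base()`, `sum_over_q()`);
2. Gaussian-approximation MSD, S(q) = exp(−q²⟨x²⟩/6), fitted over
   q ∈ [0.45, 0.9] Å⁻¹ (`gaussian_msd()`);
3. onset detection on the hydrated-minus-dry difference curve by
   segmented (bilinear breakpoint) regression or a noise-threshold rule,
   with residual-bootstrap confidence intervals (`difference_curve()`,
   `detect_onset()`, `bootstrap_onset()`);
4. Arrhenius analysis: fit of ln τ vs 1/T, activation energy ΔU = R·slope,
   and resolution-window crossing temperatures (`fit_arrhenius()`,
   `crossing_temperature()`, `onsets_to_arrhenius()`);
5. DSC glass-transition midpoint T_DSC where the heat-flow curve crosses
   the mean of the two extrapolated baselines (`fit_baselines()`,
   `detect_tdsc()`);
6. an orchestrated pipeline with a decoupling verdict (`run_study()`,
   `decoupling_verdict()`).

## Worked example

Fit the Arrhenius law to the hydration-water relaxation map
(τ = 10 ps at 250 K, 40 ps at 234 K, 1 ns at 200 K) and ask where that
process would appear to freeze at each spectrometer:

```r
library(dynonset)

fit <- fit_arrhenius(data.frame(temperature_K = c(250, 234, 200),
                                tau_ps       = c(10, 40, 1000)))
fit
#> <arrhenius_fit> dU = 37.99 kJ/mol, tau0 = 1.22e-07 ps (slope 4569.3 K, 3 points, rms(ln tau) = 0.0578)

crossing_temperature(fit, 1000)   # 1 ns window
#> [1] 200.1896
crossing_temperature(fit, 10)     # 10 ps window
#> [1] 250.7885
```

A 38 kJ/mol activated process appears to "switch on" anywhere between
200 and 251 K purely depending on which instrument looks at it. Running
the full synthetic study does the same end to end and renders the
verdict:

```r
rep <- run_study(default_study_config(seed = 1, noise_sigma = 0.005))
onset_table(rep, "protein")
#>   hydration_h dt_1000_ps dt_40_ps dt_10_ps
#> 1         0.2   247.9120 248.0000 248.1429
#> 2         0.3   238.0785 238.3243 238.3755
#> 3         0.4   227.3744 228.0779 228.2696
onset_table(rep, "water")
#>   hydration_h dt_1000_ps dt_40_ps dt_10_ps
#> 1         0.2        162 202.9930 219.1563
#> 2         0.4        162 203.1116 219.2931
rep$verdict$verdict
#> [1] "decoupled"
```

The protein onset is identical across a 100-fold change of resolution
time but drops by ~20 K from h = 0.2 to h = 0.4; the water onset climbs
by ~57 K as the window shrinks from 1 ns to 10 ps but ignores hydration.
The numbered scripts under `analysis/` walk through the same study one
stage at a time (simulation, protein onsets, water resolution effect,
DSC midpoints, final report) and write their tables under `results/`.

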