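# tauchaperone

Quantitative dissection of how molecular chaperones suppress tau amyloid
formation.

The microtubule-associated protein tau aggregates into amyloid fibrils in
Alzheimer's disease and other tauopathies. ATP-independent chaperones —
the small heat-shock protein HSPB1 and the Hsp40/J-domain proteins DNAJA2
and DNAJB1 — delay or block this aggregation, and they do so by different
microscopic mechanisms. This package implements the analysis pipeline that
identifies those mechanisms from standard biophysical measurements:

- **Kinetic model.** Thioflavin-T (ThT) aggregation traces are described by
  a nucleation / saturating-elongation / fragmentation model for the fibril
  number concentration *P* and fibril mass concentration *M*:

      dP/dt = kn · m(t)^nc + km · M(t)
      dM/dt = 2 kp · KE · m(t) / (KE + m(t)) · P(t)

  with free monomer m(t) = m_tot − M(t) by mass conservation, critical
  nucleus size nc = 2, nucleation rate kn, elongation rate kp, fragmentation
  rate km and elongation saturation constant KE (units µM and min). A
  compiled adaptive Dormand–Prince solver integrates the system.
- **Trace preparation.** Baseline subtraction, block-average binning (2–5
  points), conversion of ThT signal to fibril mass via
  M_i(t) = m_max · S_i(t) / S_max∞, half-time extraction, and the scaling
  exponent γ = d log t½ / d log m₀ with a curvature diagnostic.
- **Two-step global fitting.** Unseeded data determine only the composites
  k'n = kn·kp and k'm = km·kp (kp is fixed at 1); adding seeded traces with
  known seed mass M₀ and length L (initial conditions M(0) = M₀,
  P(0) = M₀/L) breaks the degeneracy and yields absolute rates.
- **Chaperone mechanism dissection.** With baseline rates fixed, each
  chaperone concentration is refitted allowing a single rate (kn or kp) —
  or several jointly — to scale; hypotheses are ranked by residual RMSE
  with a parsimony tie-break.
- **Seed sizing from DLS.** Single-exponential fit of the intensity
  autocorrelation g₂(τ) = 1 + β·exp(−2Dq²τ), Stokes–Einstein inversion to
  R_s, prolate-ellipsoid friction inversion a / ln(2a/b) = R_s, and
  L = a / (2 nm per monomer).
- **Binding analysis.** One-site fits of fluorescence anisotropy titrations
  (KD), NMR chemical shift perturbations Δδ = √(Δδ_H² + (Δδ_N/5)²) with a
  mean + 1 SD significance rule, and intensity-ratio (I/I₀) binding maps
  with a mean − 1 SD rule plus the 0.5 strong-attenuation cutoff and
  contiguous-region calling.
- **Synthetic data.** Generators for every input (kinetic plates, dose
  series with known rate suppression, seeded series, DLS curves,
  titrations, NMR peak tables) with recorded ground truth, so the whole
  pipeline is testable without instrument data.

## Worked example

```r
library(tauchaperone)

params <- default_baseline_params()
ds <- generate_aggregation_dataset(
  scenario_spec(baseline = params, replicates = 3),
  noise_spec(sigma = 0.01, kind = "relative", rng_seed = 7))

ht <- do.call(rbind, lapply(ds$traces, function(tr) {
  h <- extract_half_time(tr)
  data.frame(m0 = tr$condition$m0, t_half = h$t_half)
}))
aggregate(t_half ~ m0, ht, mean)
#>     m0    t_half
#> 1  2.5 182.97669
#> 2  5.0 139.14816
#> 3 10.0 109.33966
#> 4 20.0  87.79904
#> 5 40.0  69.60312

sc <- fit_scaling_exponent(ht)
#> gamma = -0.345 +/- 0.004 (curvature 0.036, significant: TRUE)

fit <- fit_unseeded_global(ds, settings = fit_settings(rng_seed = 7))
fit$rates
#> Reduced rates (kp = 1 convention):
#>   k'n = kn*kp = 8.71518e-07
#>   k'm = km*kp = 0.000415102
#>   KE  = 1.91281 uM
```

The half-times shorten only weakly with monomer concentration (γ ≈ −0.34):
the signature of primary nucleation with a fragmentation contribution, and
the upward curvature of the double-log plot reveals elongation saturation.
The reduced composites recover the generating truth (k'n = 8.2e−7,
k'm = 4.1e−4, KE = 2 µM) to a few percent from 1%-noise data.

Seed sizing from a synthetic DLS curve of sonicated seeds:

```r
inst <- instrument_params(lambda0 = 633e-9, theta = 158)
curve <- generate_autocorrelation(beta = 0.9,
                                  D = diffusion_from_radius(55e-9),
                                  q = scattering_vector(inst),
                                  noise = noise_spec(0.01, "relative", 7))
dls_seed_length(curve, inst)
#> Rs = 54.9 nm, a = 203.4 nm, L = 102 monomers
```

A 55 nm Stokes radius, interpreted as a prolate ellipsoid of 10 nm
thickness, corresponds to a ~200 nm fibril of ~100 tau monomers — the seed
length used in the seeded global fit.

`demo_bundle(seed, out_dir)` writes a complete synthetic study (including
three chaperone dose series whose ground-truth mechanisms mirror the
elongation-suppressing, nucleation-suppressing and mixed cases) plus a
ready-to-run JSON config for `run_analysis()`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, against the installed package, the seed-geometry calculation:
the ellipsoid long axis solving a / ln(2a/b) = R_s for R_s = 55 nm and
b = 10 nm, reported in nm.
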