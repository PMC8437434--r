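---
title: "Methods: kinetic dissection of chaperone-mediated suppression of tau aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic dissection of chaperone-mediated suppression of tau aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauchaperone)
```

## The model and its assumptions

Tau amyloid formation under aggregation-promoting conditions is described
by three microscopic processes acting on two moments of the fibril length
distribution — the number concentration $P(t)$ and the mass concentration
$M(t)$ (monomer equivalents inside fibrils):

$$\dot P = k_n m^{n_c} + k_m M, \qquad
  \dot M = 2 k_+ \frac{K_E\, m}{K_E + m} P,$$

with free monomer $m(t)$, primary nucleation rate constant $k_n$,
fragmentation rate constant $k_m$, elongation rate constant $k_+$ (written
`kp` in code) and saturation constant $K_E$, the monomer concentration at
half-maximal growth. The critical nucleus size is fixed at $n_c = 2$ and is
never fitted. ThT fluorescence reports $M$, not $P$: all observables in the
pipeline are mass traces.

Assumptions worth keeping in mind:

- **Mass conservation by construction.** The monomer is never integrated;
  it is eliminated algebraically, $m = m_\mathrm{tot} - M$ with
  $m_\mathrm{tot} = m_0 + M_0$, clamped at zero to absorb numerical
  overshoot near full conversion. This reduces the system to two ODEs and
  makes $m + M = m_\mathrm{tot}$ exact.
- **No secondary nucleation and no explicit co-factor kinetics.** The
  aggregation trigger (heparin) is implicit in the rate constants.
- **Chaperones act as rate scalings.** Chaperone concentration never
  enters the ODEs; each dose is summarized by per-concentration scale
  factors on the microscopic rates. The analysis also assumes chaperones do
  not change the ThT signal per unit fibril mass.

## Numerical integration

No ODE-solver package is available in the target environment, so the
package ships a compiled adaptive Dormand–Prince 5(4) pair with
error-controlled step size (defaults `rtol = 1e-8`, `atol = 1e-10`) and
first-same-as-last reuse. The reduced two-ODE system is only mildly stiff
over the parameter ranges of interest; correctness is checked in the test
suite against an independent fixed-step fourth-order integrator at 10×
finer steps (agreement to better than $10^{-6}$ relative). Initial
conditions always refer to $t = 0$; an output grid starting later (as
produced by block binning) is integrated from 0 to its first point.

## Identifiability and the two-step global fit

For unseeded data ($P_0 = M_0 = 0$) the mass trace is invariant under
$(k_n, k_+, k_m) \to (c\,k_n, k_+/c, c\,k_m)$: only the composites
$k'_n = k_n k_+$ and $k'_m = k_m k_+$, together with $K_E$, are
observable. The fit therefore proceeds in two steps:

1. `fit_unseeded_global()` fixes $k_+ \equiv 1$ and fits
   $(k'_n, k'_m, K_E)$ to all unseeded concentrations simultaneously. The
   amplitude of each trace is *not* a free parameter — it is pinned by that
   trace's $m_0$ through mass conservation.
2. `fit_seeded_global()` adds seeded traces with initial conditions
   $M(0) = M_0$, $P(0) = M_0 / L$ and fits the single parameter $k_+$ with
   $k_n = k'_n/k_+$ and $k_m = k'_m/k_+$ tied so the composites are
   preserved. Seeding supplies a known fibril number, which breaks the
   degeneracy. The seeded model retains the (numerically negligible)
   primary-nucleation term for consistency with the unseeded model.

The seed length $L$ comes from the DLS chain below (default 100 monomers).
Note that $L$ and $k_+$ compensate: doubling $L$ halves $P_0$ and roughly
doubles the recovered $k_+$, so absolute elongation rates inherit the
uncertainty of the seed-length estimate. The composites do not.

**Optimization.** Fits search log10-parameter space. With two or more free
parameters a plain differential-evolution (rand/1/bin, reflection at
bounds) global search is used; with one free parameter, a deterministic
coarse-grid scan followed by golden-section refinement. Both are
bit-reproducible given `fit_settings(rng_seed = )`. Default bounds span
six decades (`k'n`, `k'm` in $[10^{-8}, 10^{-2}]$, $K_E \in [0.1, 10^3]$
µM, factors in $[10^{-4}, 10]$); the objective is the unweighted sum of
squared mass residuals over every point of every trace (no per-trace
weighting by default — none is standard for this assay).

**Uncertainties.** `estimate_rate_errors()` refits independent replicate
sets: with two sets the uncertainty is half the absolute difference, with
more the standard deviation.

## Chaperone mechanism dissection

With baseline rates frozen, `fit_chaperone_single_rate()` refits each
chaperone concentration allowing only $k_n$ or only $k_+$ to scale;
`fit_chaperone_joint()` allows $(k_n, k_+)$ — and $k_m$ when seeded traces
constrain it — to scale together. Fragmentation is otherwise held fixed,
motivated by the observation that chaperone addition leaves fibril length
distributions unchanged. `compare_rate_hypotheses()` ranks hypotheses by
pooled RMSE; at numerically equal residual the hypothesis with fewer free
parameters wins. Each concentration is fitted independently (no shared
dose-response shape is imposed), matching how per-trace refits are done in
practice.

## Half-times and the scaling exponent

The half-time of a mass trace is the linearly interpolated first upward
crossing of half the plateau, where the plateau is the mean of the trailing
10% of points (`plateau_fraction`, configurable). A trace is rejected as
unsaturated when the trailing-window slope exceeds 1% of the peak slope —
this is what excludes fully inhibited chaperone conditions, which show no
ThT signal, from half-time analysis. Whether half-times are taken from raw
or binned traces is the caller's choice; binning shifts them by less than
one bin width on clean data.

The scaling exponent $\gamma$ is the OLS slope of $\log_{10} t_{1/2}$
against $\log_{10} m_0$ (the base cancels in the slope; log10 is used for
reporting). A quadratic term supplies the curvature; it is flagged when its
magnitude exceeds twice its standard error. In this model family, $\gamma$
near $-n_c/2 = -1$ indicates nucleation–elongation control, fragmentation
pulls it toward shallower values, and elongation saturation bends the
double-log plot. The bend is largest — and positive — when $K_E$ falls at
or below the sampled concentration window, as in the calibrated default
world ($K_E = 2$ µM against 2.5–40 µM); very deep saturation
($K_E \ll$ all $m_0$) straightens the plot again, so a green curvature test
establishes saturation onset within the window, not its depth.

## Seed sizing from dynamic light scattering

`fit_autocorrelation()` fits $g_2(\tau) = 1 + \beta e^{-2 D q^2 \tau}$ with
the baseline fixed at exactly 1 (no floated offset; the generators and the
fit agree on this convention), with
$q = (4\pi n/\lambda_0)\sin(\theta/2)$. Stokes–Einstein gives
$R_s = k_B T / (6 \pi \eta D)$. A rod-like seed is modeled as a prolate
ellipsoid of long axis $a$ (the full fibril length) and thickness $b$;
equating its friction $6\pi\eta a / \ln(2a/b)$ to the sphere's $6\pi\eta
R_s$ gives $a / \ln(2a/b) = R_s$, solved by bracketed bisection with a
Newton polish (residual below $10^{-9} R_s$; the tangent case
$b = 2R_s/e$ is returned in closed form). Dividing by the ~2 nm axial rise
per tau monomer yields the seed length $L$. With $R_s = 55$ nm and $b = 10$
nm this gives $a \approx 204$ nm and $L \approx 102$, i.e. the round
numbers 200 nm and 100 monomers quoted for this geometry. Defaults chosen
here: buffer viscosity $8.9\times10^{-4}$ Pa·s (water, 25 °C) since the
buffer value is rarely reported; $\lambda_0$ and $\theta$ are
instrument-specific and required, with no defaults.

## Binding analysis

Anisotropy titrations are fitted with the hyperbolic one-site form
$r(c) = r_\mathrm{free} + (r_\mathrm{bound} - r_\mathrm{free})\,
c/(K_D + c)$, neglecting ligand depletion because the labeled species (0.1
µM) is far below every $K_D$ of interest (µM to hundreds of µM); the exact
quadratic solution is available via `quadratic = TRUE`. A fit is declared
unidentifiable when the fitted amplitude is below three times the residual
noise — the "no binding observed" case.

Chemical shift perturbations combine amide shifts as
$\Delta\delta = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N/5)^2}$ and are
significant above mean + 1 SD computed over *all* quantified residues
(binding region included; an outlier-excluding iteration is deliberately
not the default, since the descriptive rule is stated without exclusions).
Intensity ratios $I/I_0$ are significant below mean − 1 SD — the SD of the
ratios themselves, not of the signal loss $1 - I/I_0$; the two choices give
identical flags for symmetric noise — with a fixed 0.5 cutoff marking
strong attenuation. `call_binding_regions()` reports maximal runs of at
least 3 significant residues, bridging single-residue gaps (both
configurable); the rectangular footprints used in testing
(residues 275–280 and 306–311, the two amyloid-driving hexapeptides) are
recovered exactly at depths of 2 SD or more.

## The synthetic world

The generators produce every input the pipeline reads, each a pure
function of (spec, seed) with the generating truth attached. Because the
source study deposits no raw data and prints no fitted rate values, the
default kinetic baseline was calibrated once to the published observables
and then frozen: $k_n = 1.64\times10^{-8}$, $k_+ = 50$,
$k_m = 8.2\times10^{-6}$, $K_E = 2$ (µM, min; composites
$k'_n = 8.2\times10^{-7}$, $k'_m = 4.1\times10^{-4}$), which reproduces a
110-min half-time at 10 µM tau, a scaling exponent of −0.345 over 2.5–40
µM and positive double-log curvature. Default designs mirror the study:
unseeded series at 2.5–40 µM; chaperone doses 0–10 µM against 10 µM tau;
seeds at $M_0 = 1$ µM, $L = 100$; 3 replicates; additive Gaussian noise at
1–2% of the signal amplitude (instrument noise levels are conventions, not
recoverable from published figures; a heteroscedastic option exists for
robustness checks).

What a green test does and does not establish: the synthetic world has
iid Gaussian noise, perfectly synchronized time grids, no well-position or
gain artifacts, rectangular NMR footprints and a single diffusing species
in DLS. Recovery under these conditions validates the estimators and their
identifiability logic — not robustness to correlated drift, optical
artifacts, polydispersity, or model misspecification.

## Workflow and reproducibility

`run_analysis()` executes the stages in dependency order (prep → baseline
fit → seeded fit → chaperone fits; seed sizing and binding independently),
refusing up front when an enabled stage lacks its inputs or its upstream
stage. Configs are JSON (no YAML parser is available in the target
environment); reports carry the config hash (MD5 of the canonical JSON),
RNG seed, package version, per-stage timings and any warnings (unsaturated
traces, unidentifiable fits) as report fields. `demo_bundle()` emits a
complete synthetic study plus config; the bundled optimizer budget is
deliberately reduced so the full run stays in the minutes range on one
CPU.

## Known limitations

- Absolute rates are conditional on the seed length $L$; only the
  composites $k'_n$, $k'_m$ and $K_E$ are seed-independent.
- The single-exponential DLS fit assumes one diffusing species; no
  cumulant or inverse-Laplace polydispersity analysis is provided.
- Hypothesis ranking is residual-based (RMSE with parsimony tie-break);
  no Bayesian model comparison.
- The ODE model omits secondary nucleation; systems where it dominates
  will be misfit, typically showing up as structured residuals that no
  rate-scaling hypothesis removes.
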