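---
title: "Models and methods behind specbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind specbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

`specbind` analyzes ligand-protein binding by fluorescence quench
titration and protein stability by chemical denaturation, for systems like
small drugs binding serum albumin. This vignette explains the models the
package fits, the assumptions they carry, the design of the synthetic-data
generator used to validate every estimator, and the numerical choices
that matter. It states no result that the test suite or the acceptance
script does not itself compute.

## Quench titrations

A titration series holds total added ligand concentrations (mol/L,
first entry 0) and fluorescence intensities at a fixed emission
wavelength; the first intensity is the ligand-free reference `F0`.
Concentrations are totals: no free-ligand iteration is attempted, because
the plots being reproduced are drawn against added ligand. No
inner-filter correction is applied; a user with corrected intensities
simply supplies them.

**Stern-Volmer.** `fit_stern_volmer()` regresses `F0/F` on `[Q]` by
ordinary least squares. The intercept is *fitted*, not pinned at its
theoretical value 1: a free intercept exposes baseline and dilution
errors instead of absorbing them into the slope, and a warning is flagged
when it strays from 1 by more than 0.05. The slope is `Ksv`
(M⁻¹); dividing by the unquenched lifetime `τ0` gives the apparent
bimolecular quenching rate `kq`. The default `τ0 = 5e-9` s is the
accepted fluorescence lifetime of serum albumin and is overridable.

**Mechanism classification.** Static quenching (ground-state complex)
produces apparent `kq` far above the diffusion-collision ceiling and a
`Ksv` that *falls* as temperature rises (complexes dissociate when
heated); dynamic quenching sits at or below the ceiling and strengthens
with temperature. `classify_mechanism()` applies exactly that rule with a
default ceiling of 1e10 M⁻¹s⁻¹, judging the temperature trend on strict
ordering of the point estimates — three temperatures cannot power a
regression-slope test, so no formal test is pretended. Conflicting
evidence returns `indeterminate`, and the rule and threshold are recorded
in the result.

**Specificity.** Colloidal aggregates of a small molecule sequester
protein, so apparent affinity collapses as protein concentration rises.
`specificity_check()` passes when the maximum pairwise relative spread of
`Ksv` across protein concentrations stays below 0.5 (default), a
deliberately generous bound: genuine colloid artifacts change `Ksv`
severalfold, while a specific binder varies by ~10%.

**Double-log binding plot.** `fit_double_log()` regresses
`log10[(F0−F)/F]` on `log10[Q]`; the slope is the site number `n` and the
intercept `log10 Ka`. Base-10 logarithms are used because the intercept
is read directly off a plot drawn in decades. The regression is
unweighted even though the log transform is heteroscedastic (weakly
quenched points are noisiest); weighted variants are deliberately not
implemented so the estimator matches standard least-squares practice for
these plots. Points with `F >= F0` carry no binding information on the
log scale and are excluded with a count.

A consequence worth knowing: the intercept sits several decades below
the data (`[Q]` ~ 1e-6 to 2e-5 M, intercept at `[Q]` = 1 M), so its
sampling error is amplified and `Ka = 10^intercept` has a lognormal
tail. Under 1% multiplicative intensity noise the *mean* of `Ka` across
replicates is inflated by tens of percent even though `log10 Ka` and `n`
are nearly unbiased (the test suite measures ≤ 1% bias for both and a
median site-number error below 0.04). Report `log10 Ka`, or a median,
when averaging replicates.

## Thermodynamics and kinetics

`fit_vant_hoff()` fits `ln Ka` against `1/T`: `ΔH = −R·slope`,
`ΔS = R·intercept`, with `R = 8.3145` J/mol/K and energies carried in
J/mol (printed in kJ/mol). With exactly two temperatures the line is
exact and standard errors are reported as `NA` rather than fabricated.
`ΔG(T)` is populated from `ΔH − TΔS`; the alternative route `−RT·ln Ka`
is computed and stored as a diagnostic (`dG_minus_RTlnKa_at`) because the
two differ whenever the line misfits, and silently blessing one route
hides that.

`diffusion_limited_kf()` implements the Smoluchowski encounter rate
`kf = 4π·r·D·N_A × 1000` (radius in m, `D` in m²/s; the factor 1000
converts m³ to litres). With the conventional inputs `D = 1e-9` m²/s
(= 1e-5 cm²/s) and `r = 0.4` nm it gives 3.027e9 M⁻¹s⁻¹. Literature
discussions of this estimate sometimes quote ~4e9 M⁻¹s⁻¹ and a
correspondingly shorter residence time; the package computes the stated
formula from the stated inputs and reports its actual output rather than
adjusting constants toward a quoted figure. `residence_time()` then
applies `kb = kf/Ka`, `τ = 1/kb`, so `Ka = kf·τ` holds exactly.

## Three-state chemical denaturation

The unfolding model is the sequential scheme N ⇌ I ⇌ U with step free
energies linear in denaturant, `ΔG_i = ΔG_i^H2O − m_i·[urea]`, each step
treated as a two-state equilibrium. The analysis pipeline is:

1. **Baselines** (`fit_baselines()`): independent OLS lines over the
   pre-transition, intermediate and post-transition windows. Defaults
   N: 0–2.25 M, I: 4.75–5.25 M, U: ≥ 8 M encode the known landmarks of
   serum-albumin urea unfolding (onset near 2.4 M, intermediate plateau
   near 5 M) and are aligned to a 0.25 M grid so each window holds at
   least two points. Windows are user-supplied in any real analysis;
   automatic region detection is fragile and deliberately absent.
2. **Fractions** (`state_fractions()`): `f_I = (y − y_N)/(y_I − y_N)` in
   the first transition range, `f_U = (y − y_I)/(y_U − y_I)` in the
   second, with baselines extrapolated as fitted lines. Transition
   ranges are the *open* intervals between adjacent windows: a point
   lying exactly on a window boundary is baseline data, not transition
   data. Values outside [−0.05, 1.05] are flagged, not altered; nearly
   coincident baselines (relative separation < 1e-12) are a degenerate
   error.
3. **Per-point free energies** (`per_point_dG()`):
   `ΔG = −RT·ln(f/(1−f))`, restricted to `f` in [0.05, 0.95] (default)
   because the log-ratio diverges at the bounds; excluded points are
   counted. The transform and the two-state logistic are exact mutual
   inverses, which the tests assert to 1e-12.
4. **Fits**: `fit_lem()` regresses the per-point `ΔG` on `[urea]`
   (intercept `ΔG^H2O`, slope `−m`, midpoint `ΔG^H2O/m`);
   `fit_nonlinear()` fits the two-state logistic in fraction space by
   Levenberg-Marquardt, initialized from the LEM line, with a small
   restart grid (×0.5/×2/×4 on both parameters) before declaring
   failure. Fitting fraction space rather than raw signal avoids
   re-estimating baselines inside the optimizer; non-identifiable data
   (constant fractions, or fractions never entering (0.1, 0.9)) are
   refused with a fit-failure error rather than returned with huge
   uncertainties. Temperature defaults to 298 K throughout.

`compare_stability()` totals `ΔG^H2O` over both transitions per side and
reports `ΔΔG^H2O = total_complex − total_apo` with a per-transition
breakdown; both sides must come from the same regression method.

## The synthetic-data generator

The generator's purpose is to give every analysis stage an oracle whose
answer is known exactly, so estimator defects cannot hide behind model
misfit.

**Quench titrations** are drawn from the saturable form
`F = F0/(1 + Ka·[Q]^n)`, which makes the Stern-Volmer relation exact at
`n = 1` and the double-log plot an exact line for every `n` — the fitted
equations *are* the generating model. Defaults mirror the bench
experiment: a 0–20 µM grid in 1 µM steps (a 0–20 µL titration of 2.7 mM
stock into 3 mL), `F0 = 1000`. Temperature families are generated with
`Ka(T) = exp(−ΔH/RT + ΔS/R)` exactly; per-temperature seeds derive from
the base seed by increment.

**Noise** is multiplicative lognormal with unit mean and specified
coefficient of variation (refused at ≥ 0.2 as implausible for a
fluorimeter): fluorescence error scales with intensity, and positivity is
preserved so log transforms never fail. The ligand-free `F0` point is
emitted exactly.

**Denaturation profiles** offer two signal models.
`signal_model = "stepwise"` (default) renders each transition as its
exact two-state conversion inside its own denaturant zone (defaults
2.25–4.75 M and 5.25–8 M, matching the analysis windows) with pure
baseline lines outside. For this model the baseline → fraction → fit
pipeline is an exact inverse, and the linear and nonlinear routes agree
to machine precision — the same design philosophy as the quench
generator. `signal_model = "sequential"` instead emits the
thermodynamically coupled mixture `y = p_N·y_N + p_I·y_I + p_U·y_U` with
populations from the sequential partition function
(`p_N = 1/(1 + K1 + K1·K2)`, exposed by `three_state_populations()`,
which sums to one to 1e-12 by construction).

The distinction matters. With realistic albumin-like parameters
(`ΔG ≈ 15–17` kJ/mol, so `K2 ≥ exp(−ΔG2/RT) ≈ 0.002` at *any* urea
concentration), the three states genuinely coexist: the intermediate
never exceeds ~90% population, and with the default `m`-values the two
transitions overlap heavily. Applying the two-state fraction analysis to
such coupled data is structurally biased — in internal experiments the
recovered `ΔG^H2O` was off by anywhere from ~10% to the point of
unusability depending on the overlap — and no choice of baseline windows
repairs it, because the baseline regions themselves are never pure
states. That bias is a property of the classical analysis, not of this
implementation; the stepwise model exists precisely so that estimator
correctness can be verified independently of it. Users analyzing real
profiles of marginally stable proteins should read reported `ΔG^H2O`
values as the two-state-per-step approximation the method defines, not
as exact partition-function quantities.

**Scattering series** emulate colloid-formation monitoring: flat mean
signal below an aggregation threshold, steep linear rise above, or flat
everywhere when no threshold is given.

The generator does *not* simulate wavelength-resolved emission spectra,
emission-maximum shifts, photobleaching, inner-filter effects, or
instrument drift; passing tests therefore demonstrate estimator
correctness under the stated models, not robustness to every artifact of
real instruments.

## Numerical choices and problem sizes

- Energies in J/mol, concentrations in mol/L, `R = 8.3145` J/mol/K,
  `N_A = 6.02214076e23`; readers convert `mM`/`µM` inputs on ingest.
- All file I/O is plain text; writers emit ≥ 15 significant digits so
  write/read round trips are identities to float precision, and no
  interpolation is ever performed in I/O (mismatched wavelength grids are
  an error).
- CD conversion uses `[θ] = CD_mdeg/(10·n·l·C_p)`, the divisor convention
  that yields deg·cm²·dmol⁻¹ from millidegrees, centimetres and molar
  concentration; a unit test pins the convention so changing it is a
  deliberate one-line edit.
- Seeding: every stochastic generator takes an explicit integer seed and
  restores the caller's RNG state afterwards; the pipeline runner derives
  per-stage seeds as `seed + stage index` and refuses noisy simulation
  stages without a seed. Identical config and seed give byte-identical
  JSON artifacts (verified by manifest MD5 comparison in the tests).
- Validation problem sizes were chosen to keep the whole suite under
  ~10 s: 1000 replicates for the Stern-Volmer and double-log noise
  calibrations (21- and 20-point series), 500 replicates for the
  nonlinear-fit standard-error calibration (9-point fraction curves), and
  37-point denaturation grids. At these sizes the measured calibrations
  are: Stern-Volmer mean bias ≤ 1% with ~95% t-interval coverage,
  double-log `n` and `log10 Ka` mean bias ≤ 1%, and ≥ 95% of nonlinear
  fits within three reported standard errors of truth.

## Known limitations

- No combined static+dynamic (sphere-of-action) quenching model, no
  time-resolved lifetime fitting.
- No multi-site (Scatchard/Adair) binding models; `n` is the empirical
  double-log slope, not a site count from a partition function.
- van't Hoff analysis assumes temperature-independent `ΔH` (no `ΔC_p`
  term), appropriate for narrow temperature spans only.
- No global three-state fit of raw signal with shared baselines; the
  package implements the classical baseline-partition analysis and
  documents its bias regime instead.
- CD secondary-structure deconvolution is out of scope; only the raw
  conversion and shape ratios are provided.
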