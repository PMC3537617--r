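# specbind

Spectroscopic analysis of small-molecule binding to serum albumin and its
consequences for protein stability.

When a ligand quenches the intrinsic tryptophan fluorescence of a protein,
a bench fluorimeter is enough to measure how tightly it binds, how many
sites it occupies, what drives the interaction thermodynamically, how long
the complex lives, and — with a urea titration — how much the ligand
stabilizes the folded protein. `specbind` packages that entire analysis
chain for R, together with a seeded synthetic-data generator with known
ground truth, so every estimator can be validated against data whose
answer is known exactly.

## What it computes

**Quenching and binding.** For a titration with quencher concentrations
`[Q]` and intensities `F` (ligand-free intensity `F0`):

- Stern-Volmer: `F0/F = 1 + Ksv·[Q]`, fitted by OLS with a free intercept;
  the bimolecular quenching rate is `kq = Ksv/τ0` (default lifetime
  τ0 = 5 ns for serum albumin). `kq` far above the diffusion-collision
  ceiling (~1e10 M⁻¹s⁻¹) together with Ksv falling as temperature rises
  classifies the mechanism as static (complex formation);
  `classify_mechanism()` encodes that rule, and `specificity_check()`
  flags the colloid-aggregation signature (Ksv collapsing with increasing
  protein concentration).
- Double-logarithmic binding plot: `log10[(F0−F)/F] = log10 Ka + n·log10[Q]`,
  giving the association constant `Ka` (intercept) and site number `n`
  (slope).

**Thermodynamics and kinetics.** `fit_vant_hoff()` regresses `ln Ka` on
`1/T`: `ΔH = −R·slope`, `ΔS = R·intercept`, `ΔG(T) = ΔH − TΔS` (with
`−RT·ln Ka` reported alongside as a diagnostic). `residence_time()` uses
`Ka = kf/kb` with a Smoluchowski diffusion-limited forward rate
`kf = 4π·r·D·N_A·1000` to give the complex residence time `τ = 1/kb = Ka/kf`.

**Stability.** For urea denaturation following the sequential three-state
scheme N ⇌ I ⇌ U, `fit_unfolding()` fits linear baselines to the pre-,
intermediate- and post-transition regions, converts signal to state
fractions `f = (y − y_low)/(y_high − y_low)`, transforms to per-point free
energies `ΔG = −RT·ln(f/(1−f))`, and estimates each step's
`ΔG^H2O` and `m`-value both by the linear extrapolation method
(`ΔG = ΔG^H2O − m·[urea]`) and by nonlinear fitting of the two-state
logistic in fraction space. `compare_stability()` totals the two steps for
apo protein and complex and reports the ligand-induced stabilization
`ΔΔG^H2O`.

**CD.** `to_mre()` converts raw circular dichroism (millidegrees) to mean
residue ellipticity `[θ] = CD_mdeg/(10·n·l·C_p)` in deg·cm²·dmol⁻¹, and
`ellipticity_ratio()` computes near-UV shape diagnostics such as the
268/262 nm ratio.

All inputs are plain delimited text (CSV/TSV with optional `# key: value`
metadata lines); results serialize to JSON with units in the field names.
`run_pipeline()` executes a whole simulate → fit → compare analysis from
one YAML/JSON config, writing every artifact plus a manifest, and is
byte-reproducible given a seed. A thin command-line wrapper lives at
`inst/scripts/specbind.R`.

## Worked example

Simulate a three-temperature titration family with known binding
thermodynamics (ΔH = −15.13 kJ/mol, ΔS = 40.87 J/mol/K), then run the full
quench → binding → van't Hoff → kinetics chain:

```r
library(specbind)
base <- quench_truth(Ka_assoc_per_M = 1, F0 = 1000)   # Ka comes from dH, dS
series <- generate_temperature_series(-15130, 40.87, c(293, 298, 303), base)

fits <- lapply(series, fit_stern_volmer)
fits[[2]]
#> <Stern-Volmer fit: Ksv = 6.12e+04 +/- 6e-12 M^-1, kq = 1.224e+13 M^-1 s^-1, R^2 = 1.00000, T = 298 K>
classify_mechanism(fits)
#> <quenching mechanism: static (limit 1e+10 M^-1 s^-1)>

ka <- vapply(series, function(s) fit_double_log(s)$Ka_assoc_per_M, 0)
fit_vant_hoff(data.frame(temperature_K = c(293, 298, 303), Ka_assoc_per_M = ka))
#> <van't Hoff fit: dH = -15.13 kJ/mol, dS = 40.87 J/mol/K, R^2 = 1.00000>
#>   dG(293 K) = -27.10 kJ/mol (dH - T dS); differs from -RT lnKa by -0.00 kJ/mol
#>   dG(298 K) = -27.31 kJ/mol (dH - T dS); differs from -RT lnKa by -0.00 kJ/mol
#>   dG(303 K) = -27.51 kJ/mol (dH - T dS); differs from -RT lnKa by -0.00 kJ/mol

residence_time(ka[2])
#> <kinetics: kf = 3.03e+09 M^-1 s^-1, kb = 4.95e+04 s^-1, residence time = 2.02e-05 s>
```

The recovered ΔH and ΔS are the generator's truth; the quenching rate sits
three decades above the collisional ceiling, so the call is static
quenching, and the diffusion-limited model puts the complex residence time
at ~20 µs.

Stability analysis of a synthetic apo/complex pair (truths 17.19 + 15.23
vs 19.09 + 15.32 kJ/mol):

```r
apo <- fit_unfolding(generate_unfolding(unfold_truth()))
apo
#> <three-state unfolding analysis>
#>   linear N_to_I: dG_H2O = 17.19 kJ/mol, m = 3.50 kJ/mol/M, midpoint = 4.91 M
#>   linear I_to_U: dG_H2O = 15.23 kJ/mol, m = 2.50 kJ/mol/M, midpoint = 6.09 M
#>   nonlinear N_to_I: dG_H2O = 17.19 kJ/mol, m = 3.50 kJ/mol/M, midpoint = 4.91 M
#>   nonlinear I_to_U: dG_H2O = 15.23 kJ/mol, m = 2.50 kJ/mol/M, midpoint = 6.09 M

cpx <- fit_unfolding(generate_unfolding(
  unfold_truth(dG1_J_per_mol = 19090, m1_J_per_mol_per_M = 3900,
               dG2_J_per_mol = 15320)))
compare_stability(apo$fits$nonlinear, cpx$fits$nonlinear)
#> <stability (nonlinear): total apo 32.42, complex 34.41, ddG_H2O = 1.99 kJ/mol>
#>   per transition: N->I +1.90, I->U +0.09 kJ/mol
```

Both regression routes recover the generator truths exactly, and the
stabilization is confined to the first (N → I) transition — the signature
of a ligand binding the native state of the domain that unfolds first.

## Further reading

The methods vignette (`vignettes/specbind-methods.Rmd`) documents the
models and their assumptions, the synthetic generator's design — including
why its default unfolding signal renders each transition as an exact
two-state conversion, and the bias to expect when analyzing
thermodynamically coupled three-state data — numerical choices,
tolerances, and known limitations.
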