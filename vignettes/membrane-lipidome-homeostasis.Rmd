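---
title: "Quantifying membrane lipidome homeostasis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane lipidome homeostasis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memlipid)
```

## The problem

Mammalian cells challenged with dietary polyunsaturated fatty acids (PUFAs)
such as DHA (22:6, omega-3) or arachidonic acid (AA, 20:4, omega-6) rapidly
incorporate them into membrane glycerophospholipids (GPLs). Because
polyunsaturated chains fluidize bilayers, an uncompensated influx would
perturb membrane packing and permeability. Cells respond homeostatically:
saturated lipids and cholesterol rise, di- and tri-unsaturated species fall,
and bulk biophysical properties recover. `memlipid` implements the
quantitative chain needed to measure this adaptation: shotgun-lipidomics
composition statistics, first-order incorporation/wash-out kinetics,
C-Laurdan generalized polarization (GP) spectroscopy and imaging, and
Fick's-law permeability estimation, together with synthetic-data generators
that stand in for raw measurements and retain ground truth.

## Lipid nomenclature

Species are annotated as
`[class]-[total carbons]:[total double bonds];[total hydroxyls]`, e.g.
`SM-32:2;1`, with chain-resolved variants listing each acyl chain
(`PC-16:0;0-18:1;0`). The parser accepts hyphen- and space-separated
dialects and a missing hydroxyl field (defaulting to 0), and renders a
single canonical hyphen form. Ether lipids keep the `O-` marker in the class
token (`PC O-34:1;0`); `Chol` carries no composition and isotope-labelled
cholesterol standards are stripped to `Chol` with a warning. The class
vocabulary is closed (24 classes) but extensible via
`register_lipid_class()`. Chain/total consistency is asserted at
construction, so invalid species cannot circulate downstream.

A deliberate epistemic rule governs chain queries: a sum-only species of a
multi-chain class (e.g. `PC-38:6;0`) *cannot* be judged to contain a
particular chain — guessing a split would fabricate data. Such species count
as non-carriers, and every chain-level statistic reports the mol% of
abundance that lacked chain resolution so users can bound the error. Lyso
(single-chain) classes are the exception: their one chain is implied by the
totals.

## Composition statistics

All statistics operate on mol% compositions produced by
`normalize_lipidome()`, with three scopes:

* `all` — every detected species;
* `membrane` — storage lipids (TAG, SE) removed, then renormalized;
* `GPL` — glycerophospholipid classes only (PA, PC, PE, PG, PI, PS, their
  lyso and ether variants, and CL — a chemistry-based choice, configurable
  through the class registry).

The unsaturation index is the mol%-weighted mean of total double bonds per
lipid; cholesterol, having no acyl composition, is excluded with a message.
The "remaining lipids" analysis (`exclude_set()`) removes every species
carrying a supplemented chain or one of its metabolic derivatives
(DHA set: 22:6, 20:5, 24:6; AA set: 20:4, 22:4, 24:4 — shipped as
`omega3_chains()` / `omega6_chains()`) and renormalizes, so compensatory
remodeling is not swamped by the supplemented species themselves.

Two points were genuinely open and resolved as follows:

* *"Di/tri-unsaturated" binning.* The saturation profile bins species by
  **total** double-bond count (0..6, 7+), so "di-unsaturated" means total
  db = 2. Chain-level percentages (saturated chains, 5-6 db chains) are
  computed separately over chain-resolved species, abundance-weighted with
  each chain counted once. Both views are exposed; neither is asserted as
  the only correct reading.
* *Unsaturation-index scope.* The default scope for chain statistics is GPL
  (a warning is raised otherwise); the index itself can be computed on any
  scope, since the scope travels with the object.

Replicate aggregation is mean ± SD across samples; fold changes are ratios
of group means with a delta-method standard deviation
(`condition_fold_change()`). Hypothesis testing is left to standard R
routines (`t.test`, `aov`) on the tidy per-sample output.

## Kinetics

Incorporation and wash-out time courses are fit with a single
three-parameter first-order model,

$$y(t) = y_\infty + (y_0 - y_\infty)\,e^{-kt},$$

covering rise and decay by the sign of $y_0 - y_\infty$; the half-time is
$\ln 2 / k$. Fitting uses bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with $k \in [10^{-6}, 10^3]\ \mathrm{h^{-1}}$,
initialized at $y_0$ = first value, $y_\infty$ = last value, and $k$ from
the time of closest approach to the midpoint — a robust recipe for monotone
courses. Ordinary (unweighted) least squares is used since replicate
variances are not modeled. Optimizer failure is reported via a
`converged = FALSE` flag rather than an exception, and `half_time()` refuses
non-converged fits. Courses may be fit pooled or as replicate means; pooled
is the default.

A caution on precision: with 7 time points and noise at 10% of the
amplitude, the Cramér–Rao bound puts the relative standard deviation of
$\hat k$ near 27%, so individual fits at that noise scatter widely even
though the median across many courses is accurate to a few percent. The
package's recovery tests therefore check the median at 10% noise and the
per-fit 20%-accuracy rate at ~3% noise, where the estimator is comfortably
inside the bound.

## Generalized polarization

GP compares blue- and red-shifted emission:

$$GP = \frac{I_{blue} - I_{red}}{I_{blue} + I_{red}} \in [-1, 1],$$

with higher values reporting tighter lipid packing. Two band conventions
coexist and are never mixed: cuvette spectroscopy integrates 420–460 nm vs
470–510 nm of a full emission spectrum, while confocal spectral imaging
collects 433–463 nm vs 473–503 nm detector bands (`gp_bands()`).

The imaging pipeline is: 2×2 **sum**-binning (photon-count preserving;
for a ratio like GP, sum vs mean binning is immaterial, but summation keeps
the Poisson statistics interpretable), per-channel background subtraction
clipped at zero, and a dual-channel threshold keeping pixels whose
subtracted intensity exceeds 3 background standard deviations in **both**
channels. Background statistics come from a user-supplied ROI; absent one,
pixels at or below the 10th intensity percentile in both channels serve as
an automatic, reproducible fallback. Valid pixels with a zero denominator
are invalidated and counted rather than propagated as NaN.

Internal membranes are quantified by three deliberately independent
methods — mask histogram, line scans (outermost prominent GP peaks = plasma
membrane, trimmed interior between them = internal), and a perinuclear
ROI — because agreement among them is itself the robustness check. Line-scan
parameters the underlying method leaves unstated were fixed once: peak
prominence ≥ 25% of the line's GP range (measured as the deeper one-sided
descent, so a PM peak at the edge of the valid region still registers), PM
value from a 3-pixel window around each peak (counters the upward bias of a
noisy maximum), a 3-pixel margin next to each peak excluded from the
internal average (keeps ring shoulders out), and scan lines restricted to
rows with at least 60% of the best row's valid pixels (avoids tangential
grazes of the PM). Histograms use 100 bins over [-1, 1] and report both
counts and densities. A perfectly uniform map, where no peaks exist, is
quantified as its uniform GP rather than erroring.

## Permeability

Fluorescein diacetate (FDA) permeates the plasma membrane and is hydrolyzed
intracellularly to fluorescent fluorescein, so the fluorescence slope reads
out a constant molar flux $Q$ once calibrated against fluorescein standards
(OLS through the origin by default). Fick's law then gives

$$Q = P \cdot A \cdot (C_{out} - C_{in}),$$

with $C_{in} = 0$ for FDA (instant conversion; the general form is
implemented for reuse), $A$ = cells × area per cell, and concentrations
converted with an FDA molar mass of 416.4 g/mol (fluorescein sodium salt:
376.3 g/mol; both configurable). The slope is estimated over the full trace
by default, with R² and the longest prefix window at R² ≥ 0.99 reported as
linearity diagnostics and an opt-in longest-linear-prefix slope.

One arithmetic subtlety is surfaced rather than hidden: with the classic
worked inputs ($Q = 6.6\times10^{-14}$ mol/s, 250,000 cells at
~3000 µm², 2.5 µg/mL FDA), strict evaluation gives
$P \approx 1.5\times10^{-6}$ cm/s, about 1.5-fold below the commonly quoted
$\sim2.2\times10^{-6}$ cm/s — consistent with a smaller effective per-cell
area (~2000 µm²) having been used. `permeability_coefficient()` always
returns the strict result together with every input it used; no intent is
guessed.

## Synthetic data and what passing tests mean

Each generator is seed-deterministic and returns a machine-readable truth
record.

* **Lipidomes.** A hand-constructed ~55-species baseline
  (`baseline_profile()`; class proportions loosely follow published
  mammalian whole-cell ranges, with <1 mol% omega-3-containing and ~5 mol%
  omega-6-containing GPLs) is transformed within its GPL pool: the
  supplemented-chain group is scaled to the target mol% (defaults: 15 for
  DHA, 18 for AA), fully saturated species by the configured fold (default
  2), di/tri-unsaturated species by the depletion factor (default 0.6), and
  the remainder absorbs the difference. Targets are therefore exact before
  noise. Replicate noise is multiplicative lognormal per species (default
  CV 10%, n = 4), matching the compositional character of the data.
* **Time courses** add Gaussian noise to exact first-order curves
  (defaults: half-times 4 h incorporation / 25 h wash-out, amplitude
  15 mol%).
* **Images** (128×128 px) place an elliptical cell with a 6-px PM ring at
  GP 0.45, interior at GP 0.10, a dark nucleus at background level, and a
  dye signal of 500 counts/pixel riding on an unpolarized background of 10,
  split between channels as $I(1\pm g)/2$ with optional Poisson noise.
* **Spectra** mix two Gaussian emission bands (440/490 nm, SD 15 nm) with
  weights solved so the spectroscopy band sums realize the target GP
  exactly.
* **Traces** are linear with slope $PAC_{out}/f_{cal}$ plus Gaussian noise
  (default 1% of the signal rise), from a default
  $P = 2.2\times10^{-6}$ cm/s.

These generators emulate the *statistical structure* of the measurements —
effect sizes, noise character, image geometry — not their biology. They do
not reproduce >600-species lipidomes, cell-to-cell variability, optical
aberrations, photobleaching, or enzymatic saturation of FDA hydrolysis.
Passing recovery tests therefore demonstrates that the estimators are
correct and unbiased under each measurement's idealized noise model, not
that any biological conclusion holds; conversely, a failure would indicate
an estimator defect, since the truth is known by construction.

Problem sizes used throughout the test suite and the reproduction script —
200-seed Monte-Carlo sweeps for kinetics, 4 replicates per lipidome arm,
three 128×128 images per imaging condition — were chosen as the smallest
sizes at which the Monte-Carlo error is clearly below the tolerances being
checked.

## Degenerate inputs and numerical conventions

* mol% compositions must sum to 100 within 1e-9 and are revalidated after
  every exclusion/renormalization.
* All-equal time courses are rejected (rate unidentifiable); fewer than 4
  points is an error.
* Zero-denominator GP pixels are invalidated and counted; uniform maps take
  the degenerate line-scan path described above.
* Traces must span ≥ 60 s with ≥ 10 points; calibration needs ≥ 3 standards
  spanning ≥ 10-fold concentration; a flat trace yields zero flux, a
  negative slope is an error ("no net influx").
* Matrices are row-major with masks as same-shape logicals; `bin_mask()`
  offers any/majority/all rules (1/2/4 of the 2×2 block), with the eroding
  `all` rule recommended for contamination-free region ROIs.
* Tie-breaks: the midpoint time for the kinetic $k$ start uses the first
  closest point; line-scan PM peaks are the outermost qualifying maxima.

## Limitations

* Chain-level statistics silently reflect only the chain-resolved fraction
  of the lipidome; the unresolved mol% is reported but not imputed.
* The line-scan quantifier assumes a roughly convex cell with a single PM
  crossing per side; touching cells or strongly non-convex geometries need
  user-supplied masks.
* The permeability model assumes constant flux and perfect sink conditions
  ($C_{in}=0$); saturating hydrolysis or efflux would bias $P$ downward.
* No lipid identification, mass computation, or MS feature filtering is
  performed; tables are taken as post-processed species abundances.
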