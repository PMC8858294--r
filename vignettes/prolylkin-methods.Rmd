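---
title: "Models and methods behind prolylkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prolylkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prolylkin)
```

`prolylkin` chains four analyses that together relate the catalytic
efficiency of a two-domain prolyl isomerase to the binding and structural
properties of its peptide substrates: two-site exchange NMR lineshape
fitting, titration regression to `kcat/KM`, calorimetric binding models,
and inter-domain geometry, tied together by outlier-robust correlation
statistics. This vignette records the models, their assumptions, the
defaults, and the numerical and design choices, in the package's own words.

## Two-site exchange lineshapes

### Model

A substrate methyl group adjacent to the isomerized proline resonates at
different frequencies in the cis and trans isomers. With populations
`p_cis + p_trans = 1`, angular positions `Ω = 2π·diag(ν_cis, ν_trans)`,
intrinsic relaxation `R = diag(r2_cis, r2_trans)` and the detailed-balance
exchange matrix `K` built from `k_ct = p_trans·k_ex`, `k_tc = p_cis·k_ex`,
transverse magnetization obeys `dM/dt = (iΩ − R + K)M`. The absorption
spectrum is the steady-state solution

`I(ν) = 2·A·Re{ 1ᵀ (i2πν·I − iΩ + R − K)⁻¹ p }`,

evaluated in closed form from the 2×2 complex inverse, vectorized over the
frequency grid. The normalization makes the integral over ν equal the
amplitude `A` and — a property the tests assert — independent of `k_ex`.
Assumptions: the two-site approximation (no third conformer), frequency-
independent intrinsic relaxation over the fitted window, and a flat
baseline after reference subtraction.

Two classical limits serve as analytic cross-checks: in slow exchange
(`k_ex ≪ 2πΔν`) the cis line broadens by exactly `p_trans·k_ex`; in fast
exchange a single line appears at the population-weighted frequency with
exchange broadening `p_cis·p_trans·(2πΔν)²/k_ex`. Both hold in the
implementation to well under the 2%/5% envelopes the test suite enforces.

### Fitting strategy

Following the logic of the underlying assay, nothing about the exchanging
doublet is refitted per titration point except the rate itself:

* the intrinsic relaxation rate (including field inhomogeneity) comes from
  a Lorentzian fit to the second, non-exchanging methyl of the same leucine
  (`fit_intrinsic_linewidth()`; the FWHM of a line is `r2/π` Hz);
* populations and line positions come from the enzyme-free spectrum
  (`fit_reference_doublet()`, two-Lorentzian fit; populations are
  fractional areas, the *minor* line is taken as cis by default);
* `fit_apparent_exchange()` then floats only `k_app ≥ 0` plus one shared
  amplitude and a constant baseline. For a candidate rate the amplitude and
  baseline are linear parameters and are profiled out exactly by linear
  least squares, so the rate is found by a 1-D profile search: a 60-point
  log-spaced grid on `[0.1, 2000] s⁻¹` (plus 0) followed by golden-section
  refinement of the bracketing interval. This cannot miss a basin the grid
  resolves and makes convergence failures essentially impossible; a fit at
  the upper search bound is flagged, never silently clipped.

A single shared amplitude (rather than per-line amplitudes) is used because
the two lines belong to one spin whose total integral is conserved;
per-line amplitudes would absorb part of the exchange broadening and bias
`k_app` downward.

Uncertainties are one-standard-deviation Monte-Carlo estimates
(`monte_carlo_uncertainty()`, default 500 replicates, 100 in the bundled
pipeline for speed): synthetic spectra are regenerated from the best-fit
model plus Gaussian noise at the estimated baseline noise level and
refitted; the RNG state is sandboxed so a given seed is bit-reproducible
without disturbing the caller's stream.

### Titration to `kcat/KM`

At substrate concentrations well below `K_M`, `k_app = k0 + (kcat/KM)·[E]`.
`fit_activity_slope()` fits this line, weighted `1/σ²` when Monte-Carlo
uncertainties are available and by ordinary least squares otherwise (both
are exposed; the weighted slope is invariant to a uniform rescaling of all
σ, which the tests assert). The intercept is left free rather than pinned
to the zero-enzyme rate: the uncatalysed isomerization rate is itself an
estimate, and a free intercept lets the regression absorb it with an
honest standard error. Units follow the titration convention: µM for
concentrations, so slopes are `µM⁻¹s⁻¹`; converters to `M⁻¹s⁻¹` are
provided.

The limiting-regime calculator `efficiency_regimes()` evaluates
`kcat/KM = k_on·k_cat/(k_off + k_cat)` and labels the regime EX2-like
(binding-equilibrated, value → `k_cat/K_D`) or EX1-like
(association-limited, value → `k_on`) when the relevant rate ratio is at
least 100 — the point at which the limit formulas agree with the general
form to 1% — and "intermediate" otherwise. `koff_upper_bound()` implements
the diffusion-limited bound `k_off ≤ k_on·K_D` (e.g. 5000 s⁻¹ at
`k_on = 10⁸ M⁻¹s⁻¹`, `K_D = 50 µM`).

## Calorimetric binding models

The binding model is one or two *independent* site classes
`(n_j, K_D,j, ΔH_j)`; the one-site model is the exact restriction of the
two-site model, which the tests verify by driving `n₂ → 0`. The free
titrant concentration solves the mass balance
`X_t = [X] + M_t·Σ_j n_j[X]/(K_D,j+[X])` by `uniroot` on `[0, X_t]`
(residual below `10⁻¹⁰·X_t`; for one site the quadratic closed form is the
test oracle). Cumulative heat is
`Q = V·M_t·Σ_j n_j·ΔH_j·[X]/(K_D,j+[X])`.

Two dilution conventions are exposed:

* `"perfusion"` (default): the overfilled-cell instrument convention,
  cell concentrations scaled by `(1−f/2)/(1+f/2)` with `f` the cumulative
  injected volume fraction, and differential heats corrected for the heat
  carried out in the displaced volume. Under this convention roughly 5% of
  the total heat of the default protocol leaves the active volume with
  partially saturated complex, so total heat is *not* exactly conserved —
  that is a property of the convention, not an error.
* `"exact"`: all content retained in a growing working volume; total moles
  and hence total integrated heat are conserved, which the suite asserts to
  2% (the residual being incomplete saturation at the end of the default
  protocol).

`fit_isotherm()` fits `(log K_D, ΔH, log n)` per site by Levenberg–
Marquardt (`minpack.lm`), excludes the small pre-injection by default (the
usual practice for a short first injection), orders two-site solutions by
ascending `K_D`, reports delta-method standard errors on the natural
scale, and warns when a c-value `M_t·n/K_D` leaves `[1, 1000]`, where
`K_D` is weakly determined. Stoichiometries are floated by default with a
`fix_n` option, since fixing `n = 1` is only safe when the protein
concentration is accurately known. The default protocol is a 3 µl
pre-injection plus 42 × 6.5 µl of 1.2 mM titrant into 50 µM protein at
25 °C in a 1.43 ml cell.

## Inter-domain geometry

Coordinates are read from PDB or mmCIF with `bio3d`, keeping Cα atoms,
resolving altlocs by highest occupancy and preserving insertion codes.
Superposition is the Kabsch SVD solution constrained to a proper rotation;
`bio3d`'s independent superposition is the test oracle, and a 1000-probe
random-rotation test asserts optimality. Domain selections follow the SlyD
author numbering: FKBP 1–66 + 125–150, IF 70–117, and the FKBP *core*
1–57 + 126–150 used by `core_rmsd()` for cross-construct comparisons
(e.g. full-length vs chaperone-less constructs; with the deposited
M8A-complex entries this is `core_rmsd(read_ca_coords("7oxh.pdb"),
read_ca_coords("7oxg.pdb"))`).

The conformation of the two-domain enzyme is summarized by the distance
`d` between the Cα atoms of residues 99 (IF) and 146 (FKBP) and the angle
`δ` at the residue-19 Cα subtended by residues 145 and 95. Both are
computed on Cα only — the conventional coarse-grained choice for metrics
defined "between residues" — and are invariant under rigid motion of the
model (asserted). Classification into closed / tight / loose / open is
nearest-centroid in z-scored `(d, δ)` space against a labelled reference
table, with queries further than 2 standardized units from every centroid
labelled "intermediate" (the natural label for structures with partially
occupied chaperone sites that sit between groups). Hard rectangular state
boundaries were deliberately avoided: the groups are defined by exemplars,
and a centroid rule with an explicit cutoff degrades gracefully at the
margins. The packaged reference table is a clearly marked synthetic
stand-in shipped for testability; analyses of real deposited entries
should classify against metrics computed from those entries.

`per_residue_peptide_rmsd()` quantifies how conserved each substrate
position is across complexes: all models are superposed on the FKBP
domain, then for each position the Cα distances over all unordered model
pairs are averaged. Positions missing in a model are skipped for that
pair, and a position resolved in fewer than two models is reported `NA`,
never 0.

## Robust correlation statistics

Halfspace (Tukey) depth is computed exactly: the count of cloud points in
a closed halfplane through the query point is piecewise constant as the
halfplane rotates, changing only at directions perpendicular to
query-to-point segments, so evaluating at every critical direction and
every arc midpoint between consecutive critical directions enumerates all
attainable counts (O(n²), exact; an angular brute-force grid is the test
oracle). Points coincident with the query count in every halfplane, and
collinear clouds fall out of the same enumeration.

The bagplot follows the classical construction: the *bag* is the depth
region containing half the points, obtained by radial interpolation about
the Tukey median (centroid of the deepest non-empty depth contour) between
the two consecutive *exact depth contours* — polygons
`{z : depth(z) ≥ k}` computed by halfplane intersection — whose point
counts bracket `n/2`; the fence inflates the bag threefold about the
median. Using the full-plane contours rather than hulls of deep sample
points matters at small n, where ties in sample depth would otherwise make
the bag degenerate. Depth is computed on raw coordinates by default, with
a `standardize` option that z-scores both axes first; the packaged panel
analyses use standardized coordinates because dissociation constants and
activities live on different scales. Flags under standardization are
invariant to affine rescaling of either axis (asserted).

Spearman's ρ uses midranks; p-values come from the exact permutation null
for n ≤ 10 without ties (with a hand-rolled full-enumeration oracle
verifying n ≤ 7 in the tests) and the asymptotic approximation otherwise
— which of the two the published analyses used is not stated, but at the
panel's effect sizes the conclusion is insensitive to the choice.
`correlate_robust()` chains bagplot exclusion, Spearman and an OLS fit
with a pointwise confidence band (95% default; band coverage is verified
by simulation). On the packaged variant panel this workflow flags W4E as
the sole outlier of the affinity–affinity comparison (ρ = 0.98 over the
10 remaining variants) and Y3A for the affinity–activity comparison
(ρ = −0.79 over 8); the summed-enthalpy vs activity comparison uses all 9
complete variants without exclusion (ρ = −0.53, not significant).
Missing ("n.d.") panel entries propagate as `NA` and drop the pair.
PCA (`pca_scores()`) is centred, scaled `prcomp` with each component's
sign fixed so its largest-magnitude loading is positive.

## What the generators emulate — and what they do not

`fixture_config()` pins the generators to the assay conditions: 100 µM
substrate, enzyme at 0/1/2/4/6 µM in technical triplicates, SNR 100,
cis population 0.25 (the panel's true cis fraction is not tabulated; 0.25
is an explicitly arbitrary but typical Xaa-Pro value), Δν = 20 Hz,
r2 = 8 s⁻¹, uncatalysed rate 0.05 s⁻¹, a 2048-point grid from −120 to
260 Hz containing the doublet and a same-area reference singlet, and the
calorimetry protocol above with 0.1 kcal/mol heat noise and the two-site
psWT panel values as truth. Toy structures place rigid scaffold anchors so
that `interdomain_metrics()` returns prescribed `(d, δ)` exactly, with a
15-residue peptide whose positions 5–11 scatter by 0.3 Å and whose
termini scatter by 3 Å, reproducing the qualitative pattern of a
conformationally restrained core around the proline.

The generators produce ideal Lorentzian/Gaussian data: no phase or
baseline distortions, no solvent artefacts, no heat-of-dilution drifts, no
crystallographic disorder. Passing recovery tests therefore demonstrates
the *estimators* are correct and well-conditioned under the stated noise
model — not that real spectra or isotherms are free of systematic error.
Every generator writes a truth manifest, and identical seeds give
bit-identical fixtures without touching the global RNG.

## Problem sizes and runtime choices

The test suite and acceptance script run full pipelines at deliberately
moderate sizes: 2048-point spectra, 15-spectrum titrations, 100 Monte-Carlo
replicates in pipelines (500 as the standalone default), 43-injection
isotherms, 1000-replicate coverage and optimality simulations, and depth
oracles on n = 12 clouds. At these sizes the entire suite completes in
about a minute and the acceptance script in well under one; estimates at
these sizes are already within a few percent of truth, so larger
simulations would add runtime without changing any conclusion.

## Known limitations

* The lineshape model is strictly two-site; a third conformer or
  substantial enzyme-bound population would bias `k_app`.
* The rate search is bounded at 2000 s⁻¹ by default; coalesced lines far
  into fast exchange carry little rate information and hit the flagged
  bound instead.
* The two-site isotherm fit is local optimization; pathological starting
  values can converge to a permuted or degenerate optimum, which the
  ascending-`K_D` ordering and c-value warnings mitigate but cannot
  exclude.
* Exact depth contours are O(n²) halfplane clippings — fast for panels of
  tens of points, not intended for thousands.
* The conformational reference centroids shipped with the package are
  synthetic; state labels for real structures are only as good as the
  reference table supplied.
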