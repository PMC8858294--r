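# prolylkin

Quantitative analysis of peptidyl-prolyl cis–trans isomerase (PPIase)
activity, substrate binding and inter-domain geometry for two-domain
FKBP-type enzymes such as *Thermus thermophilus* SlyD.

SlyD couples a catalytic FKBP (PPIase) domain to an IF ("insert-in-flap")
chaperone domain, each with its own substrate site. Understanding how
peptide residues far from the isomerized proline modulate catalysis
requires connecting three kinds of measurement: label-free NMR activity
assays on long peptide substrates, calorimetric binding thermodynamics of
both sites, and the relative orientation of the two domains in crystal
structures. `prolylkin` implements that full analysis chain as composable,
data-frame-first R functions, plus seeded synthetic-data generators so every
stage is testable without instrument data.

## What it computes

**Exchange lineshapes and activity.** A methyl resonance of a substrate
residue adjacent to the proline reports on the cis/trans isomer: the two
forms give distinct lines whose shape follows the steady-state two-site
Bloch–McConnell equation. For magnetization `M = (M_cis, M_trans)` evolving
under `dM/dt = (iΩ − R + K)M`, the absorption spectrum at frequency ν is

    I(ν) ∝ Re{ 1ᵀ (i2πν·I − iΩ + R − K)⁻¹ p },

with populations `p`, intrinsic relaxation `R` and detailed-balance exchange
rates `k_ct = p_trans·k_ex`, `k_tc = p_cis·k_ex`. Holding populations, line
positions and intrinsic widths fixed from enzyme-free spectra, the single
fitted shape parameter is the apparent exchange rate `k_app`, with
Monte-Carlo uncertainties. Catalysis below `K_M` makes `k_app` linear in
enzyme concentration, so the catalytic efficiency `kcat/KM` is a weighted
regression slope. The Michaelis–Menten limits — binding-equilibrated
(`k_off ≫ k_cat`, efficiency → `k_cat/K_D`, "EX2-like") and
association-limited (`k_cat ≫ k_off`, efficiency → `k_on`, "EX1-like") —
and the diffusion-limited dissociation bound `k_off ≤ k_on·K_D` are provided
as closed forms.

**Calorimetry.** Wiseman isotherms for one or two *independent* binding-site
classes: free-ligand mass balance by bracketed root finding, perfusion-cell
dilution bookkeeping, and Levenberg–Marquardt fitting of
`(n_j, K_D,j, ΔH_j)` with c-value diagnostics.

**Structure geometry.** Kabsch superposition, core and per-residue Cα RMSDs,
and the two scalar coordinates that summarize SlyD's domain arrangement:
the distance `d` (Cα 99–146) and angle `δ` (Cα 145–19–95), with
nearest-centroid classification into closed / tight / loose / open states.

**Robust correlation.** Exact 2-D Tukey halfspace depth, bagplot outlier
identification (depth-contour bag, fence = 3× bag), Spearman rank
correlation with exact small-sample permutation p-values, OLS with
confidence bands, and PCA with a deterministic sign convention.

## Worked example

The packaged substrate-variant panel (`slyd_variant_table()`) carries the
per-variant dissociation constants, binding enthalpies and catalytic
efficiencies of full-length SlyD and the chaperone-less SlyDΔIF construct.
The robust-correlation workflow — bagplot exclusion, then Spearman —
compares the FKBP-site affinities with and without the chaperone domain:

```r
library(prolylkin)
correlate_robust(slyd_variant_table(), "kd_fkbp_um", "kd_dif_um",
                 labels = "variant")
#> <correlation_result> rho = 0.976, p = 0 (exact), n = 10
#>   excluded: W4E
#>   linear fit: slope 2.861 +/- 0.14
```

The bagplot flags W4E as the single bivariate outlier; across the ten
remaining variants the two affinity scales are almost perfectly rank
correlated (ρ = 0.98), and a through-origin fit puts the chaperone-domain
enhancement of FKBP-site affinity at about 3.3-fold.

The same end-to-end machinery runs on synthetic data with known truth — a
full titration (five enzyme concentrations from 0–6 µM, technical
triplicates, SNR 100) simulated at `kcat/KM = 3 µM⁻¹s⁻¹`:

```r
cfg <- fixture_config(seed = 11, kcat_over_km = 3)
gen <- generate_titration_spectra(cfg)
pl  <- titration_pipeline(gen$spectra, gen$truth$enzyme_um,
                          mc_replicates = 100, seed = 12)
pl$activity
#> <activity_fit>
#>   kcat/KM: 3.018 +/- 0.027 uM^-1 s^-1 (weighted fit, n = 15)
#>   uncatalysed intercept k0: 0.0231 +/- 0.048 s^-1
```

The pipeline calibrates the intrinsic linewidth on the non-exchanging
reference methyl, fixes populations and positions from the enzyme-free
spectra, fits each spectrum's apparent exchange rate with Monte-Carlo
errors, and recovers the generating efficiency within ~1%.

A thin CLI wrapping the same functions ships in `inst/exec/prolylkin`
(subcommands `lineshape`, `activity`, `itc`, `stats`, `structure`, `synth`).

## Limitations

Raw FID processing, vendor file parsing, baseline integration of raw ITC
power traces and crystallographic refinement are out of scope; inputs are
processed 1D spectra (two-column text), integrated per-injection heats
(CSV) and refined coordinates (PDB/mmCIF). The packaged conformational
reference centroids are synthetic stand-ins (see
`conformation_references()`); classification of real deposited structures
should use a reference table built from `interdomain_metrics()` on those
entries.
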