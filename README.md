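# tyrcav

Structural post-processing and stability analysis for tyrosinase OCA1
mutants.

Missense mutations in human tyrosinase (Tyr) cause oculocutaneous
albinism type 1. The mild form (OCA1B) tracks structurally with the
expansion of the hydrophobic cavity at the interface between the
EGF-like domain and the catalytic domain; the severe form (OCA1A)
tracks with loss of copper coordination in the binuclear active site.
`tyrcav` implements the analysis layer that sits downstream of
molecular-dynamics simulation and ΔΔG estimation, for structural
bioinformaticians who have PDB frames and mutation tables and want the
geometry, differences and statistics computed reproducibly:

* **Structure I/O** — PDB parsing/writing (alt-loc policy, element
  normalization), atom selection, ordered frame sets, TSV tables.
* **Geometry** — Shrake–Rupley solvent-accessible surface area;
  grid-based solvent-accessible (surface-enclosed) volume.
* **Cavities** — grid detection with probe radius 3.00 Å, interior
  threshold 1.25 Å, minimum depth 5.00 Å; top-3 cavity sum; interface
  cavity identified by lining residues from both domains.
* **Metal sites** — Cu-pair separation, His ND1/NE2 coordination
  counts, loss-of-coordination flags, per-frame tracking.
* **Superposition** — Needleman–Wunsch/BLOSUM-62 residue pairing,
  Kabsch fit, iterative pruning of atom pairs > 2.0 Å.
* **Stability** — the two-state unfolding propensity
  u = 1/(1 + exp(−ΔΔG/RT)) at T = 298 K, severity classes
  (weak 0–0.19, moderate 0.2–0.8, severe 0.81–1), the ΔΔG < 0 → Severe
  labeling rule, per-residue foldability, the identity-mutation
  internal control (every u should be 0.5).
* **Differences and statistics** — ΔΔSA/ΔΔV/ΔΔV_cav between wild type
  and mutants at two timepoints; Pearson r, adjusted R²
  (1 − (1 − R²)(n − 1)/(n − k − 1)) and least-squares regression as a
  small S3 model with the usual methods.
* **Synthetic data** — deterministic generators (hollow shells with
  analytic cavity volumes, drifting two-domain assemblies with metal
  sites, noisy ΔΔG tables) so every stage is testable against
  construction.

## Worked example

Annotate the packaged OCA1B mutation table with unfolding propensities
and predicted effects:

```r
library(tyrcav)
tab <- stability_table(oca1_mutations("oca1b"))
tab[, c("mutation", "ddg", "unfolding", "predicted_effect")]
#>   mutation  ddg unfolding predicted_effect
#> 1     W39R  1.2      0.88           Severe
#> 2     R77G  5.7      1.00           Severe
#> 3    K142M -1.7      0.05           Severe
#> 4    S323R  0.8      0.79         Moderate
#> 5    T325A -0.3      0.38           Severe
#> 6    M370V  4.5      1.00           Severe
#> 7    V393D  4.8      1.00           Severe
#> 8    R402G  2.1      0.97           Severe
```

`unfolding` is the predicted fraction of unfolded protein (W39R at
ΔΔG = 1.2 kcal/mol is 88% unfolded — severe); K142M and T325A have
ΔΔG < 0 and are labeled Severe as stable-but-non-native structures
despite their low unfolded fractions.

Detect the cavity of a synthetic hollow shell and compare with its
analytic volume:

```r
sh <- make_hollow_shell(shell_radius = 12, atom_spacing = 1.5)
sh$analytic_volume
#> [1] 3104.805
detect_cavities(sh$structure)
#> <cavity_set> 1 cavities (probe 3.00, interior 1.25, min depth 5.00, spacing 0.60 A)
#>   3150.1 A^3, depth 14.6 A
```

Fit the ΔΔG-vs-cavity trend on a synthetic table generated in the
regime of the published regression (slope 749.1 Å³ per kcal/mol,
intercept 423.0 Å³, noise at the r ≈ 0.8 level):

```r
tr <- ddg_trend(dd_vcav ~ ddg,
                make_ddg_table(n_mutants = 8, noise_sd = 1300, seed = 42))
tr
#> <ddg_trend> dd_vcav ~ ddg (n = 8)
#>   Pearson r = 0.903, R^2 = 0.816, adjusted R^2 = 0.785
#>   dd_vcav = 1013.201 x ddg + 810.661
```

(With `noise_sd = 0` the generator's coefficients are recovered
exactly; at n = 8 a single noisy draw scatters widely, which is why the
tests average recovery over hundreds of seeds.)

The end-to-end demonstration couples the packaged ΔΔG table to
synthetic two-domain assemblies whose interface pocket drifts open in
proportion to ΔΔG, then emits the annotated results table and the
correlation report:

```r
res <- run_oca1_pipeline(seed = 1, out_dir = "out")   # results.tsv, correlation.tsv
```

A thin command-line front end over the same functions ships as
`inst/exec/tyrcav` (subcommands `sasa`, `volume`, `cavities`, `metals`,
`superpose`, `stability`, `correlate`, `run`).

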