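---
title: "Methods: structural post-processing for tyrosinase OCA1 analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural post-processing for tyrosinase OCA1 analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tyrcav)
```

## The scientific setting

Human tyrosinase (Tyr) catalyzes the rate-limiting step of melanin
synthesis; missense mutations in its gene cause oculocutaneous albinism
type 1 (OCA1). Two structural storylines distinguish the mild form
(OCA1B, residual activity) from the severe form (OCA1A, complete loss):

* **OCA1B** — mutations act allosterically: the EGF-like domain drifts
  away from the catalytic domain, and the hydrophobic cavity at their
  interface expands. The expansion (measured as a cavity-volume change)
  correlates with the folding free-energy change ΔΔG of the mutation.
* **OCA1A** — active-site histidine mutations compromise coordination of
  the binuclear copper pair; without the bridging dioxygen, one copper
  loses its grip and the site destabilizes.

This package implements the *post-processing* layer of that analysis.
Molecular-dynamics simulation, homology modelling and ΔΔG estimation are
upstream of it: structures arrive as PDB frames, ΔΔG values arrive in
tables, and everything downstream — geometry, differences, statistics —
is computed here, reproducibly and with testable semantics.

## The two-state unfolding propensity

A mutation's ΔΔG (kcal/mol, positive = destabilizing) is mapped to the
fraction of protein in the unfolded state under a two-state
(folded/unfolded) Boltzmann model:

$$u = \frac{1}{1 + e^{-\Delta\Delta G / RT}},
\qquad R = 1.9872\times10^{-3}\ \mathrm{kcal\,mol^{-1}K^{-1}},\ T = 298\ \mathrm{K}.$$

Properties that the tests assert: $u(0) = 0.5$ exactly (an identity
mutation is energetically neutral, so the two states are equally
populated), $u$ is strictly increasing in ΔΔG, and $u(-x) = 1 - u(x)$.
Before adopting this functional form we verified that it reproduces the
published (ΔΔG, unfolding) pairs for all 19 tabulated tyrosinase
mutants to ±0.01 after rounding to two decimals — comfortably above the
15-of-19 gate we set for accepting the conversion.

Severity binning follows the published convention — weak (0–0.19),
moderate (0.2–0.8), severe (0.81–1). The printed bins leave gaps
(0.19–0.20, 0.80–0.81); we close them by rounding $u$ to two decimals
before binning, which is also how the published values are printed. The
*predicted effect* label adds one rule: mutations with ΔΔG < 0 are
labeled Severe regardless of $u$, on the reasoning that an
over-stabilized structure is non-native and still pathogenic.

Per-residue **foldability** sums severity-weighted propensities over the
substitutions at one residue. The severity weights are not published
anywhere we could verify, so the default {weak 0, moderate 0.5,
severe 1} is an explicit, configurable choice: it makes weak
substitutions contribute nothing, which is consistent with a residue
whose substitutions are all weak scoring 0. Downstream outputs never
hard-code these weights.

The **internal control** converts identity-mutation ΔΔG values (each
residue "mutated" to itself) and checks the resulting propensities
against their theoretical value of 0.5, reporting mean, sample SD,
t-based 95% CI and a two-sided one-sample t-test. A degenerate all-equal
sample (SD 0) is reported with a collapsed CI and p = 1 when the mean is
exactly 0.5.

Temperature is configurable; 298 K is the default because it is the
simulation temperature of the upstream MD protocol. The OCA1A/OCA1B pH
difference in that protocol plays no role in the conversion, which is
temperature-only.

## Surface area and accessible volume

SASA uses the Shrake–Rupley construction: `n_sphere_points` (default
960) quasi-uniform points on each atom's expanded sphere
(r_vdw + probe, probe default 1.4 Å — a water); a point is exposed if
outside every other atom's expanded sphere. Sphere points come from a
golden-spiral lattice — a deterministic construction with no RNG, so
areas are bit-reproducible. Tests assert the closed form for isolated
spheres, zero area for a fully enclosed atom, monotone occlusion (adding
an atom never increases any per-atom area), and < 2% change from 960 to
4000 points.

Solvent-accessible volume is the volume enclosed by the
solvent-accessible surface, computed on a grid (default spacing 0.5 Å):
voxels within r_vdw + probe of any atom, plus interior voxels
unreachable by a 6-connected flood fill from the grid boundary. We read
"solvent-accessible volume" as surface-enclosed volume (interior voids
included) rather than the bare union of expanded spheres; the tests
check the enclosed volume of a hollow shell strictly exceeds an
independently computed union-of-spheres volume.

The upstream tooling that originally produced these metrics does not
document its algorithms; Shrake–Rupley and grid flood-fill were chosen
as transparent, oracle-testable equivalents. Absolute values therefore
differ from that tooling's, but every downstream statistic consumes
*differences* (ΔΔ), which is also how the published analysis uses them.

Both computations exclude hydrogens and water (HOH) by default and
include metals. The heavy-atom convention exists because MD exports may
or may not carry hydrogens, and results must not depend on that. The
van-der-Waals radii are pinned in code (C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20, Cu 1.40, P 1.80, default 1.70 Å) so all geometry is reproducible
from source.

## Cavity detection

Interior cavities are detected on a voxel grid (default spacing 0.6 Å)
with three parameters whose defaults follow the published analysis:
probe radius 3.00 Å, interior threshold 1.25 Å, minimum depth 5.00 Å.
Their semantics here:

* **clearance** of a voxel = distance to the nearest atom center minus
  that atom's vdW radius;
* **exterior** space is grown in two stages: a 6-connected flood fill
  from the grid boundary over voxels with clearance ≥ probe radius
  (where bulk solvent fits), then expansion over connected voxels with
  clearance ≥ interior threshold reachable from that set (narrower
  clefts that open into bulk solvent);
* **cavities** are the connected components of free interior voxels
  (clearance ≥ interior threshold) not in the exterior; volume = voxel
  count × spacing³;
* **depth** of a cavity = the largest Euclidean distance from one of its
  voxels to the nearest exterior voxel (computed by an exact distance
  transform); components shallower than the minimum depth are surface
  dimples and are discarded;
* **lining residues** are residues owning an atom within
  r_vdw + interior threshold + spacing of a cavity voxel.

The reference cavity tool this emulates is built on Voronoi-diagram
channel extraction, and its "interior threshold" is a facet-radius
criterion that has no exact grid counterpart; the published description
provides only the three scalar parameters, so a grid re-implementation
honoring their meaning was adopted — transparent and testable against
analytic fixtures, at the cost of absolute volumes that differ from the
reference tool's. As with SASA, the pipeline's claims are about
relative/difference quantities. Likewise its "minimum depth" may be a
tunnel length; distance-to-exterior of the deepest voxel is the closest
well-defined grid analogue. Six-connectivity is used for all flood
fills to prevent diagonal leakage through one-voxel walls.

The headline summary is the sum of the three largest cavities
(`total_cavity_volume`, top_n = 3), the published approximation of total
interior cavity volume. The EGF–Tyr interface cavity is identified as
the largest cavity whose lining residues intersect both the EGF-like
domain (default residue window 19–118 — the first hundred residues of
the mature intra-melanosomal domain, which starts at residue 19) and the
rest of the protein; the aromatic lining residues of that pocket
(F98, F105, F176, W210, F429, Y433, F438) ship as a named selection.

Tests verify: a dense cluster has no cavities; a hollow atom shell of
radius $\rho$ yields one cavity within 10% of the analytic interior
volume $\tfrac43\pi(\rho - r_{vdW} - t)^3$; two nested problems order
correctly; halving the spacing moves volumes by < 10%; and opening a
mouth wider than the probe diameter converts the interior to exterior.
The mouth case exercises the two-stage exterior rule: a mouth of
aperture 8 Å has a central clearance of about 2.3 Å — too narrow for the
3 Å probe stage but wide enough for the 1.25 Å expansion stage, so the
interior correctly drains to the exterior.

## Metal-site geometry

The tyrosinase active site holds two coppers 2.7–2.8 Å apart,
coordinated by six histidines (three per copper) through their
side-chain nitrogens. `metal_pair_distance` demands exactly two atoms of
the element; `coordination_count` counts His ND1/NE2 atoms within a
cutoff of the metal. The cutoff default of 3.0 Å is ours (typical Cu–N
bonds run 1.9–2.2 Å; the slack absorbs thermal distortion); it is
configurable. A metal with ≤ 1 coordinating atom is flagged as having
lost coordination — mirroring the observation that a copper held by only
two histidines (one lost to mutation) escapes the site once dioxygen is
absent; the threshold is configurable. Frame sets propagate these
measurements over explicit time labels; nothing maps labels to
simulation internals.

## Superposition and pruned RMSD

Residues are paired by Needleman–Wunsch global alignment under BLOSUM-62
with affine gaps. The published comparison protocol does not state gap
penalties; open −11 / extend −1 is the common BLOSUM-62 default and is
configurable. Unknown residues (X) are tolerated and scored 0. The
rigid fit is the Kabsch least-squares rotation (SVD with reflection
correction), computed on the CA atoms of paired residues — the standard
backbone convention; the protocol says "atom pairs" without specifying.
Iterative pruning then repeats {fit; drop all pairs with post-fit
distance > 2.0 Å} until no pair exceeds the cutoff, matching the quoted
stopping rule; dropping one pair at a time is available as an option.
If pruning would leave fewer than 3 pairs, the last valid fit is kept
and flagged. Both the pruned RMSD (retained pairs) and the all-pair
RMSD under the final transform are reported, and rmsd_pruned ≤ rmsd_all
always. The published RMSD values themselves are not reproduction
targets: they require the unpublished MD endpoint structures.

## Difference statistics and correlation

For each metric M (SASA, accessible volume, top-3 cavity sum, interface
cavity): ΔM = M(t₁) − M(t₀) within a structure, and
ΔΔM = ΔM_mut − ΔM_wt against the wild type. The table builder validates
that every structure is present at the same two explicit timepoints —
timepoints are labels, never assumed to be 0/100 ns.

Pearson's r, the adjusted R² ($1-(1-R^2)(n-1)/(n-k-1)$, k = 1
regressor throughout) and the least-squares line are implemented from
the formulas as printed, with one correction: the printed Pearson
denominator carries a "+" where the product-moment formula requires a
"−"; we implement the mathematically correct sign (the correct formula
is also the one consistent with the published adjusted-R² values). Base
R's `cor()` and `lm()` serve as independent cross-checks in the tests,
not as the implementation. The fitted trend is exposed as a small S3
model (`ddg_trend`) with print/summary/coef/predict/plot/residuals
methods.

## Synthetic data: what it emulates, and what it does not

All structural fixtures are generated, with ground truth attached:

* **Hollow shells** (`make_hollow_shell`): golden-spiral carbon lattices
  on a sphere, sealed at spacing 1.5 Å, standing in for a protein
  interior with a cavity of analytically known volume. An aperture
  parameter opens a mouth of given chord diameter.
* **Two-domain assemblies** (`make_two_domain_trajectory`): a shell
  split at a plane into two chains; rigid drift of one chain across
  frames widens the sealed interface pocket monotonically
  (sphere-plus-slab analytic estimate as ground truth), emulating the
  EGF-like domain moving away from the catalytic domain. An optional
  binuclear Cu site with His-like N ligands rides along. Drifts stay
  below the ~4.5 Å ring-gap width at which the pocket would drain, so
  the pocket stays a cavity throughout.
* **ΔΔG tables** (`make_ddg_table`): ΔΔG uniform over a configurable
  range (default −2 to 6 kcal/mol, the span of the published OCA1B
  values), response = slope·ΔΔG + intercept + Gaussian noise, defaults
  set to the published regression (749.1 Å³ per kcal/mol, 423.0 Å³).
  Noise sits on the structural response only: ΔΔG values are treated as
  exact energy-model outputs, cavity volumes as noisy measurements.

Everything is deterministic per seed (the shells involve no RNG at
all). These fixtures validate the *machinery* — parsers, grids,
statistics — against construction. They are not protein decoys: they
have no secondary structure, no side chains, no force field, and their
cavity walls are idealized single-atom lattices. Passing tests
establish that the pipeline measures what it claims to measure, not
that any particular biological value is reproduced; the published
absolute cavity volumes and RMSDs depend on unpublished MD endpoint
structures and are out of reach by design.

The demonstration pipeline (`run_oca1_pipeline`) couples the packaged
OCA1B ΔΔG table to synthetic assemblies whose drift is proportional to
ΔΔG (0.4 Å per kcal/mol, clamped to [−0.8, 2.4] Å), then runs the full
measurement → difference → annotation → correlation chain. Its near-unit
correlation is a property of that coupling, not a biological claim; its
purpose is an end-to-end, deterministic exercise of every module.

## Numerical choices and problem sizes

* Grid clearance values are capped at the probe radius (larger values
  are never compared), letting each atom update only a local
  neighborhood; cavity depth uses an exact Euclidean distance transform
  (Felzenszwalb–Huttenlocher) with a large finite sentinel for empty
  scanlines.
* Severity bins are applied to $u$ rounded to 2 decimals (see above);
  `round()`'s behavior at representation boundaries (e.g. 0.805 storing
  as slightly less) is accepted as-is.
* Alt-loc resolution keeps the highest-occupancy conformer, ties broken
  by file order — a deterministic single-conformer policy.
* Kabsch sign-corrects the SVD reflection case; degenerate (collinear)
  inputs are flagged.
* Test and demonstration problem sizes — shells of radius 8–12 Å
  (~300–930 atoms), grids of 0.3–1.0 Å spacing, assemblies of ~750
  atoms over 2–4 frames — were chosen so the whole suite exercises every
  code path, including a grid-refinement convergence check, at
  interactive runtimes.

## Known limitations

* Absolute SASA/volume/cavity values differ from the closed-source
  tools used upstream in the original analysis; only differences are
  comparable.
* Cavity "depth" is distance-to-exterior, not tunnel length; the
  facet-radius semantics of the reference tool's interior threshold
  cannot be mirrored exactly on a grid.
* mmCIF, compressed trajectory formats and NMR multi-model semantics
  are out of scope; frame sets are ordered PDB structures with explicit
  time labels.
* The foldability weights and the alignment gap penalties are
  field-standard defaults, not published values; both are configurable
  and recorded in every output that depends on them.
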