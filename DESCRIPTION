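Package: tyrcav
Title: Structural Post-Processing and Stability Analysis for Tyrosinase OCA1 Mutants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural post-processing and statistical analysis
    used to characterize oculocutaneous albinism type 1 (OCA1) mutations of
    human tyrosinase: PDB structure and frame-set handling, Shrake-Rupley
    solvent-accessible surface area, grid-based solvent-accessible volume and
    interior-cavity detection with probe/interior-threshold/minimum-depth
    semantics, binuclear copper-site geometry tracking, Kabsch superposition
    with iterative 2.0 Angstrom pruning, conversion of folding free-energy
    changes to two-state unfolding propensities with severity classification,
    paired wild-type/mutant difference metrics, and the Pearson and adjusted
    R-squared correlation analysis linking interface-cavity expansion to
    mutation severity. Includes deterministic synthetic-structure generators
    (hollow shells with analytically known cavity volumes, drifting two-domain
    assemblies, metal sites, noisy regression tables) so every stage is
    testable against construction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
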