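Package: confshape
Title: Shape Analysis of Disordered Protein Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the conformational ensembles of
    intrinsically disordered peptides by molecular shape. Computes the 13
    WHIM (Weighted Holistic Invariant Molecular) descriptors of each
    conformation from backbone principal-component eigenvalues, total
    solvent-accessible surface area by the Shrake-Rupley method, and
    per-residue secondary structure by Kabsch-Sander hydrogen-bond rules.
    Descriptor distributions are deconvoluted into the minimum number of
    Gaussian components reaching a target R-squared; free-energy landscapes
    over any two collective variables are built from ensemble occupancy,
    with minima detection, minimal-gradient pathways between basins, and
    basin-representative extraction by GROMOS conformational clustering.
    Includes essential-dynamics and autoscaled-descriptor PCA spaces,
    optimal Kabsch superposition and RMSD filtering against a reference
    structure, and a deterministic synthetic-ensemble generator mixing
    compact and extended chain conformations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
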