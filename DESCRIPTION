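Package: refine3d
Title: Iterative Protein Structure Refinement and Model Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An iterative protocol for all-atom protein structure refinement:
    hydrogen-bond network optimization by discrete conformational search
    followed by L-BFGS energy minimization under a composite physics- and
    knowledge-based force field (bonded terms, Calpha/Cbeta tethering, a
    pairwise potential of mean force, and an explicit hydrogen-bonding
    potential), repeated over five rounds. Also implements a model quality
    assessment framework with six metrics (GDT-TS, RMSD, GDC-SC, a
    MolProbity-style proxy, SphereGrinder, CAD-AA), robust Z-score
    normalization with a weighted overall quality score, group ranking
    against a do-nothing control, and Wilcoxon signed-rank comparisons.
    A synthetic decoy generator makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
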