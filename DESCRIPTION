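Package: ensflex
Title: Superposition-Independent Analysis of Protein Structural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compares ensembles of protein structures (crystal forms, NMR
    models, MD snapshots) without any global superposition, using per-residue
    differential-geometry descriptors of the C-alpha trace (curvature and
    torsion of the osculating helix), side-chain sentinel-atom coordinates in
    a local backbone frame, and phi/psi circular order parameters. Provides
    grouped-variance statistics that separate thermal noise from significant
    conformational change (hinge and loop-flip detection), masked descriptor
    matrices over a multiple sequence alignment, gap-free submatrix selection,
    NIPALS principal component analysis, correlated conformational-change
    discovery, distinct druggable-pocket selection from per-residue
    druggability scores, per-residue interaction fingerprints, hierarchical
    clustering with Newick export, and writers for Jalview features and
    molecular-graphics attribute scripts. A seeded synthetic-ensemble
    generator with planted hinges, loop flips, rotamer switches and disorder
    makes every statistic testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ape,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
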