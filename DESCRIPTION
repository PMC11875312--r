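Package: ConformerSelect
Title: Conformer Ensemble Selection Against NMR Chemical Shift and NOESY Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores candidate protein conformer ensembles against solution NMR
    data and assembles single- or multi-state structural models. Computes the
    random coil index (RCI) and RCI-derived fluctuation estimates from chemical
    shifts, matches 3D NOESY peak lists to assigned proton pairs to obtain
    recall/precision/F scores, combines NOESY recall and pLDDT-RCI concordance
    into a Bayesian per-model selection metric weighted by pTM, clusters
    conformers by principal components of Calpha-Calpha distance matrices,
    greedily combines cluster-derived candidate states to maximise concordance
    (Lin's CCC) between ensemble and shift-derived fluctuations, and
    cross-validates states by NOESY Double Recall. Includes a seeded synthetic
    two-state fixture generator so the full pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
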