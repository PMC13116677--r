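Package: vstriage
Title: Virtual-Screening Triage and Enrichment Analysis for Ensemble Docking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision machinery for structure-based virtual screening
    campaigns against an ensemble of receptor conformers, built around a
    kinase-inhibitor discovery workflow. Implements ROC/AUC and
    early-enrichment LogAUC metrics with conformer ranking and selection,
    benchmark active-set curation and property-matched decoy selection,
    ECFP4/Tanimoto novelty filtering, leader clustering, polar-contact
    geometry triage of docked poses (key-residue contacts, unsatisfied
    donor/acceptor detection, docking-grid specification), and enzyme-assay
    quantification (Michaelis-Menten, dose-response IC50 fitting, and
    Cheng-Prusoff conversion to Ki). Seeded synthetic-data generators with
    emitted ground truth stand in for commercial docking engines and wet-lab
    instruments so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    minpack.lm,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
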