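Package: evscreen
Title: Ensemble Virtual Screening with Pharmacophore Filtering and
    Naive Bayes Consensus Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for structure-ensemble virtual screening against a
    single protein target. Clusters crystal-structure ensembles by
    C-alpha RMSD with silhouette-guided selection of the cluster number
    and medoid representatives; represents and fits 3D pharmacophore
    models with a Catalyst-style geometric FitValue and a fixed fail
    sentinel; assembles property-matched active/decoy benchmarks with
    stratified train/test splits and descriptor-space PCA; evaluates
    docking poses (symmetry-corrected RMSD, top-scored versus best pose,
    2 Angstrom success rule) and docking scores (Mann-Whitney U,
    ROC/AUC); and fuses scores from several receptor conformations in a
    binned naive Bayes consensus classifier with cross-validated AUC.
    Synthetic generators for toy ensembles, ligand libraries, and score
    tables make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    ChemmineR,
    bio3d,
    igraph,
    cluster,
    jsonlite,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
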