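Package: phd2screen
Title: Consensus Impact Classification and Surface Mapping of PHD2 Missense Variants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for assessing missense variants of the human
    oxygen sensor PHD2 (EGLN1) from heterogeneous in silico evidence.
    Normalizes the outputs of eight stability/pathogenicity predictors into
    deleterious votes, combines them with sequence conservation and
    structural annotations in a four-tier consensus classifier, grades
    conservation from multiple sequence alignments on a ConSurf-style 1-9
    scale, and provides a structural layer: Shrake-Rupley solvent accessible
    surface area, typed residue interaction networks and their diffs,
    substrate-interface extraction, neighbor analysis against an annotated
    residue catalog, and single-linkage clustering of exposed surface
    patches. Ships a published PHD2 polycythemia variant panel and evidence
    table as worked examples, plus seed-deterministic generators for
    synthetic structures, alignments and predictor tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
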