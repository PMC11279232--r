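Package: colonyscreen
Title: High-Throughput Colony-Array Screening of Microbial Growth,
    Pairwise Interactions, and Antifungal Activity
Version: 0.1.0
Authors@R:
    person("Colonyscreen", "Developers", email = "colonyscreen@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for robotic colony-array screens of microbial
    isolates. Reads IRIS-style colony quantification tables (spot size and
    opacity per timepoint), models log2 biomass growth with a three-parameter
    Gompertz curve, screens fits by per-parameter significance, and summarizes
    growth as integrated fitness (area under the curve up to 72 h) with robust
    per-plate centering. Pairwise co-culture outcomes are classified
    ecologically (cooperation, competition, neutral) against a replicate-noise
    scale (median standard deviation, MSD) and functionally (induction,
    suppression, neutral) from qualitative inhibition-halo scores in
    spot-on-lawn antifungal assays. Includes contingency-table statistics
    (G-test, Fisher exact), summary report tables, and a ground-truth
    synthetic plate-experiment generator so the whole pipeline can be
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
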