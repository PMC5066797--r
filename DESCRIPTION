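Package: mirdegnet
Title: Integrated Small RNA, Degradome and Coexpression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for plant microRNA regulatory circuits
    built around a time-course stress experiment: small-RNA tag cataloguing
    with reference matching and end-shift/substitution variant nomenclature,
    hairpin precursor excision and thermodynamic validation (MFE, AMFE,
    MFEI), degradome (PARE)-guided target calling with complementarity
    scoring and category 0-4 cleavage-signature classification, exact-test
    differential expression with FDR control, miRNA-target anti-correlation
    integration with term enrichment, and soft-threshold coexpression
    networks (power-6 adjacency, topological overlap, module eigengenes,
    hub subnetworks). A synthetic-data generator plants ground-truth
    miRNAs, cleavage sites, expression trajectories and correlation blocks
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
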