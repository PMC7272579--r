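Package: tippingnet
Title: Early-Warning Signals of Cancer Critical Transitions from
    Patient-Specific Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects early-warning signals of critical transitions in tumor
    progression from paired tumor/tumor-adjacent expression profiles, somatic
    mutation catalogs and a protein-protein interaction network. Builds
    patient-specific networks, propagates mutation effects by random walk with
    restart, assembles mutant giant clusters, infers per-patient and
    per-subtype somatic mutation orders with a greedy minimal-growth rule,
    scores candidate dominant groups with the dynamic-network-biomarker
    criticality index to locate each patient's transition point, validates
    transition order against clinical stage, performs hypergeometric gene-set
    enrichment of giant clusters, and mines pathway-based candidate drug
    targets. Ships a synthetic-cohort generator with planted ground truth so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    igraph,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
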