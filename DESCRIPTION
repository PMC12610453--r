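Package: mirpanel
Title: Differential Expression, Power and Target Analysis for qPCR miRNA Panels
Version: 0.1.0
Authors@R: person("Panel", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for 96-assay qPCR miRNA panels: delta-Ct
    normalization against housekeeping references, delta-delta-Ct fold
    regulation with Welch two-sample inference and Benjamini-Hochberg
    adjustment, post hoc power analysis via minimal detectable effect sizes
    under Bonferroni and BH-effective alpha policies, validated miRNA-target
    convergence counting with hypergeometric over-representation, and
    cross-platform sign-concordance against an external sequencing-derived
    differential expression table. Includes a synthetic Ct-panel generator
    emulating the statistical structure the inference assumes, so every stage
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
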