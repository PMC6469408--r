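Package: hmsprot
Title: Expression Misregulation and cis-Regulatory Hotspot Analysis for
    Hybrid Male Sterility Candidate Proteases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to narrow a panel of Drosophila pseudoobscura male
    reproductive tract proteases to hybrid male sterility (HMS) candidates
    and to test their upstream regions for clustering of fixed interspecies
    substitutions.  Covers qRT-PCR relative expression (delta-Cq against dual
    reference genes) with per-gene ANOVA, Scheffe post-hoc comparisons,
    Benjamini-Hochberg q-values and compact letter displays; genetic
    exclusion logic over backcross and introgression progeny; testes versus
    accessory-gland enrichment calls; TSS-relative mapping of fixed
    substitutions from aligned interspecies sequence pairs with a shared
    polymorphism filter; and an empirical-CDF clustering statistic (G,
    delta-G, T) with Monte Carlo and exact-enumeration null distributions.
    A synthetic-data generator reproduces the statistical structure of each
    input so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
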