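Package: domssr
Title: Diversity Analysis of Dominant SSR Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing dominantly scored SSR (microsatellite)
    band-presence data from germplasm panels. Computes per-primer
    informativeness indices (PIC, multiplex ratios, marker index,
    resolving power, profile discrimination), within-group gene
    diversity, private-allele accounting across predefined groups,
    Jaccard-complement dissimilarities with group summaries,
    one-level AMOVA with a permutation test of Phi-ST,
    neighbor-joining trees with marker-bootstrap support, principal
    coordinate analysis, a bootstrap marker-sufficiency procedure,
    and Evanno delta-K model selection from clustering-run
    likelihood tables. Ships a configurable synthetic-panel
    generator with known group structure so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
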