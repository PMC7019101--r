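Package: varhotspot
Title: Consensus Prioritization and Sequence Hotspot Detection for Rare
    Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing rare missense variants from
    multi-database annotation tables and locating mutation hotspots along a
    protein sequence. Variants annotated with six deleteriousness metrics
    (PolyPhen-2, Grantham, PROVEAN, SIFT, PhastCons, GERP) are filtered by
    configurable consensus rules and benchmarked against minor allele
    frequencies of known pathogenic alleles. Positional clusters of
    prioritized variants are tested against a bootstrap null of uniform
    placement with Benjamini-Hochberg correction, summed into a per-residue
    hotspot track, and mapped onto protein subdomain intervals with an exact
    binomial enrichment test. Protein-protein interaction edge lists can be
    merged and profiled for hub structure (betweenness, closeness,
    neighborhood-connectivity disassortativity). A synthetic-data module
    generates annotation tables and hub-containing graphs with known truth,
    and a packaged table of 24 rare NUP155 missense variants supports a
    worked reproduction of a published prioritization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
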