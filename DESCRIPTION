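Package: bgcsurvey
Title: Comparative Survey of Antimicrobial Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects homologs of reference antimicrobial biosynthetic gene
    clusters (BGCs) in bacterial genome assemblies with completeness, synteny
    and identity filters; localizes clusters by published restriction-site
    patterns; profiles conservation of 5-kb flanking regions including mobile
    genetic elements and frameshift-interrupted genes; screens for horizontal
    gene transfer by %GC anomaly; and quantifies congruence between gene
    cluster trees and cpn60 marker species trees. Ships a synthetic
    strain-panel generator with ground truth so the whole pipeline is
    testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
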