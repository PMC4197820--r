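Package: mirededit
Title: Detection, Conservation Analysis and Quantification of A-to-I miRNA Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for site-specific adenosine-to-inosine
    (A-to-I) microRNA editing analysis from small-RNA sequencing reads:
    quality filtering, mismatch-tolerant short-read alignment with
    unique-best-stratum semantics and a 3' trim retry, per-site mismatch
    tallying with a battery of candidate-site filters, cross-species
    conservation calling over miRNA family alignments, remapping-based
    editing-frequency estimation with a fake-editing control, and the
    downstream statistics for tissue, age and matched tumor/normal
    comparisons. A synthetic small-RNA data generator with truth tables
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
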