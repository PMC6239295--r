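Package: tpsminer
Title: Genome-Wide Mining and Classification of Terpene Synthase Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering and classifying plant terpene
    synthase (TPS) gene families from genome assemblies. Candidate genes are
    screened with position-specific scoring profiles for the N- and C-terminal
    TPS domains (or imported HMMER3 per-domain tables), spliced and translated
    from gene models, and triaged into putatively functional, partial, and
    probable pseudogene categories. Proteins are profiled for the five
    canonical degenerate TPS motifs (RR(X)8W, RXR, DDXXD, DXDD, NSE/DTE),
    gene models are classed by intron-exon architecture, and subfamilies
    (TPS-a through TPS-g) are assigned by neighbor-joining phylogeny with
    p-distances, pairwise deletion, and bootstrap support against a labeled
    reference panel. A synthetic-genome generator with ground-truth tables
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
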