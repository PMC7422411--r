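Package: nlrforge
Title: Annotation and Comparative Analysis of Plant NLR Immune Receptor Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies NB-ARC (PF00931) encoding genes from protein domain
    annotations, classifies NLR architectures (CNL, TNL, RNL and relatives),
    detects physical gene clusters formed by tandem duplication, extracts and
    profiles integrated domains (NLR-ID fusions), assesses integrated-domain
    homology across comparator proteomes including polyploid
    progenitor-subgenome assignment, and compares alternative transcripts for
    integrated-domain exclusion, truncation and intron retention. Includes an
    affine-gap pairwise aligner, neighbor-joining tree construction with
    bootstrap supports, and a synthetic genome/proteome generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    jsonlite,
    yaml,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
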