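Package: srnapipe
Title: Small RNA Sequencing Analysis of Differential miRNA Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-library small RNA sequencing pipeline for contrasting
    miRNA expression between paired cell lines, as used to compare a
    doxorubicin-resistant hepatocellular carcinoma line against its parent.
    Covers adapter trimming and read cleaning, collapsing reads to unique
    tags, exact genome mapping, priority-rule annotation against ncRNA,
    miRNA, repeat, exon and intron feature sets, quantification of known
    mature miRNAs in transcripts per million, prediction of novel miRNA
    hairpins by minimum-free-energy folding with Dicer-cleavage read-stack
    checks, an exact two-library conditional binomial test with
    Benjamini-Hochberg correction, consensus seed-match target prediction,
    and hypergeometric term enrichment. A synthetic-data generator with a
    known ground truth makes every stage testable without real sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
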