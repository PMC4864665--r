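Package: halocline
Title: Paired-End Amplicon OTU Inference and Diversity Trends Along
    Salinity Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A metabarcoding analysis toolkit for surveys of microbial
    communities along environmental gradients. Implements paired-read
    preparation (primer and quality trimming, overlap merging or
    concatenation), two-pass greedy OTU clustering at a configurable
    identity threshold, a paired consensus taxonomy classifier with
    rank-specific identity cutoffs and bit-score top-set selection, an
    in-silico holdout experiment for calibrating those cutoffs,
    beta-diversity ordination and Mantel statistics, seeded rarefaction
    alpha-diversity, and a label-shuffling test linking chloroplast 16S
    OTUs to their nuclear 18S counterparts. A synthetic-data module
    generates rank-structured reference databases, gradient-structured
    communities with linked plastid/nuclear markers, and Phred-modelled
    paired reads, so the whole pipeline can be exercised end to end
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    Biostrings,
    ape,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
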