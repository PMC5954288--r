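Package: phasr
Title: Discovery of miRNAs, Phased siRNAs and Their Targets from Plant
    Small RNA Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for plant small RNA analysis:
    quality filtering, adapter trimming and collapsing of small RNA and
    degradome (PARE) libraries; mismatch-tolerant mapping of short tags to
    genomes and transcripts; homology- and hairpin-based annotation of
    conserved and novel microRNAs with miRNA* duplex evidence; detection of
    21- and 24-nt PHAS loci with a hypergeometric phasing P-value and a
    phase score over sliding genomic windows, including strand-offset phase
    registration, window merging, false discovery rate control and phasiRNA
    extraction; TAS3 locus identification via dual miR390 complementary
    sites; degradome-supported target validation with valid-read counting
    and T-plot export; and reads-per-ten-million expression summaries with
    correlation clustering and principal component analysis. A synthetic
    data generator produces toy genomes, planted hairpins, phased siRNA
    ladders and degradome libraries so that every stage can be exercised
    and calibrated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
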