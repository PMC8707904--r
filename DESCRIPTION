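Package: tnscout
Title: Transposon Insertion-Site Mapping from Whole-Genome Resequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes Tn5 transposon insertion sites in bacterial genomes from
    paired-end whole-genome resequencing reads. Reads are classified against the
    wild-type reference with a k-mer seed-and-verify mapper; unmapped reads that
    carry transposon sequence are extracted and assembled into unitigs with a
    canonical-k-mer De Bruijn graph; junction contigs are recognized by adjacent
    local-alignment hits to the reference genome and to the transposon cassette
    ("double hits"), converted into target-site-duplication-aware insertion
    coordinates, and annotated with the disrupted gene. A seeded simulator of
    mutant genomes and Illumina-style paired-end libraries makes the whole
    pipeline verifiable by exact recovery of known insertion positions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
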