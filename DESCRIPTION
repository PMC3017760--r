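Package: ssrscape
Title: Genome-Wide Simple Sequence Repeat Cataloguing and Read-Based
    Heterozygosity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects perfect simple sequence repeats (SSRs) in genome
    assemblies with a greedy maximal-array scanner (motif sizes 1-100,
    smallest-motif reduction), genotypes each locus from shotgun read
    alignments for repeat-unit heterozygosity, multistep variation and
    non-repeat unit polymorphisms (NRUPs) under conservative coverage and
    read-support filters, and provides the statistical layer used in
    genome-wide SSR surveys: starting-nucleotide preference tests,
    end-versus-middle interruption expectations, heterozygosity curve
    fits, scaffold abundance flags and recombination-density regressions.
    Includes a diploid genome and shotgun-read simulator with planted SSR
    loci and truth alignments so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
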