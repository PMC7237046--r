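Package: foldbind
Title: Structure-Mediated Effects of Single-Nucleotide Variants on RNA-Protein Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how single-nucleotide variants alter the binding of
    single-stranded-RNA-binding proteins (such as HuR/ELAVL1) through changes
    in RNA secondary structure. Implements a Boltzmann-ensemble partition
    function over canonical secondary structures with hard unpaired
    constraints, footprint opening free energies, a structure-aware effective
    dissociation constant built from k-mer affinity tables, a random-sequence
    scan of substitution effects versus footprint position, and a
    SNP-to-binding-site pipeline with distance and binomial asymmetry
    statistics. Includes an exhaustive enumeration oracle for small RNAs and
    seeded generators for synthetic transcripts, binding-site cohorts and
    affinity tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
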