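Package: g4telo
Title: Strand-Aware G-Quadruplex Motif Analysis for Telomeric Retrotransposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and scoring of potential quadruplex-forming sequences
    (PQS) on both DNA strands with a fully specified G-run scoring scheme,
    strand-aware intersection of PQS with repeat annotations, PQS density and
    base-pair proportion statistics, DNA versus amino-acid conservation-bias
    metrics (pairwise identity and BLOSUM62 similarity), Nei-Gojobori dN/dS
    with Jukes-Cantor correction, codon-level selection signatures (delta-GC
    against synonymous codon families, third-position cytosine and amino-acid
    usage in PQS versus non-PQS loci), upper-outlier and strand-asymmetry
    statistics, and a synthetic-data generator that emulates head-to-tail
    telomeric retrotransposon arrays with planted ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
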