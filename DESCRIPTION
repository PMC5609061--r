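Package: rdcnv
Title: Read-Depth Detection and Genotyping of Copy Number Variants from
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and genotypes copy-number variants and somatic
    copy-number alterations from whole-genome sequencing read-depth
    signals. Read counts (short reads) or mean depth of coverage (long
    reads) are computed over non-overlapping genomic windows, corrected
    for GC-content and mappability bias by median normalization, scaled
    to the two-copy level and log2-transformed. Signals are segmented
    with a shifting-level model formulated as a hidden Markov model and
    decoded by the Viterbi algorithm, and segments are classified into
    five copy-number states (double loss, loss, neutral, gain, multiple
    gain) with a mixture of truncated Gaussians that accounts for sample
    cellularity. Includes a negative-binomial simulator of synthetic
    chromosomes with embedded events and the evaluation statistics
    (reciprocal-overlap matching, breakpoint distance, copy-number
    concordance) used to benchmark read-depth callers. Supports
    no-control, paired tumor/normal and pooled-control designs, with
    tab-delimited and VCF output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    methods,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
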