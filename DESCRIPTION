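Package: poolscreen
Title: Pooled RNA-Seq Mutation Screening for Self-Fertilizing Isogenic Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward-genetics mutation identification from pooled RNA-seq of
    self-fertilizing, near-isogenic lines. Simulates allele counts for a
    selfing F2 cross segregating one recessive lethal allele (mutant, sibling
    and wild-type pools), applies a six-screen read-count filtering cascade to
    nominate the causal variant, annotates codon-level protein consequences of
    transcript variants with cross-species conservation checks, and ranks
    coverage-based expression changes between mutant and sibling pools.
    Includes readers and writers for a flat per-pool variant count table,
    transcript FASTA with CDS sidecar, and VCF export, plus an end-to-end
    pipeline driver with a plain-text configuration format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
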