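Package: dualsom
Title: Dual-Reference Somatic Mutation Detection for Highly Heterozygous Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects low-frequency somatic single-nucleotide variants in highly
    heterozygous genomes by combining alignments against a haploid and a
    diploid assembly of the same individual. Each read is assigned to one
    reference by an alignment-score / mapping-quality hierarchy, candidate
    sites are screened against a leniently-built control-position mask and a
    stringent strand-aware filter cascade, flank-based re-alignment flags
    mismapped reads, and a meristem-layer variant-allele-frequency model
    converts retained calls into per-site, annual and generational mutation
    rates. A built-in simulator generates diploid genomes, layer-structured
    somatic mutations, paired short reads and truth alignments so the whole
    pipeline can be exercised without external data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
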