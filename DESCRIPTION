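Package: barseqfit
Title: Pooled Barcoded Transposon Fitness and Genetic Interaction Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of randomly barcoded transposon sequencing (RB-TnSeq /
    BarSeq) experiments that compare a pooled insertion-mutant library's
    genetic requirements across growth contexts (alone, pairwise co-culture,
    full community). Extracts barcodes from BarSeq reads, assembles count
    matrices against an insertion pool table, estimates per-strain and
    per-gene fitness with chromosome-position and mode normalisation,
    computes moderated t-scores, classifies genes into conserved, induced
    and alleviated interaction sets (including the pairwise versus
    higher-order decomposition), applies significance thresholds to external
    differential-expression tables, computes hypergeometric category
    enrichment, and scores CFU-based competition assays. Includes a
    synthetic-data generator (genomes, insertion pools, planted fitness
    effects, multinomial sequencing counts, FASTQ emission) so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    optparse,
    rtracklayer,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
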