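Package: strandcheck
Title: Strand-Specific RNA-Seq Evaluation and Antisense Transcript Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating strand-specific (SS) against
    non-strand-specific (NSS) RNA-seq protocols. Parses UCSC refFlat gene
    models, detects transcripts mutually overlapped at the antisense strand
    and quantifies the degree of overlap, performs strand-aware read
    counting with equal-split allocation of ambiguous reads and RPKM
    computation, stratifies SS/NSS expression concordance by overlap
    percentage with size-matched resampling controls, benchmarks RNA-seq
    fold changes against qPCR delta-Ct fold changes by bootstrap, computes
    strandedness and library quality-control metrics, and discovers novel
    antisense genes from assembled contig alignments using identity and
    GT-AG splice-site filters. Includes a seeded synthetic-data generator
    (genome, annotation with controllable antisense overlap, stranded reads
    with leakage and 5'-positional bias, qPCR tables) with full ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
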