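Package: trioDNSNV
Title: Evaluation and Refinement of De Novo SNV Calls from Trio Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating and refining de novo single-nucleotide
    variant (DNSNV) call sets from father-mother-child trio sequencing.
    Extracts Mendelian-violation candidates from multi-sample VCFs,
    characterises them by windowed GC content, SNV density and
    transition/transversion ratios, scores them with a read-coverage
    (allele-depth) filter on a log10 scale, and compares call sets from
    multiple calling pipelines (overlaps, chromosomal distribution,
    genotype-quality summaries, known-variant catalog overlap rates).
    Includes a seeded synthetic trio generator with ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
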