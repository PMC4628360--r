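Package: diffmark
Title: Replicate-Aware Differential Analysis of Histone-Mark ChIP-Seq Peaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential analysis of histone-modification ChIP-seq peaks
    (e.g. H3K4me3) between two conditions with replicate peak sets:
    overlap-based replicate reproducibility, consensus peak construction,
    scale-factor normalization, low-signal quantile filtering, an
    empirical-Bayes moderated t-test with Benjamini-Hochberg FDR control,
    and fold-change/FDR peak calling. Downstream modules annotate
    differential peaks (genic/intergenic, TSS, ncRNA, chromosome
    distribution), associate them with meiotic DSB hotspot maps and compare
    DMC1 tag intensities, quantify region-level signal (e.g. the
    pseudoautosomal region), scan sequences for AT content, AT stretches
    and CpG dinucleotides, call microarray-style differential expression,
    and integrate peak and expression changes at gene TSSs. A synthetic-data
    generator emits genomes, replicate peak sets, negative-binomial count
    matrices and expression matrices with ground-truth labels so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
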