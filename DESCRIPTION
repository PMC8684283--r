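Package: nfaaScan
Title: Windowed Nearly-Fixed Alternative Allele Scans for Reference Assembly Introgression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects ancestry-discordant (introgressed) segments inside a
    reference genome assembly from multi-breed allele-frequency data. Counts
    nearly fixed alternative allele (NFAA) sites in non-overlapping scanning
    windows, derives the per-window depletion statistic Delta = mean(A) - A_i,
    flags windows beyond mean + k standard deviations and compacts them into
    candidate introgressed segments. Includes a calibrated synthetic-data
    generator with planted segments for ground-truth evaluation, pseudo
    reference-haplotype PCA validation, gene-to-segment annotation with
    cross-referencing against candidate gene lists, and paired comparisons of
    per-breed SNV counts between alternative reference assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: PopulationGenetics, SNP, Sequencing, Coverage
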