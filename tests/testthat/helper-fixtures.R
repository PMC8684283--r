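# Shared fixture builders. Everything is generated in code; no binary files.

twoChromLayout <- function(lenMb = c(10, 10)) {
  GenomeLayout(paste0("chr", seq_along(lenMb)), lenMb * 1e6)
}

# Small two-subspecies config with planted segments on both chromosomes.
smallConfig <- function(seed = 1L, n = 4, epsilon = 0.02,
                        lenMb = c(10, 10),
                        segments = NULL, breeds = NULL) {
  if (is.null(segments)) {
    # ancestry-A segments at 30-50% of chr1 and 60-70% of chr2, Mb-aligned
    s1 <- floor(0.3 * lenMb[1]); e1 <- max(s1 + 1, floor(0.5 * lenMb[1]))
    s2 <- floor(0.6 * lenMb[2]); e2 <- max(s2 + 1, floor(0.7 * lenMb[2]))
    segments <- data.frame(chrom = c("chr1", "chr2"),
                           start = c(s1, s2) * 1e6 + 1,
                           end = c(e1, e2) * 1e6)
  }
  if (is.null(breeds))
    breeds <- data.frame(name = c("A1", "A2", "A3", "B1", "B2", "B3"),
                         subspecies = rep(c("A", "B"), each = 3), n = n)
  cal <- calibrateDensities(n = n, epsilon = epsilon)
  simulationConfig(twoChromLayout(lenMb), segments, breeds,
                   divergenceDensity = cal$divergenceDensity,
                   polymorphismDensity = cal$polymorphismDensity,
                   epsilon = epsilon, seed = seed)
}

# Literal VCF text fixture exercising dosage codes, missing calls and a
# multi-allelic record.
writeToyVcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="QualByDepth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="MappingQuality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t100\t.\tA\tC\t50\tPASS\tQD=12.1;MQ=55\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tG\tA,T\t60\tPASS\tQD=8.0;MQ=60\tGT\t0/0\t1/2\t0/1",
    "chr1\t300\t.\tT\tG\t45\tPASS\tQD=1.9;MQ=41\tGT\t0/0\t./.\t1/1"),
    path)
  path
}

# Matched GFF3 / GTF encodings of one toy gene with two transcripts.
writeToyGff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t100\t900\t.\t+\t.\tID=gene:G1;Name=BCL10",
    "chr1\ttest\tmRNA\t100\t500\t.\t+\t.\tID=transcript:T1;Parent=gene:G1",
    "chr1\ttest\tmRNA\t300\t900\t.\t+\t.\tID=transcript:T2;Parent=gene:G1"),
    path)
  path
}

writeToyGtf <- function(path) {
  attr1 <- 'gene_id "G1"; transcript_id "T1"; gene_name "BCL10";'
  attr2 <- 'gene_id "G1"; transcript_id "T2"; gene_name "BCL10";'
  writeLines(c(
    paste("chr1", "test", "transcript", 100, 500, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "test", "transcript", 300, 900, ".", "+", ".", attr2, sep = "\t")),
    path)
  path
}

# A WindowCountTrack with given counts on a single-chromosome grid.
trackFromCounts <- function(counts, windowSizeMb = 1) {
  W <- windowSizeMb * 1e6
  lay <- GenomeLayout("chr1", length(counts) * W)
  countTrack <- countInWindows(
    data.frame(chrom = character(0), pos = integer(0), alt_freq = numeric(0)),
    windowGrid(lay, W))
  new("WindowCountTrack", grid = countTrack@grid, counts = as.numeric(counts),
      label = "fixture")
}

# Genotype matrix over nSites biallelic sites (plus optional multi-allelic
# ones) for a named breed.
toyGenotypeMatrix <- function(breed, nSamples, sites, seed = 1L) {
  set.seed(seed)
  dosage <- matrix(sample(0:2, nSamples * nrow(sites), replace = TRUE),
                   nrow = nSamples)
  genotypeMatrix(dosage,
                 data.frame(id = sprintf("%s_%d", breed, seq_len(nSamples)),
                            label = breed),
                 sites)
}
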