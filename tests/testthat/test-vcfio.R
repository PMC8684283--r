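# Format I/O: VCF sites, freq2 tables, hard filters, gene annotation, BED
# and chromosome-length tables.

test_that("VCF reader converts GT calls to dosages and keeps multi-allelic sites", {
  path <- writeToyVcf(withr::local_tempfile(fileext = ".vcf"))
  v <- readVcfSites(path)
  expect_equal(nrow(v$sites), 3)
  expect_equal(unname(v$dosage[1, ]), c(0L, 1L, 2L))          # 0/0 0/1 1/1
  expect_equal(v$sites$alt[2], "A,T")
  expect_equal(v$sites$n_alleles[2], 3L)
  expect_equal(unname(v$dosage[2, 2]), 2L)                    # 1/2: two non-ref
  expect_true(is.na(v$dosage[3, 2]))                          # ./.
  expect_equal(v$sites$QD, c(12.1, 8.0, 1.9))
  expect_equal(v$sites$qual, c(50, 60, 45))
})

test_that("an empty VCF body yields an empty site stream without error", {
  lay <- twoChromLayout(c(1, 1))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeVcfGenotypes(data.frame(chrom = character(0), pos = integer(0),
                               ref = character(0), alt = character(0)),
                    matrix(integer(0), 0, 2), c("s1", "s2"), lay, path)
  v <- readVcfSites(path)
  expect_equal(nrow(v$sites), 0)
})

test_that("VCF writer and reader round-trip dosages", {
  lay <- twoChromLayout(c(1, 1))
  sites <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      pos = c(10L, 500L, 99L),
                      ref = c("A", "G", "T"), alt = c("C", "T", "A"))
  dosage <- matrix(c(0L, 1L, 2L, 2L, 0L, 1L), nrow = 3)
  path <- withr::local_tempfile(fileext = ".vcf")
  writeVcfGenotypes(sites, dosage, c("x", "y"), lay, path)
  v <- readVcfSites(path)
  expect_equal(v$sites$pos, sites$pos)
  expect_equal(unname(v$dosage), unname(dosage))
})

test_that("freq2 tables round-trip and validate", {
  set.seed(3)
  n <- 1000
  nChr <- 12L
  ac <- rbinom(n, nChr, runif(n))
  rec <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    pos = sort(sample.int(1e6, n)),
                    n_alleles = 2L, n_chr = nChr,
                    freqs = I(lapply(ac, function(a) c((nChr - a) / nChr, a / nChr))))
  path <- withr::local_tempfile(fileext = ".frq")
  writeFreq2(rec, path)
  back <- readFreq2(path)
  expect_equal(back$chrom, rec$chrom)
  expect_equal(back$pos, rec$pos)
  expect_equal(unclass(back$freqs), unclass(rec$freqs), tolerance = 1e-9)

  # triallelic rows keep all three frequency columns
  tri <- data.frame(chrom = "chr1", pos = 5L, n_alleles = 3L, n_chr = 10L,
                    freqs = I(list(c(0.90, 0.06, 0.04))))
  writeFreq2(tri, path)
  backTri <- readFreq2(path)
  expect_equal(backTri$n_alleles, 3L)
  expect_equal(backTri$freqs[[1]], c(0.90, 0.06, 0.04), tolerance = 1e-9)
  expect_equal(backTri$freqs[[1]][3], 0.04, tolerance = 1e-9)

  # frequencies that do not sum to 1 are rejected
  writeLines(c("CHROM\tPOS\tN_ALLELES\tN_CHR\t{ALLELE:FREQ}",
               "chr1\t10\t2\t10\t0.5\t0.6"), path)
  expect_error(readFreq2(path), "sum")
})

test_that("hard filters fail on the published inequalities, strictly", {
  nominal <- data.frame(qual = 100, QD = 20, MQ = 60, SOR = 1, FS = 5,
                        MQRankSum = 0, ReadPosRankSum = 0)
  qdLow <- transform(nominal, QD = 1.9)
  r <- applyHardFilters(qdLow)
  expect_false(r$pass)
  expect_equal(r$reasons, "QD < 2.0")

  # every metric exactly at its boundary -> pass (strict inequalities)
  boundary <- data.frame(qual = 30.0, QD = 2.0, MQ = 40.0, SOR = 3.0,
                         FS = 60.0, MQRankSum = -12.5, ReadPosRankSum = -8.0)
  expect_true(applyHardFilters(boundary)$pass)

  two <- transform(nominal, FS = 61.0, SOR = 3.5)
  r2 <- applyHardFilters(two)
  expect_false(r2$pass)
  expect_setequal(strsplit(r2$reasons, ",")[[1]], c("SOR > 3.0", "FS > 60.0"))

  # an absent metric cannot fail
  partial <- data.frame(qual = 100, QD = 20)
  expect_true(applyHardFilters(partial)$pass)
  na <- transform(nominal, MQ = NA_real_)
  expect_true(applyHardFilters(na)$pass)
})

test_that("hard filter is monotone: worsening one metric never rescues a site", {
  set.seed(8)
  metrics <- c("qual", "QD", "MQ", "SOR", "FS", "MQRankSum", "ReadPosRankSum")
  lowerIsWorse <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE)
  for (i in 1:50) {
    site <- data.frame(qual = runif(1, 0, 60), QD = runif(1, 0, 5),
                       MQ = runif(1, 20, 60), SOR = runif(1, 0, 5),
                       FS = runif(1, 0, 100), MQRankSum = runif(1, -20, 5),
                       ReadPosRankSum = runif(1, -12, 5))
    before <- applyHardFilters(site)$pass
    j <- sample(seq_along(metrics), 1)
    worse <- site
    worse[[metrics[j]]] <- worse[[metrics[j]]] +
      if (lowerIsWorse[j]) -runif(1, 0, 10) else runif(1, 0, 10)
    after <- applyHardFilters(worse)$pass
    expect_false(!before && after)
  }
})

test_that("GFF3 and GTF encodings of one gene give identical gene models", {
  gff <- readGeneAnnotation(writeToyGff3(withr::local_tempfile(fileext = ".gff3")))
  gtf <- readGeneAnnotation(writeToyGtf(withr::local_tempfile(fileext = ".gtf")))
  expect_equal(nrow(gff), 2)                      # both transcripts retained
  expect_equal(gff, gtf)
  expect_equal(gff$gene_name, c("BCL10", "BCL10"))
  expect_equal(gff$tx_start, c(100, 300))
  expect_equal(gff$tx_end, c(500, 900))
})

test_that("annotation files without transcript features yield an empty model list", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tregion\t1\t1000\t.\t+\t.\tID=region:1"), path)
  expect_equal(nrow(readGeneAnnotation(path)), 0)
})

test_that("chromosome-length tables and BED intervals round-trip", {
  lay <- GenomeLayout(c("chr1", "chr2", "chrX"), c(5e6, 4e6, 3e6),
                      autosome = c(TRUE, TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeChromLengths(lay, path, writeAutosomeFlag = TRUE)
  back <- readChromLengths(path)
  expect_equal(chromNames(back), chromNames(lay))
  expect_equal(unname(chromLengths(back)), unname(chromLengths(lay)))
  expect_equal(autosomeNames(back), c("chr1", "chr2"))

  gr <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
                               IRanges::IRanges(c(1, 2e6 + 1, 11), c(1e6, 3e6, 20)))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeBed(gr, bed)
  raw <- read.table(bed, sep = "\t")
  expect_equal(raw$V2, c(0, 2e6, 10))             # 0-based starts
  back <- readBed(bed)
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(gr))
  expect_equal(BiocGenerics::end(back), BiocGenerics::end(gr))
})
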