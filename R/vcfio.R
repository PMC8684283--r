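# Readers/writers for the standard formats the pipeline touches, plus the
# GATK-style hard site filter.

#' Read a chromosome-length table
#'
#' Two tab-separated columns (name, length in bp), no header. An optional
#' third column flags autosomes (`1`/`0`); without it, `autosomes` selects
#' which names are autosomal (default: all).
#'
#' @param path file path.
#' @param autosomes character vector of autosome names, or `NULL` for all.
#' @return A [GenomeLayout-class].
#' @export
readChromLengths <- function(path, autosomes = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("chrom", "length")
  if (ncol(df) >= 3) names(df)[3] <- "autosome"
  auto <- if ("autosome" %in% names(df)) as.logical(as.integer(df$autosome))
          else if (is.null(autosomes)) rep(TRUE, nrow(df))
          else df$chrom %in% autosomes
  GenomeLayout(df$chrom, df$length, auto)
}

#' Write a chromosome-length table
#'
#' @param layout a [GenomeLayout-class].
#' @param path output path.
#' @param writeAutosomeFlag include the autosome flag as a third column.
#' @return `path`, invisibly.
#' @export
writeChromLengths <- function(layout, path, writeAutosomeFlag = FALSE) {
  df <- data.frame(chrom = layout@chrom, length = format(layout@lengths, scientific = FALSE, trim = TRUE))
  if (writeAutosomeFlag) df$autosome <- as.integer(layout@autosome)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GT string -> alternative-allele dosage. Counts non-reference alleles of a
# diploid call; anything not exactly two parsed alleles (missing, haploid)
# is NA so the 100%-call-rate / diploid retention filter can drop the site.
.gtToDosage <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) != 2 || any(a == ".")) return(NA_integer_)
    sum(a != "0")
  }, integer(1))
}

#' Read variant sites (with genotypes) from a VCF file
#'
#' Thin wrapper over [VariantAnnotation::readVcf()] returning the per-site
#' fields the pipeline uses. Multi-allelic sites are preserved with all
#' alternative alleles; dosages are `NA` where the GT call is missing or
#' non-diploid.
#'
#' @param path path to a VCF (v4.x) file.
#' @param samples optional character vector restricting the sample columns.
#' @return A list with elements `sites` (data.frame: `chrom`, `pos`, `ref`,
#'   `alt` comma-separated, `n_alleles`, `qual`, plus any of the INFO metrics
#'   `QD`, `MQ`, `SOR`, `FS`, `MQRankSum`, `ReadPosRankSum` present in the
#'   file) and `dosage` (integer matrix, sites x samples).
#' @export
readVcfSites <- function(path, samples = NULL) {
  param <- if (is.null(samples)) VariantAnnotation::ScanVcfParam()
           else VariantAnnotation::ScanVcfParam(samples = samples)
  vcf <- VariantAnnotation::readVcf(path, param = param)
  rr <- SummarizedExperiment::rowRanges(vcf)
  altList <- VariantAnnotation::alt(vcf)
  alt <- vapply(as(altList, "CharacterList"), paste, character(1), collapse = ",")
  sites <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    n_alleles = 1L + lengths(altList),
    qual = as.numeric(VariantAnnotation::qual(vcf)),
    stringsAsFactors = FALSE)
  infoDf <- VariantAnnotation::info(vcf)
  for (metric in c("QD", "MQ", "SOR", "FS", "MQRankSum", "ReadPosRankSum")) {
    if (metric %in% names(infoDf)) sites[[metric]] <- as.numeric(infoDf[[metric]])
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  dosage <- if (is.null(gt) || nrow(sites) == 0) {
    matrix(integer(0), nrow = nrow(sites), ncol = 0)
  } else {
    matrix(.gtToDosage(as.vector(gt)), nrow = nrow(gt),
           dimnames = list(NULL, colnames(gt)))
  }
  rownames(sites) <- NULL
  list(sites = sites, dosage = dosage)
}

#' Write a minimal multi-sample VCF (v4.2) from dosages
#'
#' Emits diploid GT-only records (`0/0`, `0/1`, `1/1`) with contig headers
#' taken from the layout. Used by the synthetic-data generator.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param dosage integer matrix (sites x samples) with values 0/1/2.
#' @param sampleNames character vector naming the sample columns.
#' @param layout a [GenomeLayout-class] providing contig lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(sites, dosage, sampleNames, layout, path) {
  stopifnot(nrow(sites) == nrow(dosage), length(sampleNames) == ncol(dosage))
  gtCode <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%s>", layout@chrom,
            format(layout@lengths, scientific = FALSE, trim = TRUE)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleNames), collapse = "\t")), con)
  if (nrow(sites)) {
    gt <- matrix(gtCode[dosage + 1L], nrow = nrow(dosage))
    body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", "PASS",
                  ".", "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a vcftools `--freq2`-dialect frequency table
#'
#' Tab-separated with header `CHROM POS N_ALLELES N_CHR {ALLELE:FREQ}` and one
#' frequency column per allele (reference first), so rows are ragged for
#' multi-allelic sites. Rows whose frequencies do not sum to 1 within `1e-6`
#' raise a validation error.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `pos`, `n_alleles`, `n_chr` and a
#'   list-column `freqs` (per-allele frequencies, reference first).
#' @export
readFreq2 <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "CHROM"))
    .stopf("not a freq2 table (missing CHROM header): %s", path)
  lines <- lines[-1]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      n_alleles = integer(0), n_chr = integer(0),
                      freqs = I(list())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nAll <- vapply(fields, function(f) as.integer(f[3]), integer(1))
  freqs <- lapply(fields, function(f) as.numeric(f[-(1:4)]))
  bad <- which(lengths(freqs) != nAll)
  if (length(bad))
    .stopf("freq2 row %d: %d frequency columns but N_ALLELES = %d",
           bad[1], lengths(freqs)[bad[1]], nAll[bad[1]])
  sums <- vapply(freqs, sum, numeric(1))
  bad <- which(abs(sums - 1) > 1e-6)
  if (length(bad))
    .stopf("freq2 row %d: frequencies sum to %.8f, not 1", bad[1], sums[bad[1]])
  data.frame(
    chrom = vapply(fields, `[`, character(1), 1),
    pos = as.integer(vapply(fields, `[`, character(1), 2)),
    n_alleles = nAll,
    n_chr = as.integer(vapply(fields, `[`, character(1), 4)),
    freqs = I(freqs), stringsAsFactors = FALSE)
}

#' Write a `--freq2`-dialect frequency table
#'
#' @param records data.frame as returned by [readFreq2()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFreq2 <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CHROM\tPOS\tN_ALLELES\tN_CHR\t{ALLELE:FREQ}", con)
  if (nrow(records)) {
    freqStr <- vapply(records$freqs, function(f)
      paste(sprintf("%.10f", f), collapse = "\t"), character(1))
    writeLines(paste(records$chrom, records$pos, records$n_alleles,
                     records$n_chr, freqStr, sep = "\t"), con)
  }
  invisible(path)
}

#' Apply GATK-style hard filters to variant sites
#'
#' A site fails if any of the strict inequalities holds: `QD < 2.0`,
#' `QUAL < 30.0`, `MQ < 40.0`, `SOR > 3.0`, `FS > 60.0`,
#' `MQRankSum < -12.5`, `ReadPosRankSum < -8.0`. Sites exactly at a boundary
#' pass. A metric that is absent or `NA` is not evaluated and cannot fail
#' (matching VariantFiltration's treatment of missing annotations).
#'
#' @param sites data.frame of sites; `qual` column holds the VCF QUAL value,
#'   the remaining metrics come from INFO.
#' @param thresholds named list overriding the default cutoffs.
#' @return data.frame with logical `pass` and character `reasons`
#'   (comma-separated failed criteria, `""` when passing), row-aligned to
#'   `sites`.
#' @export
applyHardFilters <- function(sites, thresholds = list(
    QD = 2.0, QUAL = 30.0, MQ = 40.0, SOR = 3.0, FS = 60.0,
    MQRankSum = -12.5, ReadPosRankSum = -8.0)) {
  n <- nrow(sites)
  lower <- c("QD", "QUAL", "MQ", "MQRankSum", "ReadPosRankSum")  # fail if metric < cutoff
  upper <- c("SOR", "FS")                                        # fail if metric > cutoff
  colFor <- function(metric) if (metric == "QUAL") "qual" else metric
  reasons <- rep("", n)
  fail <- rep(FALSE, n)
  for (metric in names(thresholds)) {
    col <- colFor(metric)
    if (!col %in% names(sites)) next
    v <- sites[[col]]
    cut <- thresholds[[metric]]
    hit <- if (metric %in% upper) !is.na(v) & v > cut else !is.na(v) & v < cut
    op <- if (metric %in% upper) ">" else "<"
    tag <- sprintf("%s %s %.1f", metric, op, cut)
    reasons[hit] <- ifelse(reasons[hit] == "", tag, paste(reasons[hit], tag, sep = ","))
    fail <- fail | hit
  }
  data.frame(pass = !fail, reasons = reasons, stringsAsFactors = FALSE)
}

#' Read gene models from GFF3 or GTF
#'
#' Imports via rtracklayer::import() and assembles one row per transcript
#' with its parent gene. Transcript-like features (`mRNA`, `transcript`)
#' lacking a resolvable gene id are skipped with a message.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"gtf"`.
#' @return data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `tx_start`, `tx_end` (1-based inclusive), one row per transcript.
#' @export
readGeneAnnotation <- function(path, format = c("auto", "gff3", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf"
              else if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3"
              else .stopf("cannot infer annotation format from '%s'; pass format=", path)
  }
  gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  isTx <- type %in% c("mRNA", "transcript")
  empty <- data.frame(gene_id = character(0), gene_name = character(0),
                      chrom = character(0), tx_start = integer(0),
                      tx_end = integer(0))
  if (!any(isTx)) return(empty)
  tx <- gr[isTx]
  txMd <- S4Vectors::mcols(tx)
  if (format == "gtf") {
    geneId <- as.character(txMd$gene_id)
    geneName <- if ("gene_name" %in% names(txMd)) as.character(txMd$gene_name) else geneId
  } else {
    parent <- vapply(as(txMd$Parent, "CharacterList"), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    parent <- sub("^gene:", "", parent)
    geneRows <- type == "gene"
    geneIds <- sub("^gene:", "", as.character(md$ID[geneRows]))
    geneNames <- if ("Name" %in% names(md)) as.character(md$Name[geneRows]) else geneIds
    idx <- match(parent, geneIds)
    geneId <- parent
    geneName <- ifelse(is.na(idx) | is.na(geneNames[idx]), geneId, geneNames[idx])
  }
  drop <- is.na(geneId) | geneId == ""
  if (any(drop))
    .msgf("readGeneAnnotation: skipped %d transcript feature(s) without a gene id",
          sum(drop))
  tx <- tx[!drop]
  out <- data.frame(
    gene_id = geneId[!drop],
    gene_name = ifelse(is.na(geneName[!drop]), geneId[!drop], geneName[!drop]),
    chrom = as.character(GenomeInfoDb::seqnames(tx)),
    tx_start = BiocGenerics::start(tx),
    tx_end = BiocGenerics::end(tx),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write genomic intervals as BED (0-based, half-open)
#'
#' Internal coordinates are 1-based inclusive; the writer converts. Optional
#' `name` and `score` metadata columns become BED columns 4-5.
#'
#' @param gr a `GRanges` (or a [SegmentSet-class], exported via
#'   [segmentRanges()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  if (is(gr, "SegmentSet")) {
    sr <- segmentRanges(gr)
    S4Vectors::mcols(sr)$name <- sprintf("segment_%d", seq_along(sr))
    S4Vectors::mcols(sr)$score <- S4Vectors::mcols(sr)$total_delta
    gr <- sr
  }
  md <- S4Vectors::mcols(gr)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = format(BiocGenerics::start(gr) - 1, scientific = FALSE, trim = TRUE),
                   end = format(BiocGenerics::end(gr), scientific = FALSE, trim = TRUE))
  if ("name" %in% names(md)) {
    df$name <- md$name
    if ("score" %in% names(md)) df$score <- sprintf("%.2f", md$score)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into 1-based GRanges
#'
#' @param path BED3+ file.
#' @return `GRanges` with 1-based inclusive coordinates (and `name`/`score`
#'   metadata when present).
#' @export
readBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}
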