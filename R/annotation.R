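# Gene-to-segment assignment, cross-referencing against a candidate gene
# list, and the expected-by-chance gene count.

#' Load the packaged positive-selection segment table
#'
#' Candidate introgressed segments (window units, start inclusive / end
#' exclusive) that harbour genes reported under positive selection in
#' influential Brahman bulls, with the summed Delta and segment size, and the
#' comma-separated positive genes per segment.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return data.frame with columns `chrom`, `start_mb`, `end_mb`,
#'   `total_delta`, `size_mb`, `positive_genes`.
#' @export
positiveSegmentTable <- function(path = system.file(
    "extdata", "positive_segments_table.tsv", package = "nfaaScan")) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "numeric", "numeric",
                                   "numeric", "numeric", "character"))
}

#' Load the packaged positive-selection gene list
#'
#' @param path one gene symbol per line; defaults to the packaged list.
#' @return character vector of gene symbols.
#' @export
positiveGeneList <- function(path = system.file(
    "extdata", "brahman_positive_selection_genes.txt", package = "nfaaScan")) {
  readLines(path)
}

#' Assign genes to candidate segments
#'
#' A gene is assigned to a segment when at least one of its transcripts
#' qualifies: in `"contained"` mode (default) the transcript must lie
#' entirely within the segment; in `"overlap"` mode any intersection
#' suffices. Duplicate gene/segment pairs are collapsed; a gene may appear
#' in several segments.
#'
#' @param genes data.frame of transcripts from [readGeneAnnotation()]
#'   (columns `gene_id`, `gene_name`, `chrom`, `tx_start`, `tx_end`).
#' @param segments a [SegmentSet-class] or a `GRanges` of 1-based segment
#'   intervals.
#' @param mode `"contained"` or `"overlap"`.
#' @param layout optional [GenomeLayout-class]; when given, transcripts
#'   exceeding their chromosome bounds raise a coordinate-mismatch error.
#' @return data.frame with one row per (segment, gene): `chrom`,
#'   `seg_start`, `seg_end` (bp, 1-based inclusive), `gene_id`, `gene_name`,
#'   with attribute `mode`.
#' @export
assignGenes <- function(genes, segments, mode = c("contained", "overlap"),
                        layout = NULL) {
  mode <- match.arg(mode)
  if (!is.null(layout)) {
    lens <- chromLengths(layout)
    bad <- which(genes$tx_end > lens[genes$chrom] | genes$tx_start < 1)
    if (length(bad))
      .stopf("transcript of gene %s exceeds chromosome bounds (coordinate system mismatch?)",
             genes$gene_id[bad[1]])
  }
  segGr <- if (methods::is(segments, "SegmentSet")) segmentRanges(segments)
           else segments
  empty <- data.frame(chrom = character(0), seg_start = numeric(0),
                      seg_end = numeric(0), gene_id = character(0),
                      gene_name = character(0))
  attr(empty, "mode") <- mode
  if (length(segGr) == 0 || nrow(genes) == 0) return(empty)
  txGr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$tx_start, genes$tx_end))
  hits <- GenomicRanges::findOverlaps(txGr, segGr,
                                      type = if (mode == "contained") "within" else "any")
  if (length(hits) == 0) return(empty)
  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(segGr))[S4Vectors::subjectHits(hits)],
    seg_start = BiocGenerics::start(segGr)[S4Vectors::subjectHits(hits)],
    seg_end = BiocGenerics::end(segGr)[S4Vectors::subjectHits(hits)],
    gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
    gene_name = genes$gene_name[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$chrom, out$seg_start, out$gene_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

#' Cross-reference assigned genes against a candidate gene list
#'
#' Symbol matching is by case-insensitive string comparison; aliases are not
#' resolved.
#'
#' @param assignment data.frame from [assignGenes()].
#' @param geneList character vector of candidate gene symbols.
#' @return list with `perSegment` (data.frame: `chrom`, `seg_start`,
#'   `seg_end`, `matched` comma-separated symbols, `n_matched`),
#'   `genesMatched` (unique matched symbols), `nGenesMatched` and
#'   `nSegmentsWithMatch`.
#' @export
crossrefGeneList <- function(assignment, geneList) {
  if (length(geneList) == 0) {
    warning("crossrefGeneList: empty reference gene list")
    return(list(perSegment = data.frame(), genesMatched = character(0),
                nGenesMatched = 0L, nSegmentsWithMatch = 0L))
  }
  hit <- toupper(assignment$gene_name) %in% toupper(geneList)
  m <- assignment[hit, , drop = FALSE]
  segKey <- paste(m$chrom, m$seg_start, m$seg_end)
  per <- if (nrow(m)) {
    agg <- lapply(split(m, segKey), function(s)
      data.frame(chrom = s$chrom[1], seg_start = s$seg_start[1],
                 seg_end = s$seg_end[1],
                 matched = paste(sort(unique(s$gene_name)), collapse = ","),
                 n_matched = length(unique(s$gene_name)),
                 stringsAsFactors = FALSE))
    out <- do.call(rbind, agg)
    out <- out[order(out$chrom, out$seg_start), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else data.frame()
  list(perSegment = per,
       genesMatched = sort(unique(m$gene_name)),
       nGenesMatched = length(unique(toupper(m$gene_name))),
       nSegmentsWithMatch = length(unique(segKey)))
}

#' Expected-by-chance gene count in flagged regions
#'
#' Under a uniform placement of genes over windows, the expected number of
#' genes inside the flagged fraction of the genome is
#' `totalGenes * flaggedFraction`, rounded half away from zero. The deficit
#' is `expectation - observed`.
#'
#' @param totalGenes total annotated genes on the assembly.
#' @param flaggedFraction flagged genome fraction in `[0, 1]`.
#' @param observed genes actually found inside flagged regions (optional).
#' @return list with `expectation` (rounded), `expectationRaw` and, when
#'   `observed` is given, `deficit`.
#' @export
expectedGeneCount <- function(totalGenes, flaggedFraction, observed = NULL) {
  stopifnot(flaggedFraction >= 0, flaggedFraction <= 1)
  raw <- totalGenes * flaggedFraction
  out <- list(expectation = roundHalfAwayFromZero(raw), expectationRaw = raw)
  if (!is.null(observed)) out$deficit <- out$expectation - observed
  out
}
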