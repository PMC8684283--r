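#' @import methods
#' @importFrom GenomicRanges GRanges
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' GenomeLayout: ordered chromosomes with lengths and autosome flags
#'
#' Describes the reference assembly the scan runs against: chromosome names,
#' lengths in bp, and which chromosomes are autosomes. Only autosomes enter
#' the scanning-window grid; sex chromosomes and unplaced contigs must be
#' flagged `autosome = FALSE` explicitly.
#'
#' @slot chrom character vector of chromosome names (unique, ordered).
#' @slot lengths numeric vector of chromosome lengths in bp (> 0).
#' @slot autosome logical vector, `TRUE` for autosomes.
#' @export
setClass("GenomeLayout",
  representation(chrom = "character", lengths = "numeric", autosome = "logical"))

setValidity("GenomeLayout", function(object) {
  if (length(object@chrom) != length(object@lengths) ||
      length(object@chrom) != length(object@autosome))
    return("chrom, lengths and autosome must have equal length")
  if (anyDuplicated(object@chrom)) return("chromosome names must be unique")
  if (any(!is.finite(object@lengths)) || any(object@lengths <= 0))
    return("chromosome lengths must be positive and finite")
  TRUE
})

#' GenomeLayout constructor
#'
#' @param chrom character vector of chromosome names.
#' @param lengths numeric vector of lengths in bp.
#' @param autosome logical vector; defaults to all `TRUE`.
#' @return A [GenomeLayout-class] object.
#' @examples
#' GenomeLayout(c("chr1", "chrX"), c(1e7, 5e6), autosome = c(TRUE, FALSE))
#' @export
GenomeLayout <- function(chrom, lengths, autosome = rep(TRUE, length(chrom))) {
  new("GenomeLayout", chrom = as.character(chrom), lengths = as.numeric(lengths),
      autosome = as.logical(autosome))
}

setMethod("show", "GenomeLayout", function(object) {
  cat(sprintf("GenomeLayout: %d chromosomes (%d autosomes), %.1f Mb total\n",
              length(object@chrom), sum(object@autosome),
              sum(object@lengths) / 1e6))
})

#' SimulationConfig: parameters of the mosaic-ancestry simulator
#'
#' Holds the generative model for synthetic multi-breed frequency data: a
#' genome layout, planted ancestry-discordant segments, the breed panel
#' (subspecies label, admixture fraction of subspecies-A ancestry, diploid
#' sample size), per-Mb densities of fixed inter-subspecies differences and
#' shared polymorphic sites, the residual minor-allele frequency `epsilon`
#' at divergence sites, and the RNG seed.
#'
#' @slot layout a [GenomeLayout-class].
#' @slot plantedSegments `GRanges` of segments whose reference-local ancestry
#'   is subspecies A (the rest of the genome is ancestry B).
#' @slot breeds data.frame with columns `name`, `subspecies` (`"A"`/`"B"`),
#'   `admixture` (fraction of subspecies-A ancestry in `[0,1]`), `n`
#'   (diploid individuals, >= 1).
#' @slot divergenceDensity fixed-difference sites per Mb (> 0).
#' @slot polymorphismDensity shared segregating sites per Mb (>= 0).
#' @slot epsilon residual minor-allele frequency at divergence sites, in
#'   `[0, 0.05)` so divergence sites can exceed the 0.95 NFAA threshold.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(layout = "GenomeLayout", plantedSegments = "GRanges",
                 breeds = "data.frame", divergenceDensity = "numeric",
                 polymorphismDensity = "numeric", epsilon = "numeric",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  b <- object@breeds
  need <- c("name", "subspecies", "admixture", "n")
  if (!all(need %in% names(b)))
    return(sprintf("breeds must have columns %s", paste(need, collapse = ", ")))
  if (nrow(b) == 0) return("at least one breed is required")
  if (anyDuplicated(b$name)) return("breed names must be unique")
  if (!all(b$subspecies %in% c("A", "B")))
    return("subspecies labels must be 'A' or 'B'")
  if (any(b$admixture < 0 | b$admixture > 1))
    return("admixture fractions must lie in [0, 1]")
  if (any(b$n < 1)) return("all breeds need n_individuals >= 1")
  if (object@divergenceDensity <= 0) return("divergence_density must be > 0")
  if (object@polymorphismDensity < 0) return("polymorphism_density must be >= 0")
  if (object@epsilon < 0 || object@epsilon >= 0.05)
    return("epsilon must lie in [0, 0.05) so divergence sites can pass the NFAA threshold")
  seg <- object@plantedSegments
  if (length(seg)) {
    lay <- object@layout
    segChrom <- as.character(GenomeInfoDb::seqnames(seg))
    bad <- which(!(segChrom %in% lay@chrom))
    if (length(bad))
      return(sprintf("planted segment %d lies on unknown chromosome '%s'",
                     bad[1], segChrom[bad[1]]))
    lens <- lay@lengths[match(segChrom, lay@chrom)]
    bad <- which(BiocGenerics::start(seg) < 1 | BiocGenerics::end(seg) > lens)
    if (length(bad))
      return(sprintf("planted segment %d (%s:%d-%d) exceeds chromosome bounds",
                     bad[1], segChrom[bad[1]],
                     BiocGenerics::start(seg)[bad[1]], BiocGenerics::end(seg)[bad[1]]))
    red <- GenomicRanges::reduce(seg, min.gapwidth = 0L)
    if (sum(BiocGenerics::width(red)) != sum(BiocGenerics::width(seg)))
      return("planted segments overlap; they must be disjoint")
  }
  TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d breeds, %d planted segments (%.1f Mb), ",
    "divergence %.0f/Mb, polymorphism %.0f/Mb, epsilon %.3f, seed %d\n"),
    nrow(object@breeds), length(object@plantedSegments),
    sum(BiocGenerics::width(object@plantedSegments)) / 1e6,
    object@divergenceDensity, object@polymorphismDensity,
    object@epsilon, object@seed))
})

#' WindowGrid: non-overlapping scanning windows tiling the autosomes
#'
#' Window k (0-based) on a chromosome covers 1-based positions
#' `[k*W + 1, (k+1)*W]`; the final window is truncated at the chromosome end.
#'
#' @slot windows `GRanges`, one range per window, ordered by chromosome then
#'   position, with metadata column `windowIndex` (0-based within chromosome).
#' @slot windowSize window width W in bp.
#' @slot layout the [GenomeLayout-class] the grid was built from.
#' @export
setClass("WindowGrid",
  representation(windows = "GRanges", windowSize = "numeric",
                 layout = "GenomeLayout"))

setValidity("WindowGrid", function(object) {
  if (length(object@windowSize) != 1 || object@windowSize < 1)
    return("windowSize must be a single positive number")
  if (length(object@windows) == 0) return("grid must contain at least one window")
  TRUE
})

setMethod("show", "WindowGrid", function(object) {
  cat(sprintf("WindowGrid: %d windows of %.0f bp over %d autosomes\n",
              length(object@windows), object@windowSize,
              length(unique(as.character(GenomeInfoDb::seqnames(object@windows))))))
})

#' WindowCountTrack: per-window NFAA site counts A_i
#'
#' Integer counts for a single breed, or non-negative rational per-window
#' means for a breed group.
#'
#' @slot grid the [WindowGrid-class] the counts live on.
#' @slot counts numeric vector, one value per grid window, >= 0.
#' @slot label breed or group label.
#' @export
setClass("WindowCountTrack",
  representation(grid = "WindowGrid", counts = "numeric", label = "character"))

setValidity("WindowCountTrack", function(object) {
  if (length(object@counts) != length(object@grid@windows))
    return("counts must have one value per grid window")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    return("counts must be finite and non-negative")
  TRUE
})

setMethod("show", "WindowCountTrack", function(object) {
  cat(sprintf("WindowCountTrack '%s': %d windows, total %.1f, mean %.2f\n",
              object@label, length(object@counts), sum(object@counts),
              mean(object@counts)))
})

#' DeltaTrack: per-window depletion statistic Delta_i = mean(A) - A_i
#'
#' Large positive Delta marks windows depleted of NFAA sites relative to the
#' genome-wide mean. The mean and sd of both A and Delta are retained for
#' thresholding; `sd` is the sample standard deviation (n - 1 denominator).
#'
#' @slot grid the [WindowGrid-class].
#' @slot delta numeric vector of Delta_i values.
#' @slot meanA,sdA genome-wide mean and sample sd of the counts A.
#' @slot meanDelta,sdDelta mean (zero up to rounding) and sample sd of Delta.
#' @slot label source track label.
#' @export
setClass("DeltaTrack",
  representation(grid = "WindowGrid", delta = "numeric", meanA = "numeric",
                 sdA = "numeric", meanDelta = "numeric", sdDelta = "numeric",
                 label = "character"))

setValidity("DeltaTrack", function(object) {
  if (length(object@delta) != length(object@grid@windows))
    return("delta must have one value per grid window")
  if (abs(sum(object@delta)) >= 1e-6 * length(object@delta))
    return("sum of delta values must be zero up to accumulated rounding")
  TRUE
})

setMethod("show", "DeltaTrack", function(object) {
  cat(sprintf("DeltaTrack '%s': %d windows, mean(A) = %.2f, sd(Delta) = %.2f\n",
              object@label, length(object@delta), object@meanA, object@sdDelta))
})

#' SegmentSet: compacted flagged windows (candidate introgressed segments)
#'
#' Maximal runs of consecutive flagged windows per chromosome, each reported
#' with inclusive start and exclusive end in window units (Mb for the default
#' 1-Mb windows), the summed Delta over member windows, and the size.
#'
#' @slot grid the [WindowGrid-class].
#' @slot flagged integer indices (into grid windows) of the flagged set T.
#' @slot kSd the flagging threshold multiplier used.
#' @slot table data.frame with columns `chrom`, `start_mb`, `end_mb`,
#'   `total_delta`, `size_mb`, sorted by (chrom, start).
#' @slot members list of integer vectors: grid-window indices per segment.
#' @export
setClass("SegmentSet",
  representation(grid = "WindowGrid", flagged = "integer", kSd = "numeric",
                 table = "data.frame", members = "list"))

setValidity("SegmentSet", function(object) {
  tb <- object@table
  if (nrow(tb) && !isTRUE(all.equal(tb$size_mb, tb$end_mb - tb$start_mb)))
    return("size_mb must equal end_mb - start_mb for every segment")
  memberUnion <- sort(as.integer(unlist(object@members, use.names = FALSE)))
  if (!identical(memberUnion, sort(unique(object@flagged))))
    return("union of segment member windows must equal the flagged set")
  TRUE
})

setMethod("show", "SegmentSet", function(object) {
  cat(sprintf("SegmentSet: %d segments from %d flagged windows (k = %.2f sd)\n",
              nrow(object@table), length(object@flagged), object@kSd))
})

#' GenotypeMatrix: samples x biallelic sites alternative-allele dosages
#'
#' @slot dosage integer matrix (samples x sites) with values in \{0, 1, 2\},
#'   no missing entries.
#' @slot samples data.frame with columns `id` (unique) and `label`
#'   (population / subspecies label).
#' @slot sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
setClass("GenotypeMatrix",
  representation(dosage = "matrix", samples = "data.frame", sites = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  if (nrow(object@dosage) != nrow(object@samples))
    return("dosage rows must match samples")
  if (ncol(object@dosage) != nrow(object@sites))
    return("dosage columns must match sites")
  if (anyDuplicated(object@samples$id)) return("sample ids must be unique")
  if (anyNA(object@dosage)) return("no missing dosages are allowed")
  if (!all(object@dosage %in% 0:2)) return("dosages must be 0, 1 or 2")
  TRUE
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d samples x %d biallelic sites\n",
              nrow(object@dosage), ncol(object@dosage)))
})

#' PcaResult: principal components of a dosage matrix
#'
#' @slot coords matrix (samples x components) of PC coordinates.
#' @slot eigenvalues non-increasing variances of the retained components.
#' @slot varExplained fraction of total variance per retained component.
#' @slot samples data.frame of sample `id` and `label`, row-aligned to coords.
#' @export
setClass("PcaResult",
  representation(coords = "matrix", eigenvalues = "numeric",
                 varExplained = "numeric", samples = "data.frame"))

setValidity("PcaResult", function(object) {
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    return("eigenvalues must be non-increasing")
  if (any(object@varExplained < 0 | object@varExplained > 1))
    return("variance-explained fractions must lie in [0, 1]")
  TRUE
})

setMethod("show", "PcaResult", function(object) {
  cat(sprintf("PcaResult: %d samples, %d components (PC1 %.1f%% of variance)\n",
              nrow(object@coords), ncol(object@coords),
              100 * object@varExplained[1]))
})
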