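# Accessor generics. Slot access from user code should go through these.

#' @rdname GenomeLayout-class
#' @param x an object.
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))
#' @rdname GenomeLayout-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @rdname GenomeLayout-class
#' @export
setGeneric("autosomeNames", function(x) standardGeneric("autosomeNames"))

setMethod("chromNames", "GenomeLayout", function(x) x@chrom)
setMethod("chromLengths", "GenomeLayout",
          function(x) stats::setNames(x@lengths, x@chrom))
setMethod("autosomeNames", "GenomeLayout", function(x) x@chrom[x@autosome])

#' @rdname WindowGrid-class
#' @param x an object.
#' @export
setGeneric("gridWindows", function(x) standardGeneric("gridWindows"))
#' @rdname WindowGrid-class
#' @export
setGeneric("windowSize", function(x) standardGeneric("windowSize"))
#' @rdname WindowGrid-class
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

setMethod("gridWindows", "WindowGrid", function(x) x@windows)
setMethod("windowSize", "WindowGrid", function(x) x@windowSize)
setMethod("nWindows", "WindowGrid", function(x) length(x@windows))
setMethod("gridWindows", "WindowCountTrack", function(x) x@grid@windows)
setMethod("gridWindows", "DeltaTrack", function(x) x@grid@windows)

#' @rdname WindowCountTrack-class
#' @param x an object.
#' @export
setGeneric("windowCounts", function(x) standardGeneric("windowCounts"))
#' @rdname WindowCountTrack-class
#' @export
setGeneric("trackLabel", function(x) standardGeneric("trackLabel"))

setMethod("windowCounts", "WindowCountTrack", function(x) x@counts)
setMethod("trackLabel", "WindowCountTrack", function(x) x@label)
setMethod("trackLabel", "DeltaTrack", function(x) x@label)

#' @rdname DeltaTrack-class
#' @param x an object.
#' @export
setGeneric("deltaValues", function(x) standardGeneric("deltaValues"))
#' @rdname DeltaTrack-class
#' @export
setGeneric("deltaStats", function(x) standardGeneric("deltaStats"))

setMethod("deltaValues", "DeltaTrack", function(x) x@delta)
setMethod("deltaStats", "DeltaTrack", function(x)
  list(meanA = x@meanA, sdA = x@sdA, meanDelta = x@meanDelta,
       sdDelta = x@sdDelta))

#' @rdname SegmentSet-class
#' @param x an object.
#' @export
setGeneric("flaggedWindows", function(x) standardGeneric("flaggedWindows"))
#' @rdname SegmentSet-class
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))
#' @rdname SegmentSet-class
#' @export
setGeneric("segmentRanges", function(x) standardGeneric("segmentRanges"))

setMethod("flaggedWindows", "SegmentSet", function(x) x@flagged)
setMethod("segmentTable", "SegmentSet", function(x) x@table)

# Segment intervals in bp on the assembly, 1-based inclusive; the terminal
# window of a chromosome is truncated at the chromosome end.
setMethod("segmentRanges", "SegmentSet", function(x) {
  tb <- x@table
  W <- x@grid@windowSize
  if (nrow(tb) == 0)
    return(GenomicRanges::GRanges())
  lens <- chromLengths(x@grid@layout)
  ends <- pmin(tb$end_mb * W, lens[tb$chrom])
  gr <- GenomicRanges::GRanges(tb$chrom,
                               IRanges::IRanges(tb$start_mb * W + 1, ends))
  S4Vectors::mcols(gr)$total_delta <- tb$total_delta
  S4Vectors::mcols(gr)$size_mb <- tb$size_mb
  gr
})

#' @rdname GenotypeMatrix-class
#' @param x an object.
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))
#' @rdname GenotypeMatrix-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname GenotypeMatrix-class
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

setMethod("dosageMatrix", "GenotypeMatrix", function(x) x@dosage)
setMethod("sampleInfo", "GenotypeMatrix", function(x) x@samples)
setMethod("siteInfo", "GenotypeMatrix", function(x) x@sites)

#' @rdname PcaResult-class
#' @param x an object.
#' @export
setGeneric("pcaCoords", function(x) standardGeneric("pcaCoords"))
#' @rdname PcaResult-class
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))
#' @rdname PcaResult-class
#' @export
setGeneric("pcaEigenvalues", function(x) standardGeneric("pcaEigenvalues"))

setMethod("pcaCoords", "PcaResult", function(x) x@coords)
setMethod("varianceExplained", "PcaResult", function(x) x@varExplained)
setMethod("pcaEigenvalues", "PcaResult", function(x) x@eigenvalues)
setMethod("sampleInfo", "PcaResult", function(x) x@samples)
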