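# The core scan statistic: per-window NFAA counts A_i, z-scores, the
# depletion statistic Delta_i = mean(A) - A_i, threshold flagging at
# mean(Delta) + k * sd(Delta), and compaction of flagged windows into
# segments. Means and standard deviations are computed genome-wide over ALL
# grid windows, including zero-count and truncated terminal windows; sd is
# the sample standard deviation (n - 1).

#' Build the scanning-window grid over the autosomes
#'
#' @param layout a [GenomeLayout-class]; only autosomes are tiled.
#' @param size window width W in bp (default 1 Mb).
#' @return A [WindowGrid-class].
#' @export
windowGrid <- function(layout, size = 1e6) {
  auto <- layout@autosome
  if (!any(auto)) .stopf("layout contains no autosomes")
  seqlens <- stats::setNames(layout@lengths[auto], layout@chrom[auto])
  gr <- GenomicRanges::tileGenome(seqlens, tilewidth = size,
                                  cut.last.tile.in.chrom = TRUE)
  idx <- unlist(lapply(table(factor(as.character(GenomeInfoDb::seqnames(gr)),
                                    levels = names(seqlens))),
                       function(k) seq_len(k) - 1L), use.names = FALSE)
  S4Vectors::mcols(gr)$windowIndex <- idx
  new("WindowGrid", windows = gr, windowSize = as.numeric(size), layout = layout)
}

# (chrom, pos) -> row index into the grid windows; NA when the chromosome is
# not on the grid, error when a position exceeds its chromosome.
.windowRow <- function(grid, chrom, pos) {
  gr <- grid@windows
  W <- grid@windowSize
  chromLevels <- unique(as.character(GenomeInfoDb::seqnames(gr)))
  offset <- stats::setNames(c(0, cumsum(S4Vectors::runLength(GenomeInfoDb::seqnames(gr))))[
    seq_along(chromLevels)], chromLevels)
  lens <- chromLengths(grid@layout)
  beyond <- which(pos > lens[chrom] | pos < 1)
  if (length(beyond))
    .stopf("site %s:%d lies outside its chromosome (length %d)",
           chrom[beyond[1]], pos[beyond[1]], lens[chrom[beyond[1]]])
  k <- floor((pos - 1) / W)
  unname(offset[chrom] + k + 1L)
}

#' Count NFAA sites per scanning window (A_i)
#'
#' Each site falls in exactly one window: window index
#' `k = floor((pos - 1) / W)` on its chromosome. Windows without sites are
#' present with count 0.
#'
#' @param nfaa data.frame of NFAA sites (columns `chrom`, `pos`), as from
#'   [selectNfaa()].
#' @param grid a [WindowGrid-class].
#' @param label track label; defaults to the `breed` attribute of `nfaa`.
#' @return A [WindowCountTrack-class].
#' @export
countInWindows <- function(nfaa, grid, label = NULL) {
  if (is.null(label))
    label <- if (!is.null(attr(nfaa, "breed"))) attr(nfaa, "breed") else "track"
  counts <- numeric(nWindows(grid))
  if (nrow(nfaa)) {
    onGrid <- nfaa$chrom %in% unique(as.character(GenomeInfoDb::seqnames(grid@windows)))
    if (!all(onGrid))
      .stopf("site %s:%d is not on a grid chromosome",
             nfaa$chrom[!onGrid][1], nfaa$pos[!onGrid][1])
    rows <- .windowRow(grid, nfaa$chrom, nfaa$pos)
    tab <- tabulate(rows, nbins = length(counts))
    counts <- as.numeric(tab)
  }
  new("WindowCountTrack", grid = grid, counts = counts,
      label = as.character(label))
}

#' Average window-count tracks across breeds
#'
#' @param tracks list of [WindowCountTrack-class] objects sharing one grid.
#' @param label label for the group track.
#' @return A [WindowCountTrack-class] of per-window arithmetic means.
#' @export
groupMeanTrack <- function(tracks, label = "group") {
  if (length(tracks) == 0) .stopf("groupMeanTrack: no tracks supplied")
  ref <- tracks[[1]]@grid
  same <- vapply(tracks, function(t)
    identical(GenomicRanges::granges(t@grid@windows), GenomicRanges::granges(ref@windows)),
    logical(1))
  if (!all(same)) .stopf("groupMeanTrack: tracks are on different grids")
  m <- rowMeans(vapply(tracks, windowCounts, numeric(nWindows(ref))))
  new("WindowCountTrack", grid = ref, counts = m, label = label)
}

#' Z-score transform of a window-count track
#'
#' `z_i = (A_i - mean(A)) / sd(A)` with the sample sd over all grid windows.
#'
#' @param track a [WindowCountTrack-class].
#' @return numeric vector of z-scores (mean 0, sd 1).
#' @export
zscoreTrack <- function(track) {
  a <- track@counts
  s <- stats::sd(a)
  if (!is.finite(s) || s == 0)
    .stopf("zscoreTrack: constant track (sd = 0)")
  (a - mean(a)) / s
}

#' Depletion statistic Delta_i = mean(A) - A_i
#'
#' Large positive Delta marks windows depleted of NFAA sites; the genome-wide
#' mean is taken over all grid windows including zero-count ones.
#'
#' @param track a [WindowCountTrack-class] covering the full grid.
#' @return A [DeltaTrack-class].
#' @export
deltaTrack <- function(track) {
  a <- track@counts
  if (length(a) == 0) .stopf("deltaTrack: empty grid")
  mu <- mean(a)
  d <- mu - a
  new("DeltaTrack", grid = track@grid, delta = d, meanA = mu,
      sdA = stats::sd(a), meanDelta = mean(d), sdDelta = stats::sd(d),
      label = track@label)
}

#' Flag NFAA-depleted windows (the set T)
#'
#' Strict inequality: window i is flagged when
#' `Delta_i > mean(Delta) + kSd * sd(Delta)`; a window exactly at the
#' threshold is not flagged.
#'
#' @param delta a [DeltaTrack-class].
#' @param kSd threshold multiplier (> 0); default 1.5.
#' @return integer vector of flagged grid-window indices.
#' @export
flagWindows <- function(delta, kSd = 1.5) {
  if (length(kSd) != 1 || !is.finite(kSd) || kSd <= 0)
    .stopf("kSd must be a single positive number")
  if (!is.finite(delta@sdDelta) || delta@sdDelta == 0)
    .stopf("flagWindows: sd(Delta) is zero")
  which(delta@delta > delta@meanDelta + kSd * delta@sdDelta)
}

#' Compact flagged windows into segments
#'
#' Maximal runs of consecutive flagged windows on one chromosome are merged.
#' Each segment reports its inclusive start and exclusive end in window units
#' (integer Mb for 1-Mb windows), `size_mb = end - start`, and the summed
#' Delta over member windows. Segments are sorted by (chrom, start).
#'
#' @param flagged integer vector of flagged window indices (subset of the
#'   grid), as from [flagWindows()].
#' @param delta the [DeltaTrack-class] the flags came from.
#' @param kSd threshold multiplier recorded in the result.
#' @return A [SegmentSet-class].
#' @export
compactSegments <- function(flagged, delta, kSd = 1.5) {
  grid <- delta@grid
  flagged <- sort(unique(as.integer(flagged)))
  if (length(flagged) && (min(flagged) < 1 || max(flagged) > nWindows(grid)))
    .stopf("flagged indices outside the grid")
  if (length(flagged) == 0) {
    return(new("SegmentSet", grid = grid, flagged = integer(0), kSd = kSd,
               table = data.frame(chrom = character(0), start_mb = numeric(0),
                                  end_mb = numeric(0), total_delta = numeric(0),
                                  size_mb = numeric(0)),
               members = list()))
  }
  gr <- grid@windows
  chrom <- as.character(GenomeInfoDb::seqnames(gr))[flagged]
  widx <- S4Vectors::mcols(gr)$windowIndex[flagged]
  newRun <- c(TRUE, !(chrom[-1] == chrom[-length(chrom)] &
                        widx[-1] == widx[-length(widx)] + 1L))
  runId <- cumsum(newRun)
  members <- split(flagged, runId)
  tb <- data.frame(
    chrom = vapply(members, function(m) chrom[match(m[1], flagged)], character(1)),
    start_mb = vapply(members, function(m) widx[match(m[1], flagged)], numeric(1)),
    end_mb = vapply(members, function(m) widx[match(m[length(m)], flagged)] + 1, numeric(1)),
    total_delta = vapply(members, function(m) sum(delta@delta[m]), numeric(1)),
    stringsAsFactors = FALSE)
  tb$size_mb <- tb$end_mb - tb$start_mb
  ord <- order(tb$chrom, tb$start_mb)
  tb <- tb[ord, , drop = FALSE]
  rownames(tb) <- NULL
  members <- unname(members[ord])
  new("SegmentSet", grid = grid, flagged = flagged, kSd = kSd, table = tb,
      members = members)
}

#' Flagged genome fraction
#'
#' @param segments a [SegmentSet-class].
#' @return flagged-window count / total grid windows.
#' @export
genomeFraction <- function(segments) {
  length(segments@flagged) / nWindows(segments@grid)
}

#' Run the full scan on a simulated dataset
#'
#' Convenience pipeline mirroring the frequency-scan workflow on synthetic
#' data: simulate population frequencies, sample each breed pool's genotypes,
#' compute empirical alternative-allele frequencies, select NFAA sites, count
#' them per window for every breed of the chosen subspecies, average the
#' breed tracks, form Delta, flag and compact.
#'
#' @param config a [SimulationConfig-class].
#' @param subspecies which breed group to scan (default `"A"`, the group
#'   discordant with most of the reference).
#' @param threshold NFAA frequency cutoff.
#' @param kSd flagging threshold multiplier.
#' @param size scanning-window width in bp.
#' @param seed RNG seed; defaults to `config@seed`.
#' @return list with `grid`, per-breed `tracks`, `groupTrack`, `delta`,
#'   `flagged`, `segments` and `truthWindows` (grid indices of windows
#'   overlapping planted segments).
#' @export
runNfaaScan <- function(config, subspecies = "A", threshold = 0.95,
                        kSd = 1.5, size = 1e6, seed = config@seed) {
  sim <- simulateSiteFrequencies(config, seed = seed)
  grid <- windowGrid(config@layout, size)
  b <- config@breeds[config@breeds$subspecies %in% subspecies, , drop = FALSE]
  if (nrow(b) == 0) .stopf("no breeds with subspecies %s", subspecies)
  tracks <- lapply(seq_len(nrow(b)), function(j) {
    bj <- match(b$name[j], config@breeds$name)
    geno <- sampleGenotypes(sim$popFreq[, bj], b$n[j], seed = seed + bj)
    nChr <- 2L * b$n[j]
    freqs <- data.frame(chrom = sim$sites$chrom, pos = sim$sites$pos,
                        n_chr = nChr, alt_freq = colSums(geno) / nChr,
                        stringsAsFactors = FALSE)
    attr(freqs, "breed") <- b$name[j]
    countInWindows(selectNfaa(freqs, threshold), grid)
  })
  group <- groupMeanTrack(tracks, label = paste0("subspecies_", paste(subspecies, collapse = "")))
  delta <- deltaTrack(group)
  flagged <- flagWindows(delta, kSd)
  segments <- compactSegments(flagged, delta, kSd)
  truth <- which(GenomicRanges::countOverlaps(grid@windows,
                                              config@plantedSegments) > 0)
  list(grid = grid, tracks = tracks, groupTrack = group, delta = delta,
       flagged = flagged, segments = segments, truthWindows = truth)
}

#' Precision and recall of flagged windows against planted truth
#'
#' @param flagged integer vector of flagged window indices.
#' @param truth integer vector of planted (truth) window indices.
#' @return named numeric vector `c(precision, recall)`.
#' @export
recoveryStats <- function(flagged, truth) {
  tp <- length(intersect(flagged, truth))
  c(precision = if (length(flagged)) tp / length(flagged) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_)
}
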