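# Reference-haplotype validation: build the all-reference pseudo-individual,
# merge per-breed genotype matrices to the shared biallelic site set,
# partition sites by segment class, run PCA, and exchange files with an
# external admixture-model tool.

#' GenotypeMatrix constructor
#'
#' @param dosage integer matrix (samples x sites) of dosages in \{0, 1, 2\}.
#' @param samples data.frame with columns `id`, `label` (or a character
#'   vector of ids).
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return A validated [GenotypeMatrix-class].
#' @export
genotypeMatrix <- function(dosage, samples, sites) {
  if (is.character(samples))
    samples <- data.frame(id = samples, label = NA_character_,
                          stringsAsFactors = FALSE)
  storage.mode(dosage) <- "integer"
  new("GenotypeMatrix", dosage = dosage, samples = samples,
      sites = as.data.frame(sites))
}

#' GenotypeMatrix from a parsed VCF
#'
#' Keeps biallelic sites with complete diploid calls.
#'
#' @param vcfSites list from [readVcfSites()].
#' @param label population label for all samples.
#' @return A [GenotypeMatrix-class].
#' @export
vcfToGenotypeMatrix <- function(vcfSites, label = NA_character_) {
  s <- vcfSites$sites
  d <- vcfSites$dosage
  keep <- s$n_alleles == 2L & rowSums(is.na(d)) == 0
  genotypeMatrix(t(d[keep, , drop = FALSE]),
                 data.frame(id = colnames(d), label = label,
                            stringsAsFactors = FALSE),
                 s[keep, c("chrom", "pos", "ref", "alt")])
}

#' Build the all-reference pseudo-sample ("reference haplotype")
#'
#' An artificial individual homozygous for the reference allele (dosage 0) at
#' every site, used to place the assembly itself in PCA / admixture space.
#'
#' @param sites data.frame of sites (`chrom`, `pos`, `ref`, `alt`), e.g.
#'   `siteInfo(x)` of a merged matrix.
#' @param id sample id for the pseudo-individual.
#' @param label population label (default `"reference"`).
#' @return A single-sample [GenotypeMatrix-class] of zeros.
#' @export
referenceHaplotype <- function(sites, id = "reference_hap", label = "reference") {
  if (nrow(sites) == 0) .stopf("referenceHaplotype: empty site index")
  genotypeMatrix(matrix(0L, nrow = 1, ncol = nrow(sites)),
                 data.frame(id = id, label = label, stringsAsFactors = FALSE),
                 sites)
}

#' Merge genotype matrices on shared biallelic sites
#'
#' Sites are keyed by (chrom, pos) and intersected across all inputs so that
#' no dosage is missing after the merge. Sites showing more than two distinct
#' alleles across the union are removed (triallelic removal; count reported).
#' Where two inputs carry the same two alleles with ref and alt exchanged,
#' dosages are reconciled by flipping (`2 - dosage`); sites with
#' irreconcilable alleles are dropped. Duplicate sample ids are an error.
#'
#' @param matrices list of [GenotypeMatrix-class] objects.
#' @param verbose message removal counts.
#' @return the merged [GenotypeMatrix-class].
#' @export
mergeGenotypes <- function(matrices, verbose = TRUE) {
  stopifnot(length(matrices) >= 1)
  ids <- unlist(lapply(matrices, function(m) m@samples$id))
  if (anyDuplicated(ids))
    .stopf("duplicate sample id '%s' across inputs", ids[duplicated(ids)][1])
  keys <- lapply(matrices, function(m) paste(m@sites$chrom, m@sites$pos))
  shared <- Reduce(intersect, keys)
  idx <- lapply(keys, match, x = shared)
  ref1 <- matrices[[1]]@sites$ref[idx[[1]]]
  alt1 <- matrices[[1]]@sites$alt[idx[[1]]]
  nShared <- length(shared)
  flip <- matrix(FALSE, nrow = length(matrices), ncol = nShared)
  multi <- grepl(",", alt1, fixed = TRUE)
  irrec <- rep(FALSE, nShared)
  for (j in seq_along(matrices)[-1]) {
    sj <- matrices[[j]]@sites[idx[[j]], ]
    multi <- multi | grepl(",", sj$alt, fixed = TRUE)
    same <- sj$ref == ref1 & sj$alt == alt1
    swapped <- sj$ref == alt1 & sj$alt == ref1
    # same two alleles observed, orientation exchanged -> dosage flip;
    # a third allele at the key -> multi-allelic; anything else irreconcilable
    union3 <- rep(FALSE, nShared)
    open <- which(!same & !swapped)
    if (length(open))
      union3[open] <- mapply(function(a, b, c, d)
        length(unique(c(a, b, c, d))) > 2,
        ref1[open], alt1[open], sj$ref[open], sj$alt[open])
    multi <- multi | union3
    irrec <- irrec | (!same & !swapped & !union3)
    flip[j, ] <- swapped
  }
  keep <- !multi & !irrec
  if (verbose && any(!keep))
    .msgf("mergeGenotypes: removed %d multi-allelic and %d irreconcilable site(s); %d retained",
          sum(multi), sum(irrec & !multi), sum(keep))
  dosage <- do.call(rbind, lapply(seq_along(matrices), function(j) {
    d <- matrices[[j]]@dosage[, idx[[j]][keep], drop = FALSE]
    f <- flip[j, keep]
    if (any(f)) d[, f] <- 2L - d[, f]
    d
  }))
  samples <- do.call(rbind, lapply(matrices, function(m) m@samples))
  rownames(samples) <- NULL
  sites <- matrices[[1]]@sites[idx[[1]][keep],
                               c("chrom", "pos", "ref", "alt")]
  rownames(sites) <- NULL
  genotypeMatrix(dosage, samples, sites)
}

#' Partition sites by candidate segments
#'
#' Splits a genotype matrix into the sites falling inside the segments
#' (position within `[start_mb * W + 1, end_mb * W]` for some segment) and
#' those outside. Every site lands on exactly one side.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param segments a [SegmentSet-class] (or a `GRanges` of 1-based intervals).
#' @return list with [GenotypeMatrix-class] elements `inside` and `outside`.
#' @export
partitionBySegments <- function(gm, segments) {
  gr <- if (methods::is(segments, "SegmentSet")) segmentRanges(segments)
        else segments
  sites <- gm@sites
  inside <- rep(FALSE, nrow(sites))
  if (length(gr)) {
    siteGr <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos, sites$pos))
    inside <- GenomicRanges::countOverlaps(siteGr, gr) > 0
  }
  subset <- function(keep) genotypeMatrix(gm@dosage[, keep, drop = FALSE],
                                          gm@samples, sites[keep, , drop = FALSE])
  list(inside = subset(inside), outside = subset(!inside))
}

#' Principal component analysis of a dosage matrix
#'
#' Sites are mean-centered and variance-standardized (the usual default for
#' genotype PCA); monomorphic (zero-variance) sites are dropped first. The
#' result is deterministic up to the sign of each component.
#'
#' @param gm a [GenotypeMatrix-class] with >= 2 samples and >= 2 sites.
#' @param nComponents components to retain (default 5); truncated with a
#'   warning when exceeding `min(samples, sites) - 1`.
#' @return A [PcaResult-class].
#' @export
runPca <- function(gm, nComponents = 5) {
  x <- gm@dosage
  if (nrow(x) < 2 || ncol(x) < 2)
    .stopf("runPca: need at least 2 samples and 2 sites")
  v <- apply(x, 2, stats::var)
  x <- x[, v > 0, drop = FALSE]
  if (ncol(x) == 0) .stopf("runPca: no polymorphic sites")
  kMax <- min(nrow(x) - 1, ncol(x))
  if (nComponents > kMax) {
    warning(sprintf("runPca: only %d component(s) available; truncating from %d",
                    kMax, nComponents))
    nComponents <- kMax
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE, rank. = nComponents)
  ev <- pc$sdev^2
  coords <- pc$x[, seq_len(nComponents), drop = FALSE]
  rownames(coords) <- gm@samples$id
  new("PcaResult", coords = coords,
      eigenvalues = ev[seq_len(nComponents)],
      varExplained = (ev / sum(ev))[seq_len(nComponents)],
      samples = gm@samples)
}

#' Export genotypes for an external admixture-model tool
#'
#' Transposed plain-text dialect: one row per site, one space-separated
#' column per sample, dosages 0/1/2. The admixture model itself is fitted by
#' the external tool; only the I/O contract lives here.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportAdmixtureInput <- function(gm, path) {
  utils::write.table(t(gm@dosage), path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Ingest a Q matrix (per-sample ancestry fractions)
#'
#' Parses the K-column table written by the external admixture tool. Rows
#' must sum to 1 within 1e-4.
#'
#' @param path Q-matrix file (whitespace-separated, no header).
#' @param sampleIds optional ids for the rows.
#' @return numeric matrix (samples x K) of ancestry fractions.
#' @export
readQMatrix <- function(path, sampleIds = NULL) {
  q <- as.matrix(utils::read.table(path, header = FALSE))
  bad <- which(abs(rowSums(q) - 1) > 1e-4)
  if (length(bad))
    .stopf("Q-matrix row %d sums to %.6f, not 1", bad[1], rowSums(q)[bad[1]])
  dimnames(q) <- list(sampleIds, paste0("K", seq_len(ncol(q))))
  q
}
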