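# Synthetic multi-breed frequency data from a mosaic-ancestry reference model.
#
# The generative model: the reference assembly carries subspecies-B ancestry
# everywhere except the planted segments (ancestry A). Fixed inter-subspecies
# differences are placed by a homogeneous Poisson process; at each such site
# the subspecies that "owns" an allele carries it at frequency 1 - epsilon.
# The reference base equals the allele of the reference's local ancestry, so a
# breed's alternative-allele frequency at a divergence site is ~1 - epsilon
# where its subspecies differs from the local reference ancestry and ~epsilon
# where it matches; admixed breeds get the admixture-weighted mixture. Shared
# polymorphic sites draw frequencies from a U-shaped Beta(0.5, 0.5),
# independently per breed (sites are unlinked; the scan statistic uses only
# marginal frequencies).

#' SimulationConfig constructor
#'
#' @param layout a [GenomeLayout-class].
#' @param plantedSegments `GRanges` of ancestry-A segments (may be empty), or
#'   a data.frame with columns `chrom`, `start`, `end` (1-based inclusive bp).
#' @param breeds data.frame with columns `name`, `subspecies` (`"A"`/`"B"`),
#'   `admixture` (fraction of subspecies-A ancestry; defaults to 1 for A
#'   breeds and 0 for B breeds when the column is absent), `n` (diploid
#'   individuals).
#' @param divergenceDensity fixed-difference sites per Mb.
#' @param polymorphismDensity shared segregating sites per Mb.
#' @param epsilon residual minor-allele frequency at divergence sites.
#' @param seed integer RNG seed.
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(layout, plantedSegments = GenomicRanges::GRanges(),
                             breeds, divergenceDensity = 1474,
                             polymorphismDensity = 679, epsilon = 0.02,
                             seed = 1L) {
  if (is.data.frame(plantedSegments)) {
    plantedSegments <- GenomicRanges::GRanges(
      plantedSegments$chrom,
      IRanges::IRanges(plantedSegments$start, plantedSegments$end))
  }
  if (!"admixture" %in% names(breeds))
    breeds$admixture <- ifelse(breeds$subspecies == "A", 1, 0)
  breeds <- breeds[, c("name", "subspecies", "admixture", "n")]
  new("SimulationConfig", layout = layout, plantedSegments = plantedSegments,
      breeds = breeds, divergenceDensity = as.numeric(divergenceDensity),
      polymorphismDensity = as.numeric(polymorphismDensity),
      epsilon = as.numeric(epsilon), seed = as.integer(seed))
}

#' Calibrate site densities to target per-window NFAA means
#'
#' Inverts the NFAA detection probabilities so that, at a given pool size and
#' `epsilon`, the expected NFAA density (computed from empirical pool
#' frequencies) in ancestry-discordant windows is `nfaaDiscordant` per Mb and
#' in concordant windows `nfaaConcordant` per Mb. The defaults are the
#' printed group means of a taurine-vs-indicine cattle scan (1162 and 95 per
#' Mb). Detection probabilities: a divergence site at population frequency
#' `1 - epsilon` is detected when the sampled pool count reaches the NFAA
#' cutoff (binomial tail); a polymorphic site draws its frequency from
#' Beta(0.5, 0.5) and is detected with the corresponding beta-binomial tail.
#'
#' @param nfaaDiscordant,nfaaConcordant target NFAA sites per Mb.
#' @param n diploid individuals per breed pool.
#' @param epsilon residual minor-allele frequency at divergence sites.
#' @param threshold NFAA frequency threshold.
#' @return list with `divergenceDensity`, `polymorphismDensity` (per Mb) and
#'   the detection probabilities `pDivergence`, `pPolymorphic`.
#' @export
calibrateDensities <- function(nfaaDiscordant = 1162, nfaaConcordant = 95,
                               n = 8, epsilon = 0.02, threshold = 0.95) {
  nChr <- 2L * n
  x0 <- .minCountAtOrAbove(threshold, nChr)
  pDiv <- stats::pbinom(x0 - 1L, nChr, 1 - epsilon, lower.tail = FALSE)
  x <- x0:nChr
  pPoly <- sum(exp(lchoose(nChr, x) + lbeta(0.5 + x, 0.5 + nChr - x) -
                     lbeta(0.5, 0.5)))
  list(divergenceDensity = (nfaaDiscordant - nfaaConcordant) / pDiv,
       polymorphismDensity = nfaaConcordant / pPoly,
       pDivergence = pDiv, pPolymorphic = pPoly)
}

#' Cattle-like simulation preset
#'
#' A compact stand-in for the real study design: a multi-chromosome autosomal
#' genome with planted ancestry-A segments covering ~13.6% of its length
#' (whole-Mb realization of the 13.7% genome fraction reported for the
#' taurine-introgressed assembly), three pure subspecies-A breeds, three pure
#' subspecies-B breeds and one small, heavily admixed breed labelled B
#' (Bohai-like). Densities are calibrated with [calibrateDensities()] so the
#' group NFAA means land near 1162/Mb (discordant) and 95/Mb (concordant).
#'
#' @param genomeMb total genome size in Mb, spread over `nChrom` equal
#'   chromosomes; planted segments scale with the genome.
#' @param nChrom number of chromosomes.
#' @param breedSet `"all"`, `"A"` (scan group only) or `"pure"` (drop the
#'   admixed breed).
#' @param n diploid individuals per pure breed.
#' @param epsilon residual minor-allele frequency at divergence sites.
#' @param seed integer RNG seed.
#' @return A [SimulationConfig-class].
#' @export
cattlePreset <- function(genomeMb = 250, nChrom = 10,
                         breedSet = c("all", "A", "pure"), n = 8,
                         epsilon = 0.02, seed = 1L) {
  breedSet <- match.arg(breedSet)
  Mb <- 1e6
  chromMb <- genomeMb / nChrom
  layout <- GenomeLayout(paste0("chr", seq_len(nChrom)), rep(chromMb * Mb, nChrom))
  # Segment sizes echo the reported size spectrum: mostly 1-Mb segments with
  # a long tail; total = 13.6% of the genome. Scaled for non-default genomes.
  segTemplate <- data.frame(
    chrom = paste0("chr", c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)),
    startMb = c(5, 10, 18, 2, 7, 20, 12, 4, 10, 3),
    sizeMb = c(1, 1, 1, 1, 2, 2, 3, 4, 8, 11))
  scale <- chromMb / 25
  segTemplate <- segTemplate[segTemplate$chrom %in% layout@chrom, , drop = FALSE]
  sizeMb <- pmax(1, round(segTemplate$sizeMb * scale))
  startMb <- pmin(round(segTemplate$startMb * scale), floor(chromMb) - sizeMb)
  seg <- data.frame(chrom = segTemplate$chrom,
                    start = startMb * Mb + 1,
                    end = (startMb + sizeMb) * Mb)
  breeds <- data.frame(
    name = c("A1", "A2", "A3", "B1", "B2", "B3", "AdxB"),
    subspecies = c("A", "A", "A", "B", "B", "B", "B"),
    admixture = c(1, 1, 1, 0, 0, 0, 0.7),
    n = c(n, n, n, n, n, n, 3))
  breeds <- switch(breedSet,
    all = breeds,
    A = breeds[breeds$subspecies == "A", ],
    pure = breeds[breeds$admixture %in% c(0, 1), ])
  cal <- calibrateDensities(n = n, epsilon = epsilon)
  simulationConfig(layout, seg, breeds,
                   divergenceDensity = cal$divergenceDensity,
                   polymorphismDensity = cal$polymorphismDensity,
                   epsilon = epsilon, seed = seed)
}

#' Build the reference's local-ancestry map
#'
#' @param config a [SimulationConfig-class].
#' @return `GRanges` tiling every chromosome exactly once, with metadata
#'   column `ancestry` (`"A"` inside planted segments, `"B"` elsewhere).
#' @export
buildMosaic <- function(config) {
  methods::validObject(config)
  lay <- config@layout
  genome <- GenomicRanges::GRanges(lay@chrom, IRanges::IRanges(1, lay@lengths))
  planted <- config@plantedSegments
  if (length(planted) == 0) {
    S4Vectors::mcols(genome)$ancestry <- "B"
    return(BiocGenerics::sort(genome, ignore.strand = TRUE))
  }
  GenomeInfoDb::seqlevels(planted) <- GenomeInfoDb::seqlevels(genome)
  rest <- GenomicRanges::setdiff(genome, planted, ignore.strand = TRUE)
  S4Vectors::mcols(planted)$ancestry <- "A"
  S4Vectors::mcols(rest)$ancestry <- "B"
  BiocGenerics::sort(c(planted, rest), ignore.strand = TRUE)
}

#' Fraction of the genome covered by planted segments
#'
#' @param config a [SimulationConfig-class].
#' @return summed planted length / genome length.
#' @export
plantedFraction <- function(config) {
  sum(BiocGenerics::width(config@plantedSegments)) / sum(config@layout@lengths)
}

.BASES <- c("A", "C", "G", "T")

#' Simulate per-breed population site frequencies
#'
#' Places divergence and polymorphic sites along each chromosome (homogeneous
#' Poisson with the configured per-Mb densities, positions de-duplicated) and
#' computes the true population alternative-allele frequency of every breed
#' at every site under the mosaic-ancestry model.
#'
#' @param config a [SimulationConfig-class].
#' @param ancestryMap output of [buildMosaic()]; rebuilt when `NULL`.
#' @param seed RNG seed; defaults to `config@seed`.
#' @return list with `sites` (data.frame: `chrom`, `pos`, `ref`, `alt`,
#'   `category` `"divergence"`/`"polymorphic"`, `refAncestry` `"A"`/`"B"`)
#'   and `popFreq` (numeric matrix, sites x breeds, of population
#'   alternative-allele frequencies in `[0, 1]`).
#' @export
simulateSiteFrequencies <- function(config, ancestryMap = NULL,
                                    seed = config@seed) {
  methods::validObject(config)
  if (is.null(ancestryMap)) ancestryMap <- buildMosaic(config)
  if (!is.null(seed)) set.seed(seed)
  lay <- config@layout
  Mb <- 1e6
  perChrom <- lapply(seq_along(lay@chrom), function(ci) {
    len <- lay@lengths[ci]
    nDiv <- stats::rpois(1, config@divergenceDensity * len / Mb)
    nPoly <- stats::rpois(1, config@polymorphismDensity * len / Mb)
    pos <- sample.int(len, min(nDiv + nPoly, len))
    category <- rep(c("divergence", "polymorphic"),
                    c(min(nDiv, length(pos)), max(0, length(pos) - nDiv)))
    ord <- order(pos)
    data.frame(chrom = lay@chrom[ci], pos = pos[ord], category = category[ord],
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, perChrom)
  siteGr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  hit <- GenomicRanges::findOverlaps(siteGr, ancestryMap, select = "first")
  sites$refAncestry <- S4Vectors::mcols(ancestryMap)$ancestry[hit]
  nSites <- nrow(sites)
  refIdx <- sample.int(4, nSites, replace = TRUE)
  altIdx <- 1 + (refIdx - 1 + sample.int(3, nSites, replace = TRUE)) %% 4
  sites$ref <- .BASES[refIdx]
  sites$alt <- .BASES[altIdx]
  b <- config@breeds
  eps <- config@epsilon
  isDiv <- sites$category == "divergence"
  refIsA <- sites$refAncestry == "A"
  popFreq <- matrix(0, nrow = nSites, ncol = nrow(b),
                    dimnames = list(NULL, b$name))
  for (j in seq_len(nrow(b))) {
    q <- b$admixture[j]                      # subspecies-A ancestry fraction
    fA <- q * (1 - eps) + (1 - q) * eps      # frequency of the A-owned allele
    freq <- numeric(nSites)
    freq[isDiv] <- ifelse(refIsA[isDiv], 1 - fA, fA)
    nPoly <- sum(!isDiv)
    freq[!isDiv] <- stats::rbeta(nPoly, 0.5, 0.5)
    popFreq[, j] <- freq
  }
  list(sites = sites, popFreq = popFreq)
}

#' Sample diploid genotypes from population frequencies
#'
#' Each individual's dosage at a site is drawn Binomial(2, freq); no missing
#' genotypes are produced (matching a 100% call-rate dataset).
#'
#' @param freqs numeric vector of per-site alternative-allele frequencies.
#' @param n number of diploid individuals.
#' @param seed RNG seed, or `NULL` to continue the current stream.
#' @return integer matrix (individuals x sites) of dosages in \{0, 1, 2\}.
#' @export
sampleGenotypes <- function(freqs, n, seed = NULL) {
  stopifnot(all(freqs >= 0 & freqs <= 1))
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rbinom(n * length(freqs), 2L, rep(freqs, each = n)),
         nrow = n)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits, for each breed, a multi-sample VCF and a `--freq2`-dialect
#' frequency table (frequencies computed from the sampled genotypes, so the
#' table and the VCF agree exactly), plus a chromosome-length table, a truth
#' BED of the planted segments (0-based half-open) and a YAML echo of the
#' configuration. Re-running with the same config and seed is byte-identical.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @return invisible list of written file paths, plus the simulated truth
#'   (`sites`, `popFreq`) for downstream checks.
#' @export
emitDataset <- function(config, dir) {
  methods::validObject(config)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    .stopf("cannot create output directory '%s'", dir)
  sim <- simulateSiteFrequencies(config, seed = config@seed)
  lay <- config@layout
  files <- list()
  b <- config@breeds
  for (j in seq_len(nrow(b))) {
    geno <- sampleGenotypes(sim$popFreq[, j], b$n[j],
                            seed = config@seed + j)
    nChr <- 2L * b$n[j]
    altCount <- colSums(geno)
    freqTab <- data.frame(chrom = sim$sites$chrom, pos = sim$sites$pos,
                          n_alleles = 2L, n_chr = nChr,
                          freqs = I(lapply(altCount, function(ac)
                            c((nChr - ac) / nChr, ac / nChr))))
    vcfPath <- file.path(dir, sprintf("%s.vcf", b$name[j]))
    frqPath <- file.path(dir, sprintf("%s.frq", b$name[j]))
    writeVcfGenotypes(sim$sites, t(geno),
                      sprintf("%s_%02d", b$name[j], seq_len(b$n[j])),
                      lay, vcfPath)
    writeFreq2(freqTab, frqPath)
    files[[b$name[j]]] <- c(vcf = vcfPath, frq = frqPath)
  }
  chromPath <- file.path(dir, "chrom_lengths.tsv")
  writeChromLengths(lay, chromPath, writeAutosomeFlag = TRUE)
  bedPath <- file.path(dir, "truth_segments.bed")
  seg <- config@plantedSegments
  S4Vectors::mcols(seg)$name <- sprintf("planted_%d", seq_along(seg))
  writeBed(seg, bedPath)
  cfgPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    chrom_lengths_bp = as.list(stats::setNames(lay@lengths, lay@chrom)),
    planted_segments = if (length(seg)) data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(seg)),
      start_bp = BiocGenerics::start(seg), end_bp = BiocGenerics::end(seg))
      else list(),
    breeds = b,
    divergence_density_per_mb = config@divergenceDensity,
    polymorphism_density_per_mb = config@polymorphismDensity,
    epsilon = config@epsilon,
    seed = config@seed), cfgPath)
  invisible(list(files = files, chromLengths = chromPath, truthBed = bedPath,
                 config = cfgPath, sites = sim$sites, popFreq = sim$popFreq))
}
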