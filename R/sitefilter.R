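# Per-breed alternative-allele frequencies, retention filters, NFAA selection.
#
# Retention mirrors the frequency-table pipeline: only biallelic autosomal
# sites at which every sample has a diploid, non-missing genotype (100% call
# rate) are kept. Frequencies may enter either from genotypes or from a
# pre-made freq2 table; both paths agree exactly on the same data.

#' Compute retained per-breed alternative-allele frequencies
#'
#' @param x either the list returned by [readVcfSites()] (elements `sites`,
#'   `dosage`) or a [GenotypeMatrix-class].
#' @param layout a [GenomeLayout-class] designating the autosomes.
#' @param breed label recorded in the result.
#' @param verbose message per-reason drop counts.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `n_chr`,
#'   `alt_freq`, restricted to retained sites, with attributes `breed` and
#'   `dropped` (named counts per drop reason).
#' @export
altFrequencies <- function(x, layout, breed = NA_character_, verbose = TRUE) {
  if (methods::is(x, "GenotypeMatrix")) {
    sites <- x@sites
    dosage <- t(x@dosage)
  } else {
    sites <- x$sites
    dosage <- x$dosage
  }
  nSamples <- ncol(dosage)
  if (nSamples == 0) .stopf("altFrequencies: zero samples")
  if (!"n_alleles" %in% names(sites))
    sites$n_alleles <- 2L + nchar(sites$alt) - nchar(gsub(",", "", sites$alt, fixed = TRUE))
  multi <- sites$n_alleles != 2L
  nonAuto <- !(sites$chrom %in% autosomeNames(layout))
  missing <- rowSums(is.na(dosage)) > 0
  keep <- !multi & !nonAuto & !missing
  dropped <- c(multiallelic = sum(multi), non_autosomal = sum(nonAuto & !multi),
               call_rate = sum(missing & !multi & !nonAuto))
  if (verbose && sum(dropped) > 0)
    .msgf("altFrequencies: dropped %d multiallelic, %d non-autosomal, %d incomplete-call site(s)",
          dropped[1], dropped[2], dropped[3])
  out <- data.frame(chrom = sites$chrom[keep], pos = sites$pos[keep],
                    ref = sites$ref[keep], alt = sites$alt[keep],
                    n_chr = 2L * nSamples,
                    alt_freq = rowSums(dosage[keep, , drop = FALSE]) / (2 * nSamples),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "breed") <- breed
  attr(out, "dropped") <- dropped
  out
}

#' Alternative-allele frequencies from a freq2 table
#'
#' Applies the same retention rules as [altFrequencies()] to a parsed
#' `--freq2` table: biallelic sites on autosomes whose called-chromosome
#' count reaches `expectedNChr` (100% call rate). When `expectedNChr` is
#' `NULL` the maximum `n_chr` in the table is used.
#'
#' @param records data.frame from [readFreq2()].
#' @param layout a [GenomeLayout-class].
#' @param breed label recorded in the result.
#' @param expectedNChr chromosome count at full call rate, or `NULL`.
#' @param verbose message per-reason drop counts.
#' @return data.frame as from [altFrequencies()] (without `ref`/`alt`).
#' @export
freq2AltFrequencies <- function(records, layout, breed = NA_character_,
                                expectedNChr = NULL, verbose = TRUE) {
  if (nrow(records) == 0) .stopf("freq2AltFrequencies: empty table")
  if (is.null(expectedNChr)) expectedNChr <- max(records$n_chr)
  multi <- records$n_alleles != 2L
  nonAuto <- !(records$chrom %in% autosomeNames(layout))
  lowCall <- records$n_chr < expectedNChr
  keep <- !multi & !nonAuto & !lowCall
  dropped <- c(multiallelic = sum(multi), non_autosomal = sum(nonAuto & !multi),
               call_rate = sum(lowCall & !multi & !nonAuto))
  if (verbose && sum(dropped) > 0)
    .msgf("freq2AltFrequencies: dropped %d multiallelic, %d non-autosomal, %d low-call-rate site(s)",
          dropped[1], dropped[2], dropped[3])
  out <- data.frame(chrom = records$chrom[keep], pos = records$pos[keep],
                    n_chr = records$n_chr[keep],
                    alt_freq = vapply(records$freqs[keep], `[`, numeric(1), 2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "breed") <- breed
  attr(out, "dropped") <- dropped
  out
}

#' Select nearly fixed alternative allele (NFAA) sites
#'
#' Keeps sites whose alternative-allele frequency is greater than or equal to
#' `threshold` (inclusive: a site at exactly the threshold is retained).
#'
#' @param freqs data.frame from [altFrequencies()] or [freq2AltFrequencies()].
#' @param threshold NFAA frequency cutoff in `(0, 1]`; default 0.95.
#' @return the NFAA subset, sorted by (chrom, pos), with attributes
#'   `threshold` and `breed` carried over.
#' @export
selectNfaa <- function(freqs, threshold = 0.95) {
  if (length(threshold) != 1 || !is.finite(threshold) ||
      threshold <= 0 || threshold > 1)
    .stopf("threshold must lie in (0, 1], got %s", format(threshold))
  out <- freqs[freqs$alt_freq >= threshold, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "breed") <- attr(freqs, "breed")
  out
}
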