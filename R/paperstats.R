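# Paired comparisons of per-breed SNV counts between two reference
# assemblies: per-breed paired differences, rounded mean difference, and the
# paired (one-sample) t-test on the differences. The packaged fixture holds
# the per-breed SNV counts of 15 cattle breeds called against the taurine
# ARS_UCD1.2 and the indicine UOA_Brahman_1 assemblies.

#' Load the per-breed SNV count table
#'
#' @param path TSV with columns `breed`, `subspecies` (`taurus`/`indicus`),
#'   `ars_ucd12_snvs`, `uoa_brahman1_snvs`; defaults to the packaged table.
#' @return data.frame with those columns.
#' @export
snvCountTable <- function(path = system.file("extdata", "snv_counts_by_breed.tsv",
                                             package = "nfaaScan")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("breed", "subspecies", "ars_ucd12_snvs", "uoa_brahman1_snvs")
  if (!all(need %in% names(df)))
    .stopf("SNV count table must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$breed)) .stopf("breed names must be unique")
  if (any(df$ars_ucd12_snvs <= 0 | df$uoa_brahman1_snvs <= 0))
    .stopf("SNV counts must be positive")
  df
}

#' Breeds carrying a subspecies label
#'
#' @param table SNV count table.
#' @param subspecies `"taurus"` or `"indicus"`.
#' @return character vector of breed names.
#' @export
breedsOf <- function(table, subspecies) {
  table$breed[table$subspecies == subspecies]
}

#' Per-breed paired SNV-count differences
#'
#' @param table SNV count table from [snvCountTable()].
#' @param group character vector of breed names.
#' @param direction `"uoa_minus_ars"` or `"ars_minus_uoa"`.
#' @return named numeric vector of differences, in `group` order.
#' @export
pairedDifferences <- function(table, group,
                              direction = c("uoa_minus_ars", "ars_minus_uoa")) {
  direction <- match.arg(direction)
  if (length(group) == 0) .stopf("group must contain at least one breed")
  idx <- match(group, table$breed)
  if (anyNA(idx)) .stopf("unknown breed '%s'", group[is.na(idx)][1])
  d <- table$uoa_brahman1_snvs[idx] - table$ars_ucd12_snvs[idx]
  if (direction == "ars_minus_uoa") d <- -d
  stats::setNames(d, group)
}

#' Mean paired difference, rounded half away from zero
#'
#' @param differences numeric vector from [pairedDifferences()].
#' @return list with `mean` (integer-rounded, half away from zero) and
#'   `meanRaw`.
#' @export
meanPairedDifference <- function(differences) {
  if (length(differences) == 0) .stopf("no differences supplied")
  raw <- mean(differences)
  list(mean = roundHalfAwayFromZero(raw), meanRaw = raw)
}

#' Paired t-test on per-breed differences
#'
#' One-sample two-sided t-test of the differences against zero:
#' `t = mean(d) / (sd(d) / sqrt(n))` with the sample sd and `df = n - 1`.
#'
#' @param differences numeric vector of per-breed paired differences (>= 2).
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
pairedTTest <- function(differences) {
  if (length(differences) < 2)
    .stopf("paired t-test needs at least 2 differences")
  if (stats::sd(differences) == 0)
    .stopf("paired t-test: zero variance among differences")
  ht <- stats::t.test(differences, mu = 0, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Reassign a breed's subspecies label
#'
#' Returns a modified copy; the input table is untouched.
#'
#' @param table SNV count table.
#' @param breed breed to relabel.
#' @param label new subspecies label (`"taurus"` or `"indicus"`).
#' @return the relabelled table.
#' @export
reassignBreed <- function(table, breed, label) {
  if (!breed %in% table$breed) .stopf("unknown breed '%s'", breed)
  if (!label %in% c("taurus", "indicus"))
    .stopf("unknown subspecies label '%s'", label)
  table$subspecies[table$breed == breed] <- label
  table
}
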