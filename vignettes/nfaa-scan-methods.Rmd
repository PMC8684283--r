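---
title: "Detecting introgressed segments in a reference assembly with windowed NFAA scans"
author: "nfaaScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting introgressed segments in a reference assembly with windowed NFAA scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfaaScan)
```

## The problem

When re-sequencing reads are aligned to a genetically divergent reference
genome, variant calling is inflated: many more SNVs are detected, and a large
share of them are *nearly fixed for the alternative allele* (NFAA) — the
whole population carries the non-reference base, because the "variant" is
really a fixed difference between the sample's lineage and the reference's.
nfaaScan turns this artifact into a signal. If a reference assembly is an
ancestry mosaic — for example an indicine (*Bos taurus indicus*) assembly
whose source animal carried taurine (*Bos taurus taurus*) segments from
historic admixture — then aligning *taurine* samples to it produces a high
NFAA density wherever the reference is locally indicine, and a conspicuously
*low* NFAA density wherever the reference is locally taurine. Scanning the
genome for windows depleted of NFAA sites therefore reveals the
ancestry-discordant (introgressed) segments of the assembly itself.

The package implements the full procedure: site filtering and NFAA
selection, the windowed depletion statistic, segment calling, a pseudo
reference-haplotype PCA validation, gene annotation of flagged segments, and
paired comparisons of per-breed SNV counts between alternative assemblies.
A synthetic-data generator with planted segments provides ground truth for
every stage.

## The statistic

For each breed pool, alternative-allele frequencies are computed per site
(`altFrequencies()`, or ingested from a vcftools `--freq2` table with
`freq2AltFrequencies()`), after retaining only biallelic autosomal sites
with a 100% call rate of diploid genotypes. Sites with alternative-allele
frequency at or above 0.95 form the NFAA set (`selectNfaa()`; the threshold
is inclusive).

With non-overlapping scanning windows of width $W$ (default 1 Mb, matching
roughly one centimorgan in cattle), window $i$ of a chromosome covers
positions $[iW + 1, (i+1)W]$ and receives the count

$$A_i = \sum_{\text{NFAA sites } s \in \text{window } i} 1 .$$

Per-breed tracks are averaged across the breeds of a group
(`groupMeanTrack()`); the depletion statistic is

$$\Delta_i = \mu(A) - A_i ,$$

where $\mu(A)$ is the genome-wide mean over **all** grid windows, including
zero-count windows and the truncated terminal window of each chromosome.
Large positive $\Delta$ marks NFAA-depleted windows. Flagged windows are

$$T = \{\, i : \Delta_i > \mu(\Delta) + k \,\mathrm{sd}(\Delta) \,\}, \qquad k = 1.5,$$

with a strict inequality (a window exactly at the threshold is not flagged)
and the sample standard deviation ($n-1$ denominator). Maximal runs of
consecutive flagged windows are compacted into segments
(`compactSegments()`), each reporting its total $\Delta$ and size, and the
flagged genome fraction is `genomeFraction()`.

Two conventions deserve a note. First, the sign of $\Delta$: depletion must
come out *positive* so that flagging with $> \mu + k\,\mathrm{sd}$ selects
depleted windows; hence $\mu(A) - A_i$, not the reverse. Second, $k = 1.5$
rather than a conventional 1.96: on data with genuinely introgressed
segments the $\Delta$ density is bimodal (the depleted windows form their
own right-hand mode), and the threshold is placed to separate the modes, not
to bound a normal tail. On null (unimodal) data the flagged fraction is
simply the one-sided 1.5-sd tail, about 6.7% — the package's tests verify
both behaviours.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` (NFAA) | 0.95 | minimum alternative-allele frequency, inclusive |
| `size` (window) | 1 Mb | scanning-window width in bp |
| `kSd` | 1.5 | flagging multiplier on sd($\Delta$) |
| `nComponents` | 5 | principal components retained |
| `mode` (annotation) | `"contained"` | transcript-in-segment rule |

Counts are not length-normalized in truncated terminal windows: $A_i$ is a
count, and normalizing silently changes the statistic; terminal windows
simply contribute slightly low counts on both sides of the comparison.

## The synthetic generator

`simulationConfig()` describes a two-subspecies model with abstract labels
A and B: the reference is ancestry B everywhere except *planted segments*
(ancestry A). Fixed inter-subspecies differences are placed by a homogeneous
Poisson process (`divergenceDensity` per Mb); at each the owning subspecies
carries its allele at frequency $1-\varepsilon$. The reference base equals
the local ancestry's allele, so a pure subspecies-A breed has population
alternative-allele frequency $\approx 1-\varepsilon$ at divergence sites in
ancestry-B regions and $\approx \varepsilon$ inside planted segments; a
breed with admixture fraction $q$ of A-ancestry gets the $q$-weighted
mixture. Shared polymorphic sites (`polymorphismDensity` per Mb) draw
frequencies from the U-shaped Beta(0.5, 0.5), independently per breed,
giving a realistic low-but-nonzero NFAA background. Genotypes are sampled
Binomial(2, freq) per individual with no missing calls; sites are unlinked
(no LD), which is adequate because the scan uses only marginal frequencies.

The default $\varepsilon = 0.02$ keeps divergence sites above the 0.95
threshold with high probability at modest pool sizes ("nearly fixed"), while
$\varepsilon < 0.05$ is required for them to pass at all.

### Calibration

`calibrateDensities()` inverts the detection probabilities so that the
expected NFAA densities match chosen targets. With $2n$ sampled chromosomes
and threshold $t$, a divergence site is detected with the binomial tail
$P\{\mathrm{Bin}(2n, 1-\varepsilon) \ge \lceil 2nt \rceil\}$ and a
polymorphic site with the corresponding Beta(0.5,0.5)-binomial tail. The
defaults target 1162 NFAA/Mb in discordant windows and 95/Mb in concordant
ones — the group means printed for a taurine-vs-indicine-assembly cattle
scan — giving, at $n = 8$ and $\varepsilon = 0.02$, about 1474 divergence
and 679 polymorphic sites per Mb.

`cattlePreset()` assembles the full study-like configuration: a 250-Mb
genome over 10 chromosomes (a deliberate ~10x scale-down of a 2.5-Gb cattle
genome, keeping per-Mb densities and window counts realistic while staying
fast), planted segments covering 34 Mb = 13.6% of the genome (the nearest
whole-Mb realization of the 13.7% flagged fraction reported for the
indicine assembly, with a size spectrum from 1-Mb segments up to an 11-Mb
one), three pure A breeds, three pure B breeds ($n = 8$ each, within the
3–16 range of real per-breed pools) and one small heavily admixed breed
labelled B (three individuals, 70% A-ancestry — a Bohai-like case).

What the generator does *not* emulate: linkage disequilibrium,
recombination-map structure, mutation-rate heterogeneity, alignment and
calling error, and reference-bias effects on read mapping itself. Passing
tests therefore demonstrate that the statistic recovers planted
frequency-structure signals, not that it is robust to every artifact of
real pipelines.

## Validation by reference-haplotype PCA

`referenceHaplotype()` constructs a pseudo-individual homozygous for the
reference allele at every site (dosage 0). After merging per-breed genotype
matrices (`mergeGenotypes()`: sites intersected on (chrom, pos), sites with
a third allele across the union removed, swapped ref/alt orientations
reconciled by dosage flip), `partitionBySegments()` splits sites into those
inside and outside the flagged segments, and `runPca()` (mean-centered,
variance-standardized dosages, monomorphic sites dropped) places the
pseudo-sample. If the flagged segments truly carry A-ancestry, the
pseudo-sample clusters with subspecies B on outside-segment sites and jumps
to the subspecies-A cluster on inside-segment sites. The admixture-model
step is delegated to the external tool by design; the package only exports
its transposed-text genotype input (`exportAdmixtureInput()`) and ingests
the resulting Q matrix (`readQMatrix()`).

## Numerical choices and degenerate inputs

* Hard site filters follow the strict printed inequalities (`QD < 2.0`,
  `QUAL < 30.0`, `MQ < 40.0`, `SOR > 3.0`, `FS > 60.0`,
  `MQRankSum < -12.5`, `ReadPosRankSum < -8.0`); boundary values pass, and
  an absent or missing metric is not evaluated (it cannot fail a site),
  matching the behaviour of the standard variant-filtration tool.
* Rounded integer summaries use round-half-away-from-zero; the published
  group means of the packaged SNV table are only reproducible under this
  rule (e.g. 30,092,547 / 6 = 5,015,424.5 → 5,015,425), so banker's
  rounding is deliberately not used.
* A constant count track has sd 0 and makes z-scores and flagging
  undefined; both raise errors rather than returning NaN.
* freq2 frequencies are serialized with 10 decimals; round-trips are exact
  to 1e-9 (exact decimal identity is impossible for denominators like 6).
* Windows are addressed by their 0-based Mb start; segment tables report
  `start_mb` inclusive, `end_mb` exclusive, `size_mb = end - start`. BED
  exports convert to 0-based half-open bp.
* The paired t-test is the one-sample two-sided test on per-breed
  differences, df = n − 1; zero-variance difference vectors are an error.

## Open design points, resolved

* *Averaging vs pooling across breeds before flagging*: both are available
  (`groupMeanTrack()` vs concatenating NFAA sets); the mean across breed
  tracks is the default, since the group curves being averaged are the
  published presentation and pooling would weight breeds by their site
  counts.
* *Containment vs overlap for gene assignment*: "transcripts located within
  the window" reads as containment, which is the default; `mode = "overlap"`
  is exposed because the phrasing is ambiguous, and overlap-mode results are
  provably a superset.
* *Autosome identification*: rather than guessing which contigs are sex
  chromosomes, `GenomeLayout` requires an explicit autosome flag.
* *Single-individual pools*: the NFAA rule is applied uniformly; a pool of
  one diploid individual can only have frequencies 0, 0.5, 1, so its NFAA
  set is its homozygous-alternative sites.

## Problem sizes used by the tests and the acceptance script

Scan recovery runs on the 250-Mb preset (250 windows, ~540k sites per
breed, 3 breeds, 20 seeds in the tests); the PCA validation on a 20-Mb
two-chromosome genome with six breeds of four individuals (20 seeds); the
null calibration on 10,000 windows; the oracle-equivalence checks on twenty
small simulated genomes. These sizes keep every stochastic check
well-powered (binomial/Poisson standard errors a few percent or less of the
quantities asserted) while the whole suite stays fast.

## Known limitations

The statistic detects *depletion of fixed differences*, so it cannot
distinguish introgression in the reference from any other cause of locally
reduced divergence (e.g. a mis-assembled or duplicated region aligning
reads from both lineages). Window-level resolution is 1 Mb; short
introgressed tracts are diluted and boundary windows are classified by
their majority signal. The generator's independence assumptions mean
false-positive rates on real, LD-structured data may differ from the
simulated ones. Finally, with few breeds in the scanned group the
breed-mean track inherits each breed's sampling noise; the calibration
tail probabilities quantify how the NFAA detection rate falls as pool
size shrinks.
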