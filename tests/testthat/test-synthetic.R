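# Synthetic mosaic-ancestry generator: ancestry map, site frequencies,
# genotype sampling, dataset emission.

test_that("mosaic ancestry map covers the genome and respects planted segments", {
  lay <- GenomeLayout("chr1", 1e7)
  breeds <- data.frame(name = "A1", subspecies = "A", n = 2)

  cfgEmpty <- simulationConfig(lay, breeds = breeds, seed = 1L)
  mapEmpty <- buildMosaic(cfgEmpty)
  expect_true(all(S4Vectors::mcols(mapEmpty)$ancestry == "B"))
  expect_equal(sum(BiocGenerics::width(mapEmpty)), 1e7)

  cfg <- simulationConfig(lay, data.frame(chrom = "chr1", start = 3e6 + 1, end = 5e6),
                          breeds = breeds, seed = 1L)
  expect_equal(plantedFraction(cfg), 0.2)
  map <- buildMosaic(cfg)
  expect_equal(sum(BiocGenerics::width(map)), 1e7)
  aWidth <- sum(BiocGenerics::width(map)[S4Vectors::mcols(map)$ancestry == "A"])
  expect_equal(aWidth / 1e7, 0.2)

  expect_error(
    simulationConfig(lay, data.frame(chrom = c("chr1", "chr1"),
                                     start = c(3e6, 4e6), end = c(5e6, 6e6)),
                     breeds = breeds, seed = 1L),
    "overlap")
  expect_error(
    simulationConfig(lay, data.frame(chrom = "chr1", start = 9e6, end = 1.2e7),
                     breeds = breeds, seed = 1L),
    "bounds")
})

test_that("divergence-site frequencies follow the mosaic ancestry model", {
  lay <- GenomeLayout("chr1", 2e6)
  seg <- data.frame(chrom = "chr1", start = 1, end = 1e6)  # ancestry A half
  breeds <- data.frame(name = c("pureA", "pureB", "half"),
                       subspecies = c("A", "B", "B"),
                       admixture = c(1, 0, 0.5), n = 2)
  cfg <- simulationConfig(lay, seg, breeds, divergenceDensity = 500,
                          polymorphismDensity = 100, epsilon = 0, seed = 11L)
  sim <- simulateSiteFrequencies(cfg)
  div <- sim$sites$category == "divergence"
  refA <- sim$sites$refAncestry == "A"
  # concordant ancestry: no fixed differences against the reference base
  expect_true(all(sim$popFreq[div & refA, "pureA"] == 0))
  expect_true(all(sim$popFreq[div & !refA, "pureB"] == 0))
  # discordant ancestry: alternative allele fixed
  expect_true(all(sim$popFreq[div & !refA, "pureA"] == 1))
  expect_true(all(sim$popFreq[div & refA, "pureB"] == 1))
  # 50:50 admixture at epsilon 0 gives exactly 0.5 everywhere at divergence sites
  expect_true(all(sim$popFreq[div, "half"] == 0.5))
  expect_true(all(sim$popFreq >= 0 & sim$popFreq <= 1))
})

test_that("divergence site counts match the configured density", {
  lay <- GenomeLayout("chr1", 1e7)
  cfg <- simulationConfig(lay,
                          breeds = data.frame(name = "A1", subspecies = "A", n = 2),
                          divergenceDensity = 1000, polymorphismDensity = 0,
                          epsilon = 0.01, seed = 5L)
  sim <- simulateSiteFrequencies(cfg)
  nDiv <- sum(sim$sites$category == "divergence")
  # Poisson(10000): 4 sd tolerance
  expect_lt(abs(nDiv - 10000), 4 * sqrt(10000))
  expect_true(all(abs(sim$popFreq[, "A1"] - 0.99) < 1e-12))
})

test_that("sampled genotypes honor degenerate and intermediate frequencies", {
  expect_true(all(sampleGenotypes(rep(0, 50), 10, seed = 1) == 0))
  expect_true(all(sampleGenotypes(rep(1, 50), 10, seed = 1) == 2))
  g <- sampleGenotypes(0.5, 5000, seed = 2)   # 10 000 haplotypes
  expect_lt(abs(mean(g) / 2 - 0.5), 3 * sqrt(0.25 / 10000))
  expect_true(all(g %in% 0:2))
  # reproducible under a fixed seed
  expect_identical(sampleGenotypes(c(0.2, 0.7), 5, seed = 9),
                   sampleGenotypes(c(0.2, 0.7), 5, seed = 9))
})

test_that("dataset emission is deterministic and round-trips the truth", {
  cfg <- smallConfig(seed = 21L, n = 3, lenMb = c(2, 2),
                     segments = data.frame(chrom = "chr1", start = 1, end = 1e6),
                     breeds = data.frame(name = c("A1", "B1"),
                                         subspecies = c("A", "B"), n = 3))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out <- suppressMessages(emitDataset(cfg, d1))
  suppressMessages(emitDataset(cfg, d2))
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)

  truth <- readBed(out$truthBed)
  expect_equal(BiocGenerics::start(truth), 1)
  expect_equal(BiocGenerics::end(truth), 1e6)

  lay2 <- readChromLengths(out$chromLengths)
  expect_equal(unname(chromLengths(lay2)), c(2e6, 2e6))

  vcf <- readVcfSites(out$files$A1["vcf"])
  expect_true(all(vcf$dosage %in% 0:2))
  frq <- readFreq2(out$files$A1["frq"])
  expect_true(all(unlist(frq$freqs) >= 0 & unlist(frq$freqs) <= 1))
  expect_equal(nrow(frq), nrow(vcf$sites))
})

test_that("calibrated densities reproduce the target NFAA scale", {
  cal <- calibrateDensities(nfaaDiscordant = 1162, nfaaConcordant = 95,
                            n = 8, epsilon = 0.02)
  # A 20-Mb all-discordant genome for a pure subspecies-A breed:
  lay <- GenomeLayout("chr1", 2e7)
  cfg <- simulationConfig(lay,
                          breeds = data.frame(name = "A1", subspecies = "A", n = 8),
                          divergenceDensity = cal$divergenceDensity,
                          polymorphismDensity = cal$polymorphismDensity,
                          epsilon = 0.02, seed = 31L)
  sim <- simulateSiteFrequencies(cfg)
  g <- sampleGenotypes(sim$popFreq[, 1], 8, seed = 32L)
  freqs <- data.frame(chrom = sim$sites$chrom, pos = sim$sites$pos,
                      alt_freq = colSums(g) / 16)
  nfaa <- selectNfaa(freqs)
  dens <- nrow(nfaa) / 20
  expect_lt(abs(dens - 1162), 60)   # ~5 se of the 20-window mean
})

test_that("NFAA density is higher in discordant than concordant windows", {
  for (eps in c(0, 0.02, 0.045)) {
    cfg <- smallConfig(seed = 40L + round(100 * eps), n = 4, epsilon = eps,
                       breeds = data.frame(name = "A1", subspecies = "A", n = 4))
    res <- runNfaaScan(cfg, subspecies = "A")
    a <- windowCounts(res$groupTrack)
    expect_gt(mean(a[-res$truthWindows]), mean(a[res$truthWindows]),
              label = sprintf("epsilon = %.3f", eps))
  }
})

test_that("frequency simulation is seed-deterministic", {
  cfg <- smallConfig(seed = 77L, lenMb = c(2, 2))
  s1 <- simulateSiteFrequencies(cfg)
  s2 <- simulateSiteFrequencies(cfg)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$popFreq, s2$popFreq)
  s3 <- simulateSiteFrequencies(cfg, seed = 78L)
  expect_false(identical(s1$popFreq, s3$popFreq))
})
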