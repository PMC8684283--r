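# The windowed scan statistic: A_i counts, z-scores, Delta, flagging,
# segment compaction and genome fraction.

test_that("sites land in windows by floor((pos - 1) / W)", {
  grid <- windowGrid(twoChromLayout(c(3, 2)), 1e6)
  expect_equal(nWindows(grid), 5)
  nfaa <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                     pos = c(1L, 1000000L, 1000001L, 1L))
  tr <- countInWindows(nfaa, grid)
  expect_equal(windowCounts(tr), c(2, 1, 0, 1, 0))  # 1 and 1e6 share window 0
  expect_equal(sum(windowCounts(tr)), nrow(nfaa))

  empty <- countInWindows(data.frame(chrom = character(0), pos = integer(0)), grid)
  expect_true(all(windowCounts(empty) == 0))

  expect_error(countInWindows(data.frame(chrom = "chr2", pos = 2000001L), grid),
               "outside")
  expect_error(countInWindows(data.frame(chrom = "chr9", pos = 5L), grid),
               "chromosome")
})

test_that("window counting matches a brute-force overlap recount", {
  set.seed(71)
  for (i in 1:5) {
    lenMb <- sample(3:8, 2)
    grid <- windowGrid(twoChromLayout(lenMb), 1e6)
    n <- 2000
    chrom <- sample(paste0("chr", 1:2), n, replace = TRUE)
    pos <- vapply(chrom, function(cm)
      sample.int(lenMb[as.integer(sub("chr", "", cm))] * 1e6, 1), integer(1))
    tr <- countInWindows(data.frame(chrom = chrom, pos = pos), grid)
    oracle <- GenomicRanges::countOverlaps(
      gridWindows(grid),
      GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos)))
    expect_equal(windowCounts(tr), as.numeric(oracle))
    expect_equal(sum(windowCounts(tr)), n)
  }
})

test_that("group track is the per-window mean across breed tracks", {
  t1 <- trackFromCounts(c(4, 0, 8))
  t2 <- trackFromCounts(c(10, 2, 0))
  expect_equal(windowCounts(groupMeanTrack(list(t1))), windowCounts(t1))
  expect_equal(windowCounts(groupMeanTrack(list(t1, t2))), c(7, 1, 4))
  expect_equal(windowCounts(groupMeanTrack(list(t1, t1, t1))), windowCounts(t1))
  other <- trackFromCounts(c(1, 2, 3, 4))
  expect_error(groupMeanTrack(list(t1, other)), "grids")
})

test_that("z-scores standardize and are idempotent", {
  tr <- trackFromCounts(c(0, 10, 20))
  expect_equal(zscoreTrack(tr), c(-1, 0, 1))
  z <- zscoreTrack(tr)
  zz <- zscoreTrack(new("WindowCountTrack", grid = tr@grid, counts = z + 10,
                        label = "z"))  # shift keeps counts valid
  expect_equal(zz, z)
  expect_lt(abs(mean(z)), 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_error(zscoreTrack(trackFromCounts(c(5, 5, 5))), "constant")
})

test_that("Delta is mean(A) - A_i and conserves mass", {
  tr <- trackFromCounts(c(10, 2, 12))
  d <- deltaTrack(tr)
  expect_equal(deltaValues(d), c(-2, 6, -4))
  expect_equal(deltaStats(d)$meanA, 8)
  expect_equal(deltaTrack(trackFromCounts(c(3, 3, 3)))@delta, c(0, 0, 0))
  set.seed(81)
  for (i in 1:10) {
    d <- deltaTrack(trackFromCounts(rpois(50, 100)))
    expect_lt(abs(sum(deltaValues(d))), 1e-6 * 50)
    expect_lt(abs(deltaStats(d)$meanDelta), 1e-6)
  }
})

test_that("flagging uses a strict threshold on Delta", {
  d <- deltaTrack(trackFromCounts(c(10, 2, 12)))  # Delta = (-2, 6, -4)
  expect_equal(deltaStats(d)$sdDelta, sd(c(-2, 6, -4)))
  # threshold 1.5 * 5.2915 = 7.937 > max Delta -> nothing flagged
  expect_length(flagWindows(d, 1.5), 0)
  # counts (0,4,4,4): Delta = (3,-1,-1,-1), sd(Delta) = 2 exactly, so the
  # 1.5-sd threshold is exactly 3 = max Delta: strict > leaves it unflagged
  dx <- deltaTrack(trackFromCounts(c(0, 4, 4, 4)))
  expect_equal(deltaStats(dx)$sdDelta, 2)
  expect_length(flagWindows(dx, 1.5), 0)
  expect_equal(flagWindows(dx, 1.49), 1L)
  expect_error(flagWindows(d, 0), "positive")
  expect_error(flagWindows(deltaTrack(trackFromCounts(c(4, 4, 4))), 1.5), "sd")
})

test_that("flagged-set size is monotone in the threshold multiplier", {
  set.seed(91)
  d <- deltaTrack(trackFromCounts(rpois(400, 50)))
  n <- vapply(c(1.0, 1.5, 2.0), function(k) length(flagWindows(d, k)), numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("segment compaction merges maximal runs and reports Table-style fields", {
  d <- deltaTrack(trackFromCounts(rep(c(10, 0), c(30, 10))))
  seg <- compactSegments(c(6L, 7L, 8L, 11L), d)
  tb <- segmentTable(seg)
  expect_equal(nrow(tb), 2)
  expect_equal(tb$start_mb, c(5, 10))              # 0-based window starts
  expect_equal(tb$end_mb, c(8, 11))
  expect_equal(tb$size_mb, c(3, 1))
  expect_equal(tb$total_delta,
               c(sum(deltaValues(d)[6:8]), deltaValues(d)[11]))

  # a run spanning windows 14..29 prints start 14, end 30, size 16
  seg2 <- compactSegments(15:30, d)
  tb2 <- segmentTable(seg2)
  expect_equal(tb2[, c("start_mb", "end_mb", "size_mb")],
               data.frame(start_mb = 14, end_mb = 30, size_mb = 16))

  empty <- compactSegments(integer(0), d)
  expect_equal(nrow(segmentTable(empty)), 0)
  expect_equal(genomeFraction(empty), 0)
})

test_that("segments never merge across chromosome boundaries", {
  grid <- windowGrid(twoChromLayout(c(3, 3)), 1e6)
  counts <- c(0, 0, 10, 10, 0, 0)
  tr <- new("WindowCountTrack", grid = grid, counts = counts, label = "x")
  d <- deltaTrack(tr)
  # windows 3 (chr1, last) and 4 (chr2, first) are consecutive rows but on
  # different chromosomes
  seg <- compactSegments(c(1L, 2L, 4L), d)
  tb <- segmentTable(seg)
  expect_equal(nrow(tb), 2)
  expect_equal(tb$chrom, c("chr1", "chr2"))
})

test_that("genome fraction is flagged windows over all windows", {
  lay <- GenomeLayout(c("chr1", "chr2"), c(1.3e9, 1.193e9))
  grid <- windowGrid(lay, 1e6)
  expect_equal(nWindows(grid), 2493)
  tr <- new("WindowCountTrack", grid = grid,
            counts = rep(c(0, 10), length.out = 2493), label = "x")
  d <- deltaTrack(tr)
  seg <- compactSegments(seq_len(343), d)
  expect_equal(genomeFraction(seg), 343 / 2493)
  expect_equal(round(genomeFraction(seg), 4), 0.1376)
  expect_equal(genomeFraction(compactSegments(seq_len(2493), d)), 1)
})

test_that("planted windows carry the most negative z-scores in a discordant scan", {
  cfg <- smallConfig(seed = 101L,
                     breeds = data.frame(name = c("A1", "A2"),
                                         subspecies = "A", n = 4))
  res <- runNfaaScan(cfg, subspecies = "A")
  z <- zscoreTrack(res$groupTrack)
  k <- length(res$truthWindows)
  expect_setequal(order(z)[seq_len(k)], res$truthWindows)
})

test_that("the Delta density on calibrated synthetic data is bimodal", {
  cfg <- cattlePreset(breedSet = "A", seed = 111L)
  res <- runNfaaScan(cfg, subspecies = "A")
  d <- deltaValues(res$delta)
  mclustBIC <- mclust::mclustBIC   # Mclust resolves it in the caller's frame
  fit1 <- mclust::Mclust(d, G = 1, verbose = FALSE)
  fit2 <- mclust::Mclust(d, G = 2, modelNames = "V", verbose = FALSE)
  expect_gt(fit2$bic, fit1$bic)
  # the two component means are far apart relative to component spreads
  mu <- fit2$parameters$mean
  expect_gt(abs(diff(mu)), 3 * max(sqrt(fit2$parameters$variance$sigmasq)))
})
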