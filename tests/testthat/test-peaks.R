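# Peak filtering, summit colocalization, stage subtraction, nearest
# distances, summit windows and random baselines.

test_that("fold-enrichment filtering is boundary-inclusive and monotone", {
  sl <- c(chr1 = 100000L)
  ps <- makePeaks(rep("chr1", 3), c(1000L, 2000L, 3000L),
                  fe = c(9.99, 10, 25), seqlengths = sl)
  kept <- filterByFoldEnrichment(ps, 10)
  expect_equal(length(kept), 2L)
  expect_true(all(foldEnrichment(kept) >= 10))

  empty <- filterByFoldEnrichment(ps, 1e9)
  expect_equal(length(empty), 0L)
  expect_equal(length(filterByFoldEnrichment(empty, 1)), 0L)

  # brute-force count over seeded FE values, several cutoffs
  set.seed(31)
  fe <- round(runif(100, 0, 30), 2)
  ps2 <- makePeaks(rep("chr1", 100), seq(1000L, by = 500L, length.out = 100),
                   fe = fe, seqlengths = c(chr1 = 10000000L))
  sizes <- integer()
  for (cut in c(0, 5, 10, 15, 30.01)) {
    expect_equal(length(filterByFoldEnrichment(ps2, cut)), sum(fe >= cut))
    sizes <- c(sizes, sum(fe >= cut))
  }
  expect_true(all(diff(sizes) <= 0))  # nonincreasing in the cutoff
})

test_that("colocalization is inclusive at the distance boundary", {
  sl <- c(chr1 = 10000L)
  a <- makePeaks("chr1", 1100L, seqlengths = sl)
  b50 <- makePeaks("chr1", 1150L, seqlengths = sl)
  b51 <- makePeaks("chr1", 1151L, seqlengths = sl)
  expect_equal(colocalize(a, b50, 50)$countA, 1L)
  expect_equal(colocalize(a, b51, 50)$countA, 0L)

  # A = B: 100% colocalized
  set.seed(32)
  big <- makePeaks(rep(c("chr1", "chr2"), each = 25),
                   sample(10000:90000, 50),
                   seqlengths = c(chr1 = 100000L, chr2 = 100000L))
  expect_equal(colocalize(big, big, 50)$percentA, 100)
})

test_that("colocalization counts and pairs match the all-pairs oracle", {
  set.seed(33)
  sl <- c(chr1 = 200000L, chr2 = 200000L)
  for (i in 1:40) {
    ca <- sample(names(sl), 25, replace = TRUE)
    sa <- sample(seq(5000L, 195000L), 25)
    cb <- sample(names(sl), 30, replace = TRUE)
    sb <- sample(seq(5000L, 195000L, by = 7L), 30)
    a <- makePeaks(ca, sa, seqlengths = sl)
    b <- makePeaks(cb, sb, seqlengths = sl)
    maxD <- sample(c(50L, 500L, 5000L), 1)
    res <- colocalize(a, b, maxD)
    # oracle over the *sorted* sets as stored in the PeakSets
    oa <- summits(a); ka <- as.character(seqnames(peakRanges(a)))
    ob <- summits(b); kb <- as.character(seqnames(peakRanges(b)))
    colA <- vapply(seq_along(oa), function(j)
      any(kb == ka[j] & abs(ob - oa[j]) <= maxD), TRUE)
    colB <- vapply(seq_along(ob), function(j)
      any(ka == kb[j] & abs(oa - ob[j]) <= maxD), TRUE)
    expect_equal(res$countA, sum(colA))
    expect_equal(res$countB, sum(colB))
    nPairs <- sum(outer(seq_along(oa), seq_along(ob), function(x, y)
      ka[x] == kb[y] & abs(oa[x] - ob[y]) <= maxD))
    expect_equal(nrow(res$pairs), nPairs)
    expect_true(all(res$pairs$distance <= maxD))
  }
})

test_that("colocalize rejects mismatched genomes", {
  a <- makePeaks("chr1", 1000L, seqlengths = c(chr1 = 10000L))
  b <- makePeaks("chr1", 1000L, seqlengths = c(chr1 = 99999L))
  expect_error(colocalize(a, b), "different genomes")
})

test_that("stage subtraction complements colocalization", {
  sl <- c(chr1 = 100000L, chr2 = 100000L)
  # full overlap: empty result
  e <- makePeaks(rep("chr1", 5), seq(1000L, 5000L, by = 1000L),
                 seqlengths = sl)
  expect_equal(length(stageOnly(e, e, 50)), 0L)
  # disjoint chromosomes: everything kept
  l2 <- makePeaks(rep("chr2", 5), seq(1000L, 5000L, by = 1000L),
                  seqlengths = sl)
  expect_equal(length(stageOnly(l2, e, 50)), 5L)
  # partition invariant: |stageOnly| + #colocalized = |late|
  set.seed(34)
  for (i in 1:20) {
    late <- makePeaks(sample(names(sl), 40, replace = TRUE),
                      sample(5000:95000, 40), seqlengths = sl)
    early <- makePeaks(sample(names(sl), 30, replace = TRUE),
                       sample(5000:95000, 30), seqlengths = sl)
    only <- stageOnly(late, early, 50)
    co <- colocalize(late, early, 50)
    expect_equal(length(only) + co$countA, length(late))
    # result equals the brute-force complement
    d <- oracleNearest(as.character(seqnames(peakRanges(late))),
                       summits(late),
                       as.character(seqnames(peakRanges(early))),
                       summits(early))
    expect_setequal(peakIds(only),
                    peakIds(late)[is.na(d) | d > 50])
  }
})

test_that("nearest summit distances match the all-pairs oracle", {
  sl <- c(chr1 = 100000L, chr2 = 100000L)
  q <- makePeaks(c("chr1", "chr1", "chr2"), c(5000L, 70000L, 9000L),
                 seqlengths = sl)
  r <- makePeaks(c("chr1", "chr1"), c(5000L, 71000L), seqlengths = sl)
  d <- nearestSummitDistance(q, r)
  expect_equal(unname(d[1]), 0)          # coincident summits
  expect_equal(unname(d[2]), 1000)
  expect_true(is.na(d[3]))               # chromosome absent from reference
  set.seed(35)
  for (i in 1:40) {
    qs <- makePeaks(sample(names(sl), 30, replace = TRUE),
                    sample(2000:98000, 30), seqlengths = sl)
    rs <- makePeaks(sample(names(sl), 20, replace = TRUE),
                    sample(2000:98000, 20), seqlengths = sl)
    expect_equal(unname(nearestSummitDistance(qs, rs)),
                 oracleNearest(as.character(seqnames(peakRanges(qs))),
                               summits(qs),
                               as.character(seqnames(peakRanges(rs))),
                               summits(rs)))
  }
})

test_that("fractionWithin counts missing distances in the denominator", {
  expect_equal(fractionWithin(c(0, 0, 0), 40000), 100)
  expect_equal(fractionWithin(c(NA_real_, NA_real_), 40000), 0)
  expect_equal(fractionWithin(c(10, NA, 50000), 40000), 100 / 3)
  # nondecreasing in the threshold
  set.seed(36)
  d <- c(sample(0:100000, 50), rep(NA_real_, 5))
  f <- vapply(c(0, 100, 1000, 40000, 1e6), fractionWithin, 0, distances = d)
  expect_true(all(diff(f) >= 0))
})

test_that("summit windows are centered, clipped and bounded", {
  sl <- c(chr1 = 100000L)
  ps <- makePeaks("chr1", 500L, seqlengths = sl, halfWidth = 100L)
  w <- summitWindows(ps, 200)
  expect_equal(start(w), 400L)
  expect_equal(end(w), 599L)   # [400, 600) half-open = 400..599 inclusive
  expect_equal(BiocGenerics::width(w), 200L)

  nearEdge <- makePeaks("chr1", 50L, seqlengths = sl, halfWidth = 20L)
  expect_warning(wc <- summitWindows(nearEdge, 200), "clipped")
  expect_equal(start(wc), 1L)
  expect_true(mcols(wc)$clipped)

  expect_error(summitWindows(ps, 201), "even")

  set.seed(37)
  batch <- makePeaks(rep("chr1", 50), sample(20:99990, 50),
                     seqlengths = sl, halfWidth = 10L)
  wb <- suppressWarnings(summitWindows(batch, 200))
  expect_true(all(BiocGenerics::width(wb) <= 200))
  expect_true(all(start(wb) >= 1 & end(wb) <= sl))
})

test_that("random coordinates are reproducible, bounded and length-weighted", {
  sl <- c(chrA = 50000L, chrB = 50000L)
  r1 <- randomCoordinates(sl, 500, 200, seed = 99)
  r2 <- randomCoordinates(sl, 500, 200, seed = 99)
  expect_identical(summits(r1), summits(r2))
  gr <- peakRanges(r1)
  expect_true(all(start(gr) >= 1 & end(gr) <= 50000))
  expect_true(all(BiocGenerics::width(gr) == 200))

  # two equal chromosomes: ~50/50 split (chi-square GOF)
  r3 <- randomCoordinates(sl, 10000, 100, seed = 5)
  counts <- table(as.character(seqnames(peakRanges(r3))))
  expect_gt(chisq.test(counts)$p.value, 0.001)

  expect_error(randomCoordinates(sl, 10, 60000, seed = 1), "exceeds")
})

test_that("narrowPeak files round-trip through write and read", {
  sl <- c(chr1 = 100000L, chr2 = 100000L)
  set.seed(38)
  ps <- makePeaks(sample(names(sl), 25, replace = TRUE),
                  sample(2000:90000, 25),
                  fe = round(runif(25, 5, 40), 2), seqlengths = sl)
  f <- tempfile(fileext = ".narrowPeak")
  writeNarrowPeak(ps, f)
  back <- readNarrowPeak(f, sl, label = "test")
  expect_identical(summits(back), summits(ps))
  expect_equal(foldEnrichment(back), foldEnrichment(ps))
  expect_identical(start(peakRanges(back)), start(peakRanges(ps)))
  expect_identical(end(peakRanges(back)), end(peakRanges(ps)))
})
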