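# TSS-window association, DE filtering, class-wise expression tests and
# permutation enrichment.

test_that("peak-gene association is inclusive at the window boundary", {
  sl <- c(chr1 = 200000L, chr2 = 200000L)
  # peak [1000, 1201] 1-based: 0-based center = (999 + 1201) %/% 2 = 1100
  ps <- PeakSet("chr1", 1000L, 1201L, summit = 1100L, foldEnrichment = 12,
                peakId = "pk1", seqlengths = sl, label = "t")
  genes <- data.frame(
    geneId = c("gAt", "gBeyond", "gOther"),
    chrom = c("chr1", "chr1", "chr2"),
    tss = c(1100L + 30000L + 1L,   # tss0 = 31100, exactly 30000 away
            1100L + 30001L + 1L,   # one bp too far
            5000L),
    strand = "+")
  res <- associatePeaksToGenes(ps, genes, 30000)
  expect_equal(res$links$geneId, "gAt")
  expect_equal(res$links$distance, 30000)

  # no genes on the peak's chromosome
  res2 <- associatePeaksToGenes(ps, genes[genes$chrom == "chr2", ], 30000)
  expect_equal(nrow(res2$links), 0L)
})

test_that("association links match a brute-force all-pairs scan from both sides", {
  set.seed(61)
  sl <- c(chr1 = 500000L, chr2 = 500000L)
  for (i in 1:25) {
    n <- 20
    ps <- makePeaks(sample(names(sl), n, replace = TRUE),
                    sample(50000:450000, n), seqlengths = sl)
    genes <- data.frame(geneId = sprintf("g%02d", 1:30),
                        chrom = sample(names(sl), 30, replace = TRUE),
                        tss = sample(1000:499000, 30), strand = "+")
    win <- sample(c(5000L, 30000L), 1)
    links <- associatePeaksToGenes(ps, genes, win)$links
    gr <- peakRanges(ps)
    center0 <- (start(gr) - 1L + end(gr)) %/% 2L
    want <- 0L
    for (p in seq_len(n)) for (g in seq_len(30)) {
      if (as.character(seqnames(gr))[p] == genes$chrom[g] &&
          abs(center0[p] - (genes$tss[g] - 1L)) <= win) want <- want + 1L
    }
    expect_equal(nrow(links), want)
    # gene-side recomputation gives the same link set
    for (j in seq_len(nrow(links))) {
      g <- match(links$geneId[j], genes$geneId)
      p <- match(links$peakId[j], peakIds(ps))
      expect_lte(abs((genes$tss[g] - 1L) - center0[p]), win)
    }
  }
})

test_that("DE filtering is boundary-inclusive, split by direction, monotone", {
  de <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    fold_change = c(1.5, 1.49, 4, 2, 1.6),
    direction = c("down", "down", "up", "up", "down"),
    padj = c(0.01, 0.01, 0.010001, 1e-5, 0.002))
  res <- deFilter(de, 0.01, 1.5)
  expect_setequal(res$down, c("a", "e"))
  expect_setequal(res$up, "d")   # c fails padj, b fails FC

  empty <- deFilter(de[0, ], 0.01, 1.5)
  expect_equal(lengths(empty), c(up = 0L, down = 0L))

  # relaxing either threshold never removes a gene; counts match brute force
  set.seed(62)
  big <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    fold_change = round(exp(rnorm(200, 0, 0.7)), 3),
                    padj = round(runif(200), 4))
  strict <- deFilter(big, 0.01, 1.5)
  loose <- deFilter(big, 0.05, 1.2)
  expect_true(all(c(strict$up, strict$down) %in% c(loose$up, loose$down)))
  mag <- ifelse(big$fold_change >= 1, big$fold_change, 1 / big$fold_change)
  expect_equal(length(c(strict$up, strict$down)),
               sum(big$padj <= 0.01 & mag >= 1.5))
})

test_that("Dunn z statistics and p-values match hand-computed values", {
  # groups (1,2,3), (4,5,6), (7,8,9): no ties, mean ranks 2, 5, 8,
  # se = sqrt(N(N+1)/12 * (1/3 + 1/3)) = sqrt(5)
  d <- pairwiseDunn(1:9, rep(c("a", "b", "c"), each = 3))
  se <- sqrt(5)
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"], -3 / se,
               tolerance = 1e-12)
  expect_equal(d$z[d$group1 == "a" & d$group2 == "c"], -6 / se,
               tolerance = 1e-12)
  expect_equal(d$p, 2 * pnorm(-abs(d$z)), tolerance = 1e-12)
  expect_equal(d$padj, pmin(1, d$p * 3), tolerance = 1e-12)

  # tie correction: duplicated values reduce the rank variance
  x <- c(1, 1, 2, 2, 3, 3, 10, 11, 12)
  dt <- pairwiseDunn(x, rep(c("a", "b", "c"), each = 3))
  ties <- table(x)
  corr <- sum(ties^3 - ties) / (12 * (9 - 1))
  rk <- rank(x)
  mr <- tapply(rk, rep(c("a", "b", "c"), each = 3), mean)
  zWant <- (mr[["a"]] - mr[["c"]]) / sqrt((9 * 10 / 12 - corr) * (2 / 3))
  expect_equal(dt$z[dt$group1 == "a" & dt$group2 == "c"], zWant,
               tolerance = 1e-12)
})

test_that("class expression summaries compute log2 mean TPM and detect shifts", {
  # single gene, replicates (3, 5), pseudocount 1 -> log2(5)
  labels <- c(pk1 = "Class1", pk2 = "Class2")
  links <- data.frame(peakId = "pk1", geneId = "g1")
  expr <- data.frame(gene_id = "g1", r1 = 3, r2 = 5)
  res <- classExpressionSummary(labels, links, expr, samples = c("r1", "r2"))
  expect_equal(res$values$value, log2(5))
  expect_equal(res$excludedClasses, "Class1")  # < 2 genes
  expect_null(res$kruskal)

  # one class shifted 4x: its Dunn comparisons are significant
  set.seed(63)
  nG <- 60
  mkClass <- function(cl, mu) {
    list(labels = stats::setNames(rep(cl, nG),
                                  sprintf("%s_pk%02d", cl, 1:nG)),
         links = data.frame(peakId = sprintf("%s_pk%02d", cl, 1:nG),
                            geneId = sprintf("%s_g%02d", cl, 1:nG)),
         expr = data.frame(gene_id = sprintf("%s_g%02d", cl, 1:nG),
                           r1 = rlnorm(nG, log(mu), 0.3),
                           r2 = rlnorm(nG, log(mu), 0.3)))
  }
  parts <- list(mkClass("Class1", 10), mkClass("Class2", 10),
                mkClass("Class3", 40))
  labels <- do.call(c, lapply(parts, `[[`, "labels"))
  links <- do.call(rbind, lapply(parts, `[[`, "links"))
  expr <- do.call(rbind, lapply(parts, `[[`, "expr"))
  res2 <- classExpressionSummary(labels, links, expr,
                                 samples = c("r1", "r2"))
  expect_lt(res2$kruskal$p.value, 1e-4)
  d <- res2$dunn
  expect_lt(d$padj[d$group1 == "Class1" & d$group2 == "Class3"], 0.01)
  expect_lt(d$padj[d$group1 == "Class2" & d$group2 == "Class3"], 0.01)
  expect_gt(d$padj[d$group1 == "Class1" & d$group2 == "Class2"], 0.05)

  # fold-change variant: identical numerator and denominator -> all zero
  resFc <- classExpressionSummary(labels, links, expr,
                                  samples = c("r1", "r2"),
                                  denominatorSamples = c("r1", "r2"),
                                  statistic = "foldChange")
  expect_true(all(resFc$values$value == 0))
})

test_that("permutation enrichment has correct degenerate and planted behavior", {
  universe <- sprintf("g%04d", 1:1000)
  # associated = universe: every permutation achieves the full overlap
  res <- enrichmentVsRandom(universe[1:50], universe, universe,
                            nPerm = 200, seed = 3)
  expect_equal(res$observed, 50L)
  expect_equal(res$p, 1)

  # empty overlap with a dense associated set: p near 1
  resDep <- enrichmentVsRandom(universe[901:1000], universe[1:800],
                               universe, nPerm = 200, seed = 4)
  expect_equal(resDep$observed, 0L)
  expect_gt(resDep$p, 0.9)

  # planted enrichment: target drawn 80% from a 10% associated set
  set.seed(64)
  associated <- universe[1:100]
  target <- c(sample(associated, 40), sample(universe[101:1000], 10))
  resEnr <- enrichmentVsRandom(target, associated, universe,
                               nPerm = 1000, seed = 5)
  expect_lte(resEnr$p, 0.01)

  # bounds, reproducibility, input checks
  expect_gte(resEnr$p, 1 / 1001)
  resEnr2 <- enrichmentVsRandom(target, associated, universe,
                                nPerm = 1000, seed = 5)
  expect_identical(resEnr, resEnr2)
  expect_error(enrichmentVsRandom(c("zz", universe[1]), associated,
                                  universe), "outside the universe")
})
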