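# IUPAC consensus scanning, exclusion-aware presence, prevalence, enrichment
# and spacing.

test_that("scanning finds direct, reverse-complement and wildcard matches", {
  reg <- defaultMotifRegistry()
  hexa <- reg$consensus[reg$name == "HEXA"]

  h <- scanMotif("TGATTGACAG", hexa, "HEXA")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 5L)
  expect_equal(h$strand, "+")

  h <- scanMotif("CTGTCA", hexa, "HEXA")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 1L)
  expect_equal(h$strand, "-")

  h <- scanMotif("TGATCCATGG", "TGATNNAT")
  expect_equal(h$start, 1L)
  expect_equal(h$strand, "+")

  expect_error(scanMotif("ACGT", "TGAX"), "invalid IUPAC")
})

test_that("scanning agrees with the per-position brute-force oracle", {
  motifs <- c("TGATTGACAG", "TGACAG", "TGATNNAT", "CCMCRCCC", "CCAAT",
              "ATRTTAA")
  set.seed(101)
  for (i in 1:100) {
    s <- randomSeq(sample(150:400, 1))
    if (i %% 7 == 0) {  # sprinkle Ns into the subject
      chars <- strsplit(s, "")[[1]]
      chars[sample(length(chars), 5)] <- "N"
      s <- paste(chars, collapse = "")
    }
    m <- motifs[(i %% length(motifs)) + 1L]
    hits <- scanMotif(s, m)
    want <- oracleScanBoth(s, m)
    expect_identical(sort(hits$start[hits$strand == "+"]), sort(want$fwd))
    expect_identical(sort(hits$start[hits$strand == "-"]), sort(want$rev))
  }
})

test_that("hit counts are reverse-complement invariant", {
  set.seed(7)
  reg <- defaultMotifRegistry()
  for (i in 1:25) {
    s <- randomSeq(300)
    rc <- oracleRevcomp(s)
    for (m in reg$consensus) {
      expect_equal(nrow(scanMotif(s, m)), nrow(scanMotif(rc, m)))
    }
  }
})

test_that("presence applies the DECA-over-HEXA exclusion rule", {
  expect_true(motifPresence("TGATTGACAG", "DECA"))
  expect_false(motifPresence("TGATTGACAG", "HEXA"))   # suppressed by DECA
  expect_true(motifPresence("AATGACAGAA", "HEXA"))
  expect_false(motifPresence("AATGACAGAA", "DECA"))

  # batch presence equals brute-force recomputation
  set.seed(11)
  reg <- defaultMotifRegistry()
  for (i in 1:50) {
    s <- randomSeq(200)
    if (i %% 3 == 0) s <- embedMotif(s, "TGATTGACAG", 50)
    if (i %% 4 == 0) s <- embedMotif(s, "TGACAG", 120)
    deca <- length(oracleScanBoth(s, "TGATTGACAG")$fwd) +
      length(oracleScanBoth(s, "TGATTGACAG")$rev) > 0
    hexaRaw <- length(oracleScanBoth(s, "TGACAG")$fwd) +
      length(oracleScanBoth(s, "TGACAG")$rev) > 0
    expect_equal(motifPresence(s, "DECA", reg), deca)
    expect_equal(motifPresence(s, "HEXA", reg), hexaRaw && !deca)
  }
})

test_that("registry validation rejects bad consensus, references and cycles", {
  expect_error(motifRegistry("X", "TGAZ"), "invalid IUPAC")
  expect_error(motifRegistry("X", "TGACAG", "missing"), "unknown motif")
  expect_error(motifRegistry(c("A", "B"), c("TGACAG", "CCAAT"),
                             c("B", "A")), "cycle")
})

test_that("registry YAML round-trips", {
  reg <- defaultMotifRegistry()
  f <- tempfile(fileext = ".yaml")
  writeMotifRegistry(reg, f)
  expect_equal(readMotifRegistry(f), reg)
})

test_that("prevalence reflects planted content and the exclusion rule", {
  # toy genome: every peak window carries a DECA at the summit
  set.seed(3)
  n <- 20L
  chromLen <- 50000L
  summit <- seq(2000L, by = 2000L, length.out = n)
  chars <- sample(c("A", "C", "G", "T"), chromLen, replace = TRUE)
  seqStr <- paste(chars, collapse = "")
  for (s in summit) seqStr <- embedMotif(seqStr, "TGATTGACAG", s - 5L)
  genome <- Biostrings::DNAStringSet(c(chrT = seqStr))
  ps <- makePeaks(rep("chrT", n), summit,
                  seqlengths = c(chrT = chromLen))
  prev <- motifPrevalence(ps, genome, motifs = c("DECA", "HEXA"))
  expect_equal(prev$percent[prev$motif == "DECA"], 100)
  expect_equal(prev$percent[prev$motif == "HEXA"], 0)
  expect_true(all(prev$percent >= 0 & prev$percent <= 100))
})

test_that("prevalence errors on peaks outside the genome", {
  genome <- Biostrings::DNAStringSet(c(chrT = randomSeq(1000)))
  ps <- makePeaks("chrT", 5000L, seqlengths = c(chrT = 10000L))
  expect_error(motifPrevalence(ps, genome), "outside the genome")
})

test_that("Fisher enrichment matches an exact enumeration oracle", {
  win <- function(withMotif) {
    s <- randomSeq(60)
    if (withMotif) embedMotif(s, "TGATTGACAG", 20) else
      gsub("TGATTGACAG|CTGTCAATCA", "AAAAAAAAAA", s)
  }
  set.seed(5)
  a <- vapply(rep(TRUE, 20), win, "")
  b <- vapply(rep(FALSE, 20), win, "")
  res <- enrichmentBetween(a, b, "DECA")
  expect_equal(res$table["present", "A"], 20)
  expect_equal(res$table["present", "B"], 0)
  expect_equal(res$pValue, oracleFisherP(20, 0, 0, 20), tolerance = 1e-10)
  expect_true(res$oddsRatio > 1)  # Haldane-corrected, finite
  expect_true(is.finite(res$oddsRatio))

  # null case: identical presence frequencies
  res0 <- enrichmentBetween(c(a, b), c(a, b), "DECA")
  expect_equal(res0$oddsRatio, 1, tolerance = 1e-9)
  expect_equal(res0$pValue, 1, tolerance = 1e-9)
})

test_that("motif spacing equals brute-force all-pairs minima", {
  # constructed: centers exactly 20 bp apart
  s <- paste(rep("A", 200), collapse = "")
  s <- embedMotif(s, "TGATTGACAG", 96)      # center 100.5
  s <- embedMotif(s, "CCAAT", 118)          # center 120 -> 19.5? no: 118+2=120
  sp <- motifSpacing(c(w1 = s), "NFY", "DECA")
  expect_equal(unname(sp$perSequence), 120 - 100.5)

  # sequences lacking either motif are excluded and counted
  sp2 <- motifSpacing(c(w1 = s, w2 = paste(rep("A", 50), collapse = "")),
                      "NFY", "DECA")
  expect_equal(sp2$nWithBoth, 1L)
  expect_equal(sp2$nExcluded, 1L)

  # multi-hit sequences vs all-pairs oracle
  set.seed(13)
  for (i in 1:30) {
    s <- randomSeq(300)
    for (p in sample(seq(10, 280, by = 15), 3)) s <- embedMotif(s, "TGACAG", p)
    for (p in sample(seq(12, 280, by = 17), 2)) s <- embedMotif(s, "CCAAT", p)
    got <- motifSpacing(stats::setNames(s, "x"), "HEXA", "NFY")
    ha <- oracleScanBoth(s, "TGACAG")
    hb <- oracleScanBoth(s, "CCAAT")
    ca <- c(ha$fwd, ha$rev) + (6 - 1) / 2
    cb <- c(hb$fwd, hb$rev) + (5 - 1) / 2
    if (length(ca) && length(cb)) {
      expect_equal(unname(got$perSequence), min(abs(outer(ca, cb, "-"))))
    } else {
      expect_equal(got$nWithBoth, 0L)
    }
  }
})

test_that("summit offset profiles localize planted motifs", {
  # planted at the summit: mode in the bin containing 0
  mk <- function(offset) {
    s <- randomSeq(200)
    embedMotif(s, "TGATTTAT", as.integer(round(100.5 + offset - 3.5)))
  }
  set.seed(21)
  hits <- do.call(rbind, lapply(1:200, function(i) scanMotif(mk(0), "TGATTTAT")))
  prof <- summitOffsetProfile(hits, 200, bin = 10)
  expect_true(abs(prof$mode) <= 10)
  expect_lt(abs(prof$meanOffset), 3)

  # planted uniformly: flat histogram (chi-square GOF not rejected)
  set.seed(22)
  offs <- sample(-80:80, 400, replace = TRUE)
  hitsU <- do.call(rbind, lapply(offs, function(o)
    scanMotif(mk(o), "TGATTTAT")))
  profU <- summitOffsetProfile(hitsU, 200, bin = 20)
  hsel <- profU$histogram[profU$histogram$lower >= -80 &
                            profU$histogram$upper <= 80, ]
  p <- suppressWarnings(chisq.test(hsel$count)$p.value)
  expect_gt(p, 0.001)
})
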