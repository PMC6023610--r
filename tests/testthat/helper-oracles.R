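# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (per-position loops, all-pairs scans) so they exercise
# none of the package's optimized code paths.

.oracleIupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T", "N"))

oracleRevcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", s),
                     "")[[1L]]), collapse = "")
}

# forward-strand match starts of an IUPAC consensus, per-position comparison
oracleScanStrand <- function(sequence, consensus) {
  sc <- strsplit(sequence, "")[[1L]]
  cc <- strsplit(consensus, "")[[1L]]
  L <- length(cc)
  out <- integer()
  if (length(sc) >= L) {
    for (i in seq_len(length(sc) - L + 1L)) {
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!(sc[i + j - 1L] %in% .oracleIupac[[cc[j]]])) { ok <- FALSE; break }
      }
      if (ok) out <- c(out, i)
    }
  }
  out
}

oracleScanBoth <- function(sequence, consensus) {
  list(fwd = oracleScanStrand(sequence, consensus),
       rev = oracleScanStrand(sequence, oracleRevcomp(consensus)))
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# quick PeakSet from summit vectors (400 bp intervals by default)
makePeaks <- function(chrom, summit, fe = NULL, seqlengths = NULL,
                      label = "test", halfWidth = 200L) {
  if (is.null(fe)) fe <- rep(12, length(summit))
  if (is.null(seqlengths)) {
    sl <- tapply(summit, chrom, max) + 10000L
    seqlengths <- stats::setNames(as.integer(sl), names(sl))
  }
  PeakSet(chrom = chrom, start = pmax(summit - halfWidth, 1L),
          end = summit + halfWidth, summit = summit, foldEnrichment = fe,
          seqlengths = seqlengths, label = label)
}

# all-pairs nearest summit distance
oracleNearest <- function(qChrom, qSummit, rChrom, rSummit) {
  vapply(seq_along(qSummit), function(i) {
    d <- abs(qSummit[i] - rSummit[rChrom == qChrom[i]])
    if (length(d)) min(d) else NA_real_
  }, 0)
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
oracleFisherP <- function(a, b, c, d) {
  m <- a + c          # column A total
  n <- b + d          # column B total
  k <- a + b          # present total
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# tiny synthetic dataset shared across test files (generated once)
tinyDataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "TALEreg-tiny")
      if (!file.exists(file.path(dir, "manifest.json"))) {
        cfg <- syntheticConfig(seed = 42, nEarlyPeaks = 200,
                               nLateOnlyPeaks = 150, genesPerClass = 25)
        generateDataset(cfg, dir)
      }
      sl <- readChromSizes(dir)
      genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
      names(genome) <- sub("\\s.*", "", names(genome))
      cache <<- list(
        dir = dir, seqlengths = sl, genome = genome,
        early = readNarrowPeak(file.path(dir, "peaks_early.narrowPeak"),
                               sl, "early"),
        late = readNarrowPeak(file.path(dir, "peaks_late.narrowPeak"),
                              sl, "late"),
        truth = read.delim(file.path(dir, "truth_peaks.tsv")))
    }
    cache
  }
})
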