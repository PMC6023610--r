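# Synthetic dataset generator. Produces a self-contained toy experiment
# (genome FASTA, two-stage narrowPeak files, histone-mark bedGraph tracks,
# TSS BED, TPM / DE / Ct tables, ground truth, manifest) whose statistical
# structure matches what the downstream stages assume: a configurable
# fraction of early peaks retained at the late stage, late-only peaks
# preferentially placed near early peaks, stage-dependent motif embedding
# with DECA/HEXA/PBX:HOX/CCAAT geometry, four marked chromatin classes plus
# an unmarked class driving the signal tracks, and class-coupled expression
# with a knockdown condition.

.SYN_BASES <- c("A", "C", "G", "T")
.SYN_MOTIFS <- c(DECA = "TGATTGACAG", HEXA = "TGACAG",
                 PBXHOX = "TGATTTAT", NFY = "CCAAT")
# reverse complements of the embedded motifs (all non-degenerate), so the
# per-window verification scan can use plain literal regexes
.SYN_MOTIFS_RC <- c(DECA = "CTGTCAATCA", HEXA = "CTGTCA",
                    PBXHOX = "ATAAATCA", NFY = "ATTGG")

#' Create a synthetic-dataset configuration
#'
#' Defaults encode the planted structure recovered by the analysis stages:
#' 60% early-peak retention, 58% of late-only peaks within 40 kb of an early
#' peak, DECA embedded in 75% of early / 7% of late-only windows, HEXA in 11%
#' / 44% (HEXA windows never carry DECA), PBX:HOX in 5% / 24% at a ~10 bp
#' summit offset, CCAAT next to half of the DECA sites at ~20 bp mean
#' spacing, a 25%/75% MPAD/non-MPAD split (Class1..4 = 7/7/6/5%), and
#' class-coupled expression with a 4-fold knockdown effect on Class4 genes.
#'
#' @param seed Integer master seed; identical seed + config gives
#'   byte-identical output files.
#' @param nChroms Number of chromosomes ("chrS1", "chrS2", ...).
#' @param chromLength Common chromosome length in bp; NA auto-sizes to fit
#'   the configured peak counts.
#' @param nEarlyPeaks,nLateOnlyPeaks Peak counts (fold enrichment >= 10).
#' @param retentionRate Fraction of early peaks still occupied late.
#' @param fracLateOnlyWithin40kb Fraction of late-only peaks placed within
#'   `proximityDistance` of an early peak.
#' @param proximityDistance Proximity radius in bp (default 40000).
#' @param earlySpacing Spacing of early summits in bp.
#' @param peakWidth Approximate peak interval width in bp.
#' @param windowWidth Summit-window width used for motif embedding (even).
#' @param motifRates Named list `early` / `late_only` of per-window embedding
#'   probabilities for DECA, HEXA (counted only without DECA) and PBXHOX.
#' @param nfyRate Probability that a DECA window also carries a CCAAT site.
#' @param nfyDecaSpacingMean,nfyDecaSpacingSd CCAAT-DECA center spacing (bp).
#' @param hoxOffsetMean,hoxOffsetSd PBX:HOX center offset from the summit.
#' @param classProportions Named fractions for Class1..4 and nonMPAD
#'   (sum to 1).
#' @param signalParams Per-mark, per-class peak amplitudes of the Gaussian
#'   signal bump.
#' @param bumpWidth Gaussian bump standard deviation in bp.
#' @param noiseSd Standard deviation of the additive track noise (floored at
#'   0).
#' @param flank Track extent on each side of the summit in bp.
#' @param genesPerClass Number of genes placed near peaks of each class.
#' @param expressionParams Baseline TPM per class, knockdown multiplier for
#'   Class4 genes, and log-scale TPM dispersion.
#' @param lowFEFraction Size (relative to `nEarlyPeaks`) of an extra tranche
#'   of sub-threshold (FE < 10) early peaks placed away from the main
#'   geometry, so fold-enrichment filtering is exercised.
#' @return A validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(
    seed = 1L, nChroms = 4L, chromLength = NA_integer_,
    nEarlyPeaks = 2000L, retentionRate = 0.60,
    nLateOnlyPeaks = 2000L, fracLateOnlyWithin40kb = 0.58,
    proximityDistance = 40000L, earlySpacing = 3000L,
    peakWidth = 400L, windowWidth = 200L,
    motifRates = list(
      early = c(DECA = 0.75, HEXA = 0.11, PBXHOX = 0.05),
      late_only = c(DECA = 0.07, HEXA = 0.44, PBXHOX = 0.24)),
    nfyRate = 0.5, nfyDecaSpacingMean = 20, nfyDecaSpacingSd = 5,
    hoxOffsetMean = 10, hoxOffsetSd = 4,
    classProportions = c(Class1 = 0.07, Class2 = 0.07, Class3 = 0.06,
                         Class4 = 0.05, nonMPAD = 0.75),
    signalParams = list(
      H3K4me1 = c(Class1 = 9, Class2 = 8.5, Class3 = 8, Class4 = 7.5,
                  nonMPAD = 0.3),
      H3K27ac_early = c(Class1 = 10, Class2 = 5, Class3 = 1.5, Class4 = 0.3,
                        nonMPAD = 0.2),
      H3K27ac_late = c(Class1 = 6, Class2 = 4, Class3 = 2, Class4 = 4,
                       nonMPAD = 1),
      H3K27me3 = c(Class1 = 0.3, Class2 = 0.3, Class3 = 0.3, Class4 = 8,
                   nonMPAD = 0.2)),
    bumpWidth = 150, noiseSd = 0.2, flank = 1000L,
    genesPerClass = 120L,
    expressionParams = list(
      baselineTPM = c(Class1 = 100, Class2 = 60, Class3 = 20, Class4 = 5,
                      nonMPAD = 10),
      knockdownEffect = 0.25, logSdTPM = 0.4),
    lowFEFraction = 0.05) {
  new("SyntheticConfig",
      seed = as.integer(seed), nChroms = as.integer(nChroms),
      chromLength = as.integer(chromLength),
      nEarlyPeaks = as.integer(nEarlyPeaks),
      retentionRate = retentionRate,
      nLateOnlyPeaks = as.integer(nLateOnlyPeaks),
      fracLateOnlyWithin40kb = fracLateOnlyWithin40kb,
      proximityDistance = as.integer(proximityDistance),
      earlySpacing = as.integer(earlySpacing),
      peakWidth = as.integer(peakWidth),
      windowWidth = as.integer(windowWidth),
      motifRates = motifRates, nfyRate = nfyRate,
      nfyDecaSpacingMean = nfyDecaSpacingMean,
      nfyDecaSpacingSd = nfyDecaSpacingSd,
      hoxOffsetMean = hoxOffsetMean, hoxOffsetSd = hoxOffsetSd,
      classProportions = classProportions, signalParams = signalParams,
      bumpWidth = bumpWidth, noiseSd = noiseSd, flank = as.integer(flank),
      genesPerClass = as.integer(genesPerClass),
      expressionParams = expressionParams,
      lowFEFraction = lowFEFraction)
}

#' Embed a concrete instance of an IUPAC consensus into a sequence
#'
#' Each degenerate code is instantiated by a uniform draw among its options
#' (using the current RNG stream); for strand "-" the reverse complement of
#' the instantiated motif is written. All other bases are unchanged.
#'
#' @param sequence DNA string.
#' @param consensus IUPAC consensus to embed.
#' @param position 1-based start position of the embedded motif.
#' @param strand "+" or "-".
#' @return The modified sequence.
#' @export
embedMotif <- function(sequence, consensus, position, strand = "+") {
  len <- nchar(consensus)
  if (position < 1 || position + len - 1 > nchar(sequence))
    stop("motif does not fit the sequence at position ", position)
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC code in consensus: ",
                        paste(unique(bad), collapse = ", "))
  inst <- vapply(chars, function(ch) {
    opts <- .IUPAC[[ch]]
    if (length(opts) == 1L) opts else opts[sample.int(length(opts), 1L)]
  }, "")
  inst <- paste(inst, collapse = "")
  if (strand == "-") inst <- .revcompConsensus(inst)
  substr(sequence, position, position + len - 1L) <- inst
  sequence
}

# Exactly-k TRUE flags at random positions.
.pickExact <- function(n, rate) {
  k <- round(rate * n)
  out <- logical(n)
  if (k > 0) out[sample.int(n, min(k, n))] <- TRUE
  out
}

# Truncated-normal integer draw.
.truncNormInt <- function(n, mean, sd, lo, hi) {
  out <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      v <- round(stats::rnorm(1, mean, sd))
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

# Synthesize one summit window: clean background (no spurious core-motif
# hits) with the designated motifs embedded; rejection-resampled until a
# rescan reproduces the intended truth exactly.
.synthWindow <- function(deca, hexa, pbxhox, nfy, spacing, hoxOffset, w) {
  summitLocal <- w %/% 2L + 1L
  for (try in seq_len(500L)) {
    s <- paste(sample(.SYN_BASES, w, replace = TRUE), collapse = "")
    place <- list()
    if (deca) {
      st <- summitLocal - 5L + sample(-3:3, 1L)
      place$DECA <- c(st, 10L)
    }
    if (nfy) {
      decaCenter <- place$DECA[1L] + 4.5
      st <- as.integer(round(decaCenter + spacing - 2))
      place$NFY <- c(st, 5L)
    }
    if (hexa) {
      st <- summitLocal - 3L + sample(-3:3, 1L)
      place$HEXA <- c(st, 6L)
    }
    if (pbxhox) {
      # desired position from the configured summit offset; slide away from
      # the summit if it would overlap an already-placed motif
      st <- as.integer(round(summitLocal - 0.5 + hoxOffset - 3.5))
      dir <- if (hoxOffset < 0) -1L else 1L
      overlaps <- function(st1, len1) {
        if (!length(place)) return(FALSE)
        os <- vapply(place, `[`, 0, 1L)
        oe <- os + vapply(place, `[`, 0, 2L) - 1L
        any(st1 <= oe & st1 + len1 - 1L >= os)
      }
      steps <- 0L
      while (overlaps(st, 8L) && steps < 200L) {
        st <- st + dir
        steps <- steps + 1L
      }
      place$PBXHOX <- c(st, 8L)
    }
    # placements must fit and must not overlap one another
    ok <- TRUE
    if (length(place)) {
      st <- vapply(place, `[`, 0, 1L)
      en <- st + vapply(place, `[`, 0, 2L) - 1L
      if (any(st < 1L) || any(en > w)) ok <- FALSE
      if (ok && length(place) > 1L) {
        o <- order(st)
        if (any(st[o][-1L] <= en[o][-length(o)])) ok <- FALSE
      }
    }
    if (!ok) next
    for (nm in names(place)) {
      s <- embedMotif(s, .SYN_MOTIFS[[nm]], place[[nm]][1L],
                      strand = sample(c("+", "-"), 1L))
    }
    # verify the scan reproduces the intended truth
    cnt <- function(nm) {
      length(.regexStarts(s, .SYN_MOTIFS[[nm]])) +
        length(.regexStarts(s, .SYN_MOTIFS_RC[[nm]]))
    }
    if (cnt("DECA") != as.integer(deca)) next
    if (!deca && cnt("HEXA") != as.integer(hexa)) next
    if (cnt("PBXHOX") != as.integer(pbxhox)) next
    if (cnt("NFY") != as.integer(nfy)) next
    return(s)
  }
  stop("failed to synthesize a window matching its designated motif truth")
}

# Draw per-window motif truth flags for one stage at exact counts.
.stageTruth <- function(n, rates, nfyRate) {
  deca <- .pickExact(n, rates[["DECA"]])
  hexa <- logical(n)
  idxNoDeca <- which(!deca)
  kHexa <- round(rates[["HEXA"]] * n)
  if (kHexa > length(idxNoDeca))
    stop("HEXA rate incompatible with DECA rate at n = ", n)
  if (kHexa > 0)
    hexa[sample(idxNoDeca, kHexa)] <- TRUE
  pbxhox <- .pickExact(n, rates[["PBXHOX"]])
  nfy <- logical(n)
  idxDeca <- which(deca)
  kNfy <- round(nfyRate * length(idxDeca))
  if (kNfy > 0) nfy[sample(idxDeca, kNfy)] <- TRUE
  data.frame(deca = deca, hexa = hexa, pbxhox = pbxhox, nfy = nfy)
}

#' Generate a synthetic dataset on disk
#'
#' Writes, under `outDir`: `genome.fa`, `peaks_early.narrowPeak` (including a
#' sub-threshold FE tranche), `peaks_late.narrowPeak`, four histone-mark
#' bedGraph tracks, `tss.bed`, `tpm.tsv`, `de.tsv`, `ct_expression.tsv`,
#' `ct_chip.tsv`, ground-truth tables (`truth_peaks.tsv`,
#' `truth_genes.tsv`), `chrom_sizes.tsv` and a `manifest.json` listing every
#' file with its MD5 checksum. Identical config + seed reproduces
#' byte-identical files.
#'
#' @param config A [SyntheticConfig-class] from [syntheticConfig()].
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list: `dir`, `files` (named paths), `seqlengths`,
#'   `counts`.
#' @export
generateDataset <- function(config, outDir) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  .withSeed(cfg@seed, .generateDatasetImpl(cfg, outDir))
}

.generateDatasetImpl <- function(cfg, outDir) {
  w <- cfg@windowWidth
  half <- w %/% 2L
  margin <- 60000L
  chroms <- paste0("chrS", seq_len(cfg@nChroms))

  splitCounts <- function(n) diff(round(seq(0, n, length.out = cfg@nChroms + 1)))
  nEc <- splitCounts(cfg@nEarlyPeaks)
  nNear <- round(cfg@fracLateOnlyWithin40kb * cfg@nLateOnlyPeaks)
  nNc <- splitCounts(nNear)
  nFc <- splitCounts(cfg@nLateOnlyPeaks - nNear)
  nLc <- splitCounts(round(cfg@lowFEFraction * cfg@nEarlyPeaks))

  peaks <- list()   # per-chrom data.frames: summit, category
  needLen <- 0L
  for (ci in seq_len(cfg@nChroms)) {
    m <- nEc[ci]
    early <- margin + (seq_len(m) - 1L) * cfg@earlySpacing +
      sample(-400:400, m, replace = TRUE)
    occupied <- early
    near <- integer(nNc[ci])
    for (i in seq_len(nNc[ci])) {
      repeat {
        anchor <- early[sample.int(m, 1L)]
        off <- sample(c(-1L, 1L), 1L) *
          sample(210:cfg@proximityDistance, 1L)
        pos <- anchor + off
        if (pos < margin %/% 2L) next
        if (min(abs(pos - occupied)) >= 210L) break
      }
      near[i] <- pos
      occupied <- c(occupied, pos)
    }
    farStart <- max(early) + cfg@proximityDistance + 20000L
    far <- farStart + (seq_len(nFc[ci]) - 1L) * 400L +
      sample(-50:50, nFc[ci], replace = TRUE)
    lowStart <- (if (nFc[ci]) max(far) else farStart) + 60000L
    low <- lowStart + (seq_len(nLc[ci]) - 1L) * 400L +
      sample(-50:50, nLc[ci], replace = TRUE)
    peaks[[ci]] <- data.frame(
      chrom = chroms[ci],
      summit = c(early, near, far, low),
      category = rep(c("early", "near", "far", "lowFE"),
                     c(m, nNc[ci], nFc[ci], nLc[ci])))
    needLen <- max(needLen,
                   as.integer((if (nLc[ci]) max(low) else lowStart) + margin))
  }
  if (!is.na(cfg@chromLength)) {
    if (cfg@chromLength < needLen)
      stop("chromLength too small: the configured peak counts need at ",
           "least ", needLen, " bp")
    chromLen <- cfg@chromLength
  } else chromLen <- needLen
  seqlengths <- stats::setNames(rep(chromLen, cfg@nChroms), chroms)

  pk <- do.call(rbind, peaks)
  pk <- pk[order(match(pk$chrom, chroms), pk$summit), ]
  rownames(pk) <- NULL
  isEarly <- pk$category == "early"
  isLow <- pk$category == "lowFE"
  isLateOnly <- pk$category %in% c("near", "far")
  pk$peakId <- NA_character_
  pk$peakId[isEarly | isLow] <-
    sprintf("early_%05d", seq_len(sum(isEarly | isLow)))
  pk$peakId[isLateOnly] <- sprintf("lateonly_%05d", seq_len(sum(isLateOnly)))

  # ---- motif truth and window sequences -------------------------------
  truthE <- .stageTruth(sum(isEarly), cfg@motifRates$early, cfg@nfyRate)
  truthL <- .stageTruth(sum(isLateOnly), cfg@motifRates$late_only,
                        cfg@nfyRate)
  truthLow <- data.frame(deca = logical(sum(isLow)),
                         hexa = logical(sum(isLow)),
                         pbxhox = logical(sum(isLow)),
                         nfy = logical(sum(isLow)))
  truthAll <- data.frame(deca = logical(nrow(pk)), hexa = logical(nrow(pk)),
                         pbxhox = logical(nrow(pk)), nfy = logical(nrow(pk)))
  truthAll[isEarly, ] <- truthE
  truthAll[isLateOnly, ] <- truthL
  truthAll[isLow, ] <- truthLow
  pk <- cbind(pk, truthAll)

  pk$nfySpacing <- NA_integer_
  nNfy <- sum(pk$nfy)
  if (nNfy)
    pk$nfySpacing[pk$nfy] <- sample(c(-1L, 1L), nNfy, replace = TRUE) *
      .truncNormInt(nNfy, cfg@nfyDecaSpacingMean, cfg@nfyDecaSpacingSd,
                    lo = 8L, hi = 60L)
  pk$hoxOffset <- NA_integer_
  nPbx <- sum(pk$pbxhox)
  if (nPbx)
    pk$hoxOffset[pk$pbxhox] <- sample(c(-1L, 1L), nPbx, replace = TRUE) *
      .truncNormInt(nPbx, cfg@hoxOffsetMean, cfg@hoxOffsetSd,
                    lo = 0L, hi = 60L)

  windowSeq <- character(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    windowSeq[i] <- .synthWindow(pk$deca[i], pk$hexa[i], pk$pbxhox[i],
                                 pk$nfy[i], pk$nfySpacing[i],
                                 pk$hoxOffset[i], w)
  }

  # ---- genome assembly -------------------------------------------------
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(chrom) {
    chars <- sample(.SYN_BASES, chromLen, replace = TRUE)
    idx <- which(pk$chrom == chrom)
    for (i in idx) {
      st <- pk$summit[i] - half
      chars[st:(st + w - 1L)] <-
        strsplit(windowSeq[i], "", fixed = TRUE)[[1L]]
    }
    paste(chars, collapse = "")
  }, ""))
  names(genome) <- chroms

  # ---- chromatin classes (fold-enrichment-filtered early peaks) -------
  eIdx <- which(isEarly)
  nE <- length(eIdx)
  clsCounts <- round(cfg@classProportions * nE)
  drift <- nE - sum(clsCounts)
  clsCounts[which.max(clsCounts)] <- clsCounts[which.max(clsCounts)] + drift
  pk$class <- NA_character_
  pk$class[eIdx] <- sample(rep(names(clsCounts), clsCounts))

  # ---- peak intervals, fold enrichment, retention ----------------------
  halfL <- sample((cfg@peakWidth %/% 2L - 80L):(cfg@peakWidth %/% 2L + 80L),
                  nrow(pk), replace = TRUE)
  halfR <- sample((cfg@peakWidth %/% 2L - 80L):(cfg@peakWidth %/% 2L + 80L),
                  nrow(pk), replace = TRUE)
  pk$start <- pk$summit - halfL
  pk$end <- pk$summit + halfR
  pk$fe <- round(10 + stats::rexp(nrow(pk), rate = 1 / 15), 2)
  pk$fe[isLow] <- round(stats::runif(sum(isLow), 2, 9.9), 2)

  retained <- sample(eIdx, round(cfg@retentionRate * nE))
  pk$retained <- FALSE
  pk$retained[retained] <- TRUE

  earlySet <- PeakSet(chrom = pk$chrom[isEarly | isLow],
                      start = pk$start[isEarly | isLow],
                      end = pk$end[isEarly | isLow],
                      summit = pk$summit[isEarly | isLow],
                      foldEnrichment = pk$fe[isEarly | isLow],
                      peakId = pk$peakId[isEarly | isLow],
                      seqlengths = seqlengths, label = "early")
  # retained sites keep their summit: the same genomic element stays bound
  lateIdx <- c(retained, which(isLateOnly))
  lateSummit <- pk$summit[lateIdx]
  lateIds <- c(sub("^early", "late", pk$peakId[retained]),
               pk$peakId[which(isLateOnly)])
  lateSet <- PeakSet(chrom = pk$chrom[lateIdx],
                     start = lateSummit - halfL[lateIdx],
                     end = lateSummit + halfR[lateIdx],
                     summit = lateSummit,
                     foldEnrichment = round(10 + stats::rexp(length(lateIdx),
                                                             1 / 15), 2),
                     peakId = lateIds,
                     seqlengths = seqlengths, label = "late")

  # ---- signal tracks ---------------------------------------------------
  binW <- 25L
  nb <- 2L * cfg@flank %/% binW
  dCenter <- (seq_len(nb) - 0.5) * binW - cfg@flank
  bump <- exp(-dCenter^2 / (2 * cfg@bumpWidth^2))
  trackFiles <- list()
  for (mark in names(cfg@signalParams)) {
    amp <- cfg@signalParams[[mark]]
    v <- rep(amp[pk$class[eIdx]], each = nb) * rep(bump, times = nE) +
      stats::rnorm(nE * nb, 0, cfg@noiseSd)
    v <- round(pmax(v, 0), 4)
    start0 <- rep((pk$summit[eIdx] - 1L) - cfg@flank, each = nb) +
      rep((seq_len(nb) - 1L) * binW, times = nE)
    df <- data.frame(chrom = rep(pk$chrom[eIdx], each = nb),
                     start = start0, end = start0 + binW, value = v)
    df <- df[order(match(df$chrom, chroms), df$start), ]
    f <- file.path(outDir, paste0("track_", mark, ".bedGraph"))
    utils::write.table(df, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    trackFiles[[mark]] <- f
  }

  # ---- genes, expression, DE ------------------------------------------
  ep <- cfg@expressionParams
  geneRows <- list()
  for (cls in names(cfg@classProportions)) {
    cand <- eIdx[pk$class[eIdx] == cls]
    pick <- if (length(cand) >= cfg@genesPerClass)
      sample(cand, cfg@genesPerClass) else
      sample(cand, cfg@genesPerClass, replace = TRUE)
    geneRows[[cls]] <- data.frame(
      geneId = sprintf("gene_%s_%03d", cls, seq_len(cfg@genesPerClass)),
      chrom = pk$chrom[pick],
      tss = pk$summit[pick] + sample(-20000:20000, cfg@genesPerClass,
                                     replace = TRUE),
      strand = sample(c("+", "-"), cfg@genesPerClass, replace = TRUE),
      class = cls, nearPeak = pk$peakId[pick])
  }
  genes <- do.call(rbind, geneRows)
  rownames(genes) <- NULL
  ctrlMean <- ep$baselineTPM[genes$class]
  kdMean <- ctrlMean * ifelse(genes$class == "Class4", ep$knockdownEffect, 1)
  reps <- function(mu) round(exp(log(mu) +
                                   stats::rnorm(length(mu), 0, ep$logSdTPM)), 3)
  tpm <- data.frame(gene_id = genes$geneId,
                    ctrl_1 = reps(ctrlMean), ctrl_2 = reps(ctrlMean),
                    ctrl_3 = reps(ctrlMean),
                    kd_1 = reps(kdMean), kd_2 = reps(kdMean),
                    kd_3 = reps(kdMean))
  trueDe <- genes$class == "Class4"
  de <- data.frame(
    gene_id = genes$geneId,
    fold_change = ifelse(trueDe, round(1 / ep$knockdownEffect, 4),
                         round(exp(abs(stats::rnorm(nrow(genes), 0, 0.05))),
                               4)),
    direction = ifelse(trueDe, "down",
                       sample(c("up", "down"), nrow(genes), replace = TRUE)),
    padj = ifelse(trueDe,
                  signif(stats::runif(nrow(genes), 1e-8, 1e-4), 3),
                  round(stats::runif(nrow(genes), 0.2, 1), 4)))

  # ---- qPCR Ct tables --------------------------------------------------
  qTargets <- c(utils::head(genes$geneId[genes$class == "Class4"], 4L),
                utils::head(genes$geneId[genes$class == "Class1"], 4L))
  qMeanCtrl <- ep$baselineTPM[genes$class[match(qTargets, genes$geneId)]]
  qMeanKd <- qMeanCtrl *
    ifelse(genes$class[match(qTargets, genes$geneId)] == "Class4",
           ep$knockdownEffect, 1)
  ctExpr <- do.call(rbind, lapply(seq_along(qTargets), function(i) {
    data.frame(target = qTargets[i],
               condition = rep(c("control", "kd"), each = 3L),
               replicate = rep(1:3, 2L),
               ct = round(c(28 - log2(qMeanCtrl[i]) + stats::rnorm(3, 0, 0.1),
                            28 - log2(qMeanKd[i]) + stats::rnorm(3, 0, 0.1)),
                          3),
               reference_ct = round(18 + stats::rnorm(6, 0, 0.05), 3))
  }))
  chipTargets <- utils::head(pk$peakId[eIdx][pk$class[eIdx] == "Class4"], 5L)
  ctChip <- do.call(rbind, lapply(chipTargets, function(tg) {
    inputCt <- round(25 + stats::rnorm(6, 0, 0.1), 3)
    data.frame(target = tg,
               condition = rep(c("specific", "IgG"), each = 3L),
               replicate = rep(1:3, 2L),
               ct = round(c(inputCt[1:3] - 3 + stats::rnorm(3, 0, 0.15),
                            inputCt[4:6] + stats::rnorm(3, 0, 0.15)), 3),
               reference_ct = inputCt)
  }))

  # ---- write files -----------------------------------------------------
  files <- list()
  files$genome <- file.path(outDir, "genome.fa")
  Biostrings::writeXStringSet(genome, files$genome)
  files$peaks_early <- file.path(outDir, "peaks_early.narrowPeak")
  writeNarrowPeak(earlySet, files$peaks_early)
  files$peaks_late <- file.path(outDir, "peaks_late.narrowPeak")
  writeNarrowPeak(lateSet, files$peaks_late)
  for (mark in names(trackFiles))
    files[[paste0("track_", mark)]] <- trackFiles[[mark]]
  files$tss <- file.path(outDir, "tss.bed")
  utils::write.table(
    data.frame(genes$chrom, genes$tss - 1L, genes$tss, genes$geneId, 0L,
               genes$strand),
    files$tss, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  files$tpm <- .writeTsv(tpm, file.path(outDir, "tpm.tsv"))
  files$de <- .writeTsv(de, file.path(outDir, "de.tsv"))
  files$ct_expression <- .writeTsv(ctExpr,
                                   file.path(outDir, "ct_expression.tsv"))
  files$ct_chip <- .writeTsv(ctChip, file.path(outDir, "ct_chip.tsv"))
  truthPeaks <- data.frame(
    peak_id = pk$peakId, chrom = pk$chrom, summit = pk$summit,
    category = pk$category, fe = pk$fe, retained = pk$retained,
    class = pk$class, deca = pk$deca, hexa = pk$hexa, pbxhox = pk$pbxhox,
    nfy = pk$nfy, nfy_spacing = pk$nfySpacing, hox_offset = pk$hoxOffset)
  files$truth_peaks <- .writeTsv(truthPeaks,
                                 file.path(outDir, "truth_peaks.tsv"))
  truthGenes <- data.frame(
    gene_id = genes$geneId, chrom = genes$chrom, tss = genes$tss,
    strand = genes$strand, class = genes$class, near_peak = genes$nearPeak,
    ctrl_mean = unname(ctrlMean), kd_mean = unname(kdMean),
    true_de = trueDe)
  files$truth_genes <- .writeTsv(truthGenes,
                                 file.path(outDir, "truth_genes.tsv"))
  files$chrom_sizes <- .writeTsv(
    data.frame(chrom = chroms, length = unname(seqlengths)),
    file.path(outDir, "chrom_sizes.tsv"))

  counts <- list(nEarly = nE, nLowFE = sum(isLow),
                 nLateOnly = sum(isLateOnly), nRetained = length(retained),
                 nGenes = nrow(genes), chromLength = chromLen)
  manifestPath <- file.path(outDir, "manifest.json")
  md5 <- tools::md5sum(unlist(files))
  manifest <- list(
    files = stats::setNames(as.list(unname(md5)),
                            basename(unlist(files))),
    seed = cfg@seed, counts = counts)
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE)
  files$manifest <- manifestPath
  invisible(list(dir = outDir, files = files, seqlengths = seqlengths,
                 counts = counts))
}

#' Read the chromosome sizes written by [generateDataset()]
#'
#' @param dir Dataset directory.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(dir) {
  df <- utils::read.delim(file.path(dir, "chrom_sizes.tsv"))
  stats::setNames(as.integer(df$length), df$chrom)
}
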