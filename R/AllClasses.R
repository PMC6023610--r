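#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom GenomeInfoDb seqlengths seqinfo Seqinfo seqlevels
#' @importFrom IRanges IRanges
NULL

#' PeakSet: an ordered collection of ChIP-seq peaks with summits
#'
#' A `PeakSet` wraps a [GenomicRanges::GRanges] whose metadata columns carry
#' the peak identifier (`peakId`), the absolute 1-based summit position
#' (`summit`) and the fold enrichment over input (`foldEnrichment`). Peaks are
#' kept sorted by (chromosome, start) and must lie within the chromosome
#' bounds recorded in the object's `seqinfo`.
#'
#' @slot peaks A `GRanges` with mcols `peakId`, `summit`, `foldEnrichment`.
#' @slot label A single string tagging the stage/condition (e.g. "early").
#' @export
setClass("PeakSet", representation(peaks = "GRanges", label = "character"))

setValidity("PeakSet", function(object) {
  gr <- object@peaks
  msg <- character()
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single string")
  need <- c("peakId", "summit", "foldEnrichment")
  if (!all(need %in% colnames(mcols(gr))))
    return(paste("peaks must carry mcols:", paste(need, collapse = ", ")))
  if (length(gr)) {
    if (anyDuplicated(mcols(gr)$peakId))
      msg <- c(msg, "peak ids must be unique")
    s <- mcols(gr)$summit
    if (any(s < start(gr) | s > end(gr)))
      msg <- c(msg, "summit must satisfy start <= summit <= end")
    if (any(mcols(gr)$foldEnrichment < 0))
      msg <- c(msg, "fold enrichment must be nonnegative")
    o <- order(as.integer(seqnames(gr)), start(gr))
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "peaks must be sorted by (chromosome, start)")
    sl <- seqlengths(gr)
    if (!any(is.na(sl))) {
      lens <- sl[as.character(seqnames(gr))]
      if (any(start(gr) < 1L) || any(end(gr) > lens))
        msg <- c(msg, "peaks must lie within chromosome bounds")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SignalTrack: genome-wide per-base signal
#'
#' Per-chromosome run-length encoded signal (coverage, histone-mark intensity
#' or any numeric score track). Uncovered bases carry value 0.
#'
#' @slot values An [IRanges::RleList] with one numeric `Rle` per chromosome.
#' @slot seqlengths Named integer vector of chromosome lengths.
#' @export
setClass("SignalTrack",
         representation(values = "RleList", seqlengths = "integer"))

setValidity("SignalTrack", function(object) {
  sl <- object@seqlengths
  if (is.null(names(sl)) || anyDuplicated(names(sl)))
    return("seqlengths must be uniquely named")
  if (!all(names(object@values) %in% names(sl)))
    return("track chromosomes absent from seqlengths")
  n <- vapply(object@values, length, 1L)
  if (!all(n == sl[names(object@values)]))
    return("per-chromosome run lengths must equal seqlengths")
  TRUE
})

#' SignalMatrix: reference-point signal around peak summits
#'
#' Rows are peaks (in the order of the source `PeakSet`), columns are
#' consecutive bins covering `[summit - flank, summit + flank)`.
#'
#' @slot values Numeric matrix, rownames are peak ids.
#' @slot flank Flank size in bp on each side of the summit.
#' @slot bin Bin width in bp; the matrix has `2 * flank / bin` columns.
#' @slot clipped Logical per row: TRUE where the window ran off the chromosome
#'   end and out-of-range bases were counted as 0.
#' @export
setClass("SignalMatrix",
         representation(values = "matrix", flank = "integer", bin = "integer",
                        clipped = "logical"))

setValidity("SignalMatrix", function(object) {
  msg <- character()
  if (object@flank %% object@bin != 0L)
    msg <- c(msg, "flank must be divisible by bin")
  if (ncol(object@values) != 2L * object@flank / object@bin)
    msg <- c(msg, "column count must equal 2*flank/bin")
  if (is.null(rownames(object@values)))
    msg <- c(msg, "rows must be named by peak id")
  if (length(object@clipped) != nrow(object@values))
    msg <- c(msg, "clipped flag must have one entry per row")
  if (length(msg)) msg else TRUE
})

#' ClassAssignment: chromatin-state labels for peaks
#'
#' Result of the two-level chromatin classification: every peak receives
#' exactly one label ("MPAD"/"nonMPAD" after the H3K4me1 step, or
#' "Class1".."Class4"/"nonMPAD" after the full classification). Cluster
#' provenance (raw k-means cluster index and per-cluster mean signal) and the
#' clustering parameters are retained.
#'
#' @slot labels Named character vector, peak id -> label.
#' @slot cluster Named integer vector, peak id -> raw k-means cluster index.
#' @slot clusterMeans Numeric matrix of per-cluster summary signal.
#' @slot params List of clustering parameters (k, seed, restarts, ...).
#' @export
setClass("ClassAssignment",
         representation(labels = "character", cluster = "integer",
                        clusterMeans = "matrix", params = "list"))

setValidity("ClassAssignment", function(object) {
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    return("labels must be uniquely named by peak id")
  if (!identical(names(object@labels), names(object@cluster)))
    return("labels and cluster must be named identically")
  TRUE
})

#' SyntheticConfig: parameters of the synthetic dataset generator
#'
#' Holds every tunable of [generateDataset()]. Defaults encode the structure
#' of a two-stage TALE ChIP-seq experiment: ~60% of early peaks retained at
#' the late stage, 58% of late-only peaks within 40 kb of an early peak,
#' DECA-rich early windows (75%) vs HEXA-rich late-only windows (44%, counted
#' only without DECA), PBX:HOX sites offset ~10 bp from summits, CCAAT sites
#' ~20 bp from DECA sites, and a 25%/75% MPAD/non-MPAD split driving
#' H3K4me1/H3K27ac/H3K27me3 signal and class-coupled expression.
#'
#' @export
setClass("SyntheticConfig", representation(
  seed = "integer", nChroms = "integer", chromLength = "integer",
  nEarlyPeaks = "integer", retentionRate = "numeric",
  nLateOnlyPeaks = "integer", fracLateOnlyWithin40kb = "numeric",
  proximityDistance = "integer", earlySpacing = "integer",
  peakWidth = "integer", windowWidth = "integer",
  motifRates = "list", nfyRate = "numeric",
  nfyDecaSpacingMean = "numeric", nfyDecaSpacingSd = "numeric",
  hoxOffsetMean = "numeric", hoxOffsetSd = "numeric",
  classProportions = "numeric", signalParams = "list",
  bumpWidth = "numeric", noiseSd = "numeric", flank = "integer",
  genesPerClass = "integer", expressionParams = "list",
  lowFEFraction = "numeric"))

.CLASS_LABELS <- c("Class1", "Class2", "Class3", "Class4", "nonMPAD")

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  frac <- c(retentionRate = object@retentionRate,
            fracLateOnlyWithin40kb = object@fracLateOnlyWithin40kb,
            nfyRate = object@nfyRate, lowFEFraction = object@lowFEFraction)
  bad <- names(frac)[frac < 0 | frac > 1]
  if (length(bad))
    msg <- c(msg, paste0("fraction out of [0,1]: ", paste(bad, collapse = ", ")))
  cp <- object@classProportions
  if (!setequal(names(cp), .CLASS_LABELS))
    msg <- c(msg, "classProportions must be named Class1..Class4, nonMPAD")
  else if (abs(sum(cp) - 1) > 1e-9)
    msg <- c(msg, "classProportions must sum to 1")
  if (any(cp < 0)) msg <- c(msg, "classProportions must be nonnegative")
  if (!setequal(names(object@motifRates), c("early", "late_only")))
    msg <- c(msg, "motifRates must have entries 'early' and 'late_only'")
  else {
    for (stage in names(object@motifRates)) {
      r <- object@motifRates[[stage]]
      if (!all(c("DECA", "HEXA", "PBXHOX") %in% names(r)))
        msg <- c(msg, paste0("motifRates$", stage,
                             " must name DECA, HEXA and PBXHOX"))
      else if (any(r < 0 | r > 1))
        msg <- c(msg, paste0("motifRates$", stage, " out of [0,1]"))
      else if (r[["DECA"]] + r[["HEXA"]] > 1)
        msg <- c(msg, paste0("motifRates$", stage,
                             ": DECA + HEXA rates exceed 1"))
    }
  }
  pos <- c(nChroms = object@nChroms, nEarlyPeaks = object@nEarlyPeaks,
           nLateOnlyPeaks = object@nLateOnlyPeaks,
           proximityDistance = object@proximityDistance,
           earlySpacing = object@earlySpacing, peakWidth = object@peakWidth,
           windowWidth = object@windowWidth, flank = object@flank,
           genesPerClass = object@genesPerClass)
  bad <- names(pos)[pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("must be positive: ", paste(bad, collapse = ", ")))
  if (object@windowWidth %% 2L != 0L)
    msg <- c(msg, "windowWidth must be even")
  if (!setequal(names(object@signalParams),
                c("H3K4me1", "H3K27ac_early", "H3K27ac_late", "H3K27me3")))
    msg <- c(msg, "signalParams must name the four histone-mark tracks")
  if (length(msg)) msg else TRUE
})
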