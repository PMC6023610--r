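#' Construct a PeakSet
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end 1-based inclusive interval bounds (width = end - start + 1).
#' @param summit Absolute 1-based summit positions.
#' @param foldEnrichment Nonnegative fold enrichment per peak.
#' @param peakId Unique peak identifiers; autogenerated when NULL.
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param label Stage/condition tag.
#' @return A [PeakSet-class] sorted by (chromosome, start).
#' @export
PeakSet <- function(chrom, start, end, summit, foldEnrichment,
                    peakId = NULL, seqlengths, label = "peaks") {
  n <- length(chrom)
  if (is.null(peakId))
    peakId <- sprintf("%s_%05d", label, seq_len(n))
  gr <- GRanges(chrom, IRanges(start, end),
                seqinfo = Seqinfo(names(seqlengths),
                                  as.integer(seqlengths)))
  mcols(gr)$peakId <- as.character(peakId)
  mcols(gr)$summit <- as.integer(summit)
  mcols(gr)$foldEnrichment <- as.numeric(foldEnrichment)
  gr <- gr[order(as.integer(seqnames(gr)), start(gr))]
  new("PeakSet", peaks = gr, label = label)
}

#' @describeIn PeakSet Number of peaks.
#' @param x A PeakSet.
#' @export
setMethod("length", "PeakSet", function(x) length(x@peaks))

#' Accessors for PeakSet
#'
#' `peakRanges()` returns the underlying `GRanges`; `peakIds()`, `summits()`
#' and `foldEnrichment()` return the per-peak columns (named by peak id);
#' `peakLabel()` returns the stage/condition tag.
#'
#' @param x A [PeakSet-class].
#' @name PeakSet-accessors
NULL

#' @rdname PeakSet-accessors
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))
#' @rdname PeakSet-accessors
#' @export
setMethod("peakRanges", "PeakSet", function(x) x@peaks)

#' @rdname PeakSet-accessors
#' @export
setGeneric("peakIds", function(x) standardGeneric("peakIds"))
#' @rdname PeakSet-accessors
#' @export
setMethod("peakIds", "PeakSet", function(x) mcols(x@peaks)$peakId)

#' @rdname PeakSet-accessors
#' @export
setGeneric("summits", function(x) standardGeneric("summits"))
#' @rdname PeakSet-accessors
#' @export
setMethod("summits", "PeakSet", function(x) {
  stats::setNames(mcols(x@peaks)$summit, mcols(x@peaks)$peakId)
})

#' @rdname PeakSet-accessors
#' @export
setGeneric("foldEnrichment", function(x) standardGeneric("foldEnrichment"))
#' @rdname PeakSet-accessors
#' @export
setMethod("foldEnrichment", "PeakSet", function(x) {
  stats::setNames(mcols(x@peaks)$foldEnrichment, mcols(x@peaks)$peakId)
})

#' @rdname PeakSet-accessors
#' @export
setGeneric("peakLabel", function(x) standardGeneric("peakLabel"))
#' @rdname PeakSet-accessors
#' @export
setMethod("peakLabel", "PeakSet", function(x) x@label)

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet '", object@label, "' with ", length(object),
      " peaks on ", length(seqlevels(object@peaks)), " chromosomes\n",
      sep = "")
  if (length(object)) {
    fe <- mcols(object@peaks)$foldEnrichment
    cat("  fold enrichment: ", sprintf("%.2f", min(fe)), " - ",
        sprintf("%.2f", max(fe)), "\n", sep = "")
  }
})

# Subset a PeakSet by a logical/integer index or peak ids (order preserved).
.subsetPeakSet <- function(x, i) {
  if (is.character(i)) i <- match(i, peakIds(x))
  new("PeakSet", peaks = x@peaks[i], label = x@label)
}

#' Read peaks from a narrowPeak file
#'
#' Parses ENCODE narrowPeak (BED6+4). Coordinates on disk are 0-based
#' half-open and are converted to 1-based; the summit column (offset from
#' interval start) is converted to an absolute position. An offset of -1
#' means "no summit called" and falls back to the interval midpoint (a
#' message reports how many peaks that affected).
#'
#' @param file Path to a narrowPeak file.
#' @param seqlengths Named chromosome lengths for the target genome.
#' @param label Stage/condition tag for the resulting set.
#' @return A [PeakSet-class].
#' @export
readNarrowPeak <- function(file, seqlengths, label = "peaks") {
  gr <- rtracklayer::import(file, format = "BED",
                            extraCols = c(signalValue = "numeric",
                                          pValue = "numeric",
                                          qValue = "numeric",
                                          peak = "integer"))
  off <- mcols(gr)$peak
  noSummit <- off < 0L
  if (any(noSummit)) {
    message(sum(noSummit), " peak(s) without a called summit; ",
            "using the interval midpoint")
    off[noSummit] <- (width(gr)[noSummit] - 1L) %/% 2L
  }
  ids <- mcols(gr)$name
  if (is.null(ids) || anyDuplicated(ids))
    ids <- sprintf("%s_%05d", label, seq_along(gr))
  PeakSet(chrom = as.character(seqnames(gr)), start = start(gr),
          end = end(gr), summit = start(gr) + off,
          foldEnrichment = mcols(gr)$signalValue, peakId = ids,
          seqlengths = seqlengths, label = label)
}

#' Write a PeakSet as narrowPeak
#'
#' @param x A [PeakSet-class].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writeNarrowPeak <- function(x, file) {
  gr <- x@peaks
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    name = mcols(gr)$peakId,
    score = 0L,
    strand = ".",
    signalValue = mcols(gr)$foldEnrichment,
    pValue = -1,
    qValue = -1,
    peak = mcols(gr)$summit - start(gr))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
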