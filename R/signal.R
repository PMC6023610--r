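# Reference-point signal matrices around peak summits, mean profiles,
# between-stage log2 change and average score profiles.

#' Construct a SignalTrack
#'
#' @param values An `RleList` (one numeric `Rle` per chromosome) or a
#'   `GRanges` with a `score` column (runs; uncovered bases become 0).
#' @param seqlengths Named chromosome lengths.
#' @return A [SignalTrack-class].
#' @export
SignalTrack <- function(values, seqlengths) {
  seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  if (is(values, "GRanges")) {
    GenomeInfoDb::seqlevels(values) <- names(seqlengths)
    GenomeInfoDb::seqlengths(values) <- seqlengths
    values <- GenomicRanges::coverage(values, weight = "score")
  }
  values <- methods::as(values, "RleList")
  # ensure full chromosome extent
  for (chrom in names(seqlengths)) {
    if (!chrom %in% names(values)) {
      values[[chrom]] <- S4Vectors::Rle(0, seqlengths[[chrom]])
    } else if (length(values[[chrom]]) < seqlengths[[chrom]]) {
      pad <- seqlengths[[chrom]] - length(values[[chrom]])
      values[[chrom]] <- c(values[[chrom]], S4Vectors::Rle(0, pad))
    }
  }
  new("SignalTrack", values = values[names(seqlengths)],
      seqlengths = seqlengths)
}

setMethod("show", "SignalTrack", function(object) {
  tot <- sum(vapply(object@values, function(r) sum(as.numeric(r)), 0))
  cat("SignalTrack over ", length(object@seqlengths), " chromosomes (",
      sum(as.numeric(object@seqlengths)), " bp), integral ",
      format(tot, digits = 6), "\n", sep = "")
})

#' Read a bedGraph file into a SignalTrack
#'
#' bedGraph intervals are 0-based half-open on disk; overlapping runs are
#' summed by coverage, uncovered bases are 0.
#'
#' @param file Path to a bedGraph file.
#' @param seqlengths Named chromosome lengths.
#' @return A [SignalTrack-class].
#' @export
readBedGraph <- function(file, seqlengths) {
  gr <- rtracklayer::import(file, format = "bedGraph")
  SignalTrack(gr, seqlengths)
}

#' Write a SignalTrack as bedGraph
#'
#' Zero-valued runs are omitted.
#'
#' @param track A [SignalTrack-class].
#' @param file Output path.
#' @export
writeBedGraph <- function(track, file) {
  rows <- lapply(names(track@values), function(chrom) {
    r <- track@values[[chrom]]
    v <- S4Vectors::runValue(r)
    len <- S4Vectors::runLength(r)
    end1 <- cumsum(len)
    start0 <- end1 - len
    keep <- v != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom, start = start0[keep], end = end1[keep],
               value = v[keep])
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Reference-point signal matrix around peak summits
#'
#' For each peak, consecutive bins tile `[summit - flank, summit + flank)`
#' (0-based half-open). The bin value is the mean track value over the bin's
#' bases; bases beyond the chromosome ends contribute 0 and such rows are
#' flagged `clipped`. Row order follows the peak set.
#'
#' @param track A [SignalTrack-class].
#' @param x A [PeakSet-class].
#' @param flank Flank in bp on each side of the summit (default 1000).
#' @param bin Bin width in bp (default 25); `flank` must be divisible by it.
#' @return A [SignalMatrix-class] with `2*flank/bin` columns.
#' @export
computeMatrix <- function(track, x, flank = 1000, bin = 25) {
  stopifnot(is(track, "SignalTrack"), is(x, "PeakSet"))
  flank <- as.integer(flank)
  bin <- as.integer(bin)
  if (flank %% bin != 0L) stop("flank must be divisible by bin")
  ncolM <- 2L * flank %/% bin
  ids <- peakIds(x)
  vals <- matrix(0, nrow = length(x), ncol = ncolM,
                 dimnames = list(ids, NULL))
  clipped <- logical(length(x))
  chromOf <- as.character(seqnames(x@peaks))
  s <- mcols(x@peaks)$summit
  for (chrom in unique(chromOf)) {
    if (!chrom %in% names(track@values))
      stop("track has no chromosome ", chrom)
    r <- track@values[[chrom]]
    len <- length(r)
    rows <- which(chromOf == chrom)
    # 1-based start of the first bin for each peak on this chromosome
    first <- s[rows] - flank
    binStart <- rep(first, each = ncolM) +
      rep(seq_len(ncolM) - 1L, times = length(rows)) * bin
    binEnd <- binStart + bin - 1L
    cs <- pmax(binStart, 1L)
    ce <- pmin(binEnd, len)
    ok <- cs <= ce
    sums <- numeric(length(binStart))
    if (any(ok)) {
      v <- IRanges::Views(r, IRanges(cs[ok], ce[ok]))
      sums[ok] <- IRanges::viewSums(v)
    }
    vals[rows, ] <- matrix(sums / bin, ncol = ncolM, byrow = TRUE)
    clipFlag <- matrix(binStart < 1L | binEnd > len, ncol = ncolM,
                       byrow = TRUE)
    clipped[rows] <- rowSums(clipFlag) > 0L
  }
  new("SignalMatrix", values = vals, flank = flank, bin = bin,
      clipped = clipped)
}

#' @describeIn computeMatrix Accessor for the numeric matrix.
#' @export
setGeneric("matrixValues", function(x) standardGeneric("matrixValues"))
#' @rdname computeMatrix
#' @export
setMethod("matrixValues", "SignalMatrix", function(x) x@values)

setMethod("show", "SignalMatrix", function(object) {
  cat("SignalMatrix: ", nrow(object@values), " peaks x ",
      ncol(object@values), " bins (flank ", object@flank, " bp, bin ",
      object@bin, " bp), ", sum(object@clipped), " clipped row(s)\n",
      sep = "")
})

#' Column-wise mean profile of a signal matrix
#'
#' @param x A [SignalMatrix-class].
#' @param rows Optional subset of row ids (peak ids).
#' @return Numeric vector of per-bin means.
#' @export
meanProfile <- function(x, rows = NULL) {
  stopifnot(is(x, "SignalMatrix"))
  v <- x@values
  if (!is.null(rows)) {
    bad <- setdiff(rows, rownames(v))
    if (length(bad)) stop("unknown row id(s): ",
                          paste(utils::head(bad, 5L), collapse = ", "))
    v <- v[rows, , drop = FALSE]
  }
  if (!nrow(v)) stop("empty row subset")
  colMeans(v)
}

#' Cell-wise log2 change between two signal matrices
#'
#' `log2((v2 + pseudocount) / (v1 + pseudocount))` per cell, for matrices of
#' identical shape, row order, flank and bin. Also returns the per-row mean
#' change.
#'
#' @param matrixT2,matrixT1 [SignalMatrix-class] objects (later, earlier).
#' @param pseudocount Added to both matrices before the ratio (default 1).
#' @return A list: `lfc` (a [SignalMatrix-class]) and `rowMeanChange` (named
#'   numeric).
#' @export
log2Change <- function(matrixT2, matrixT1, pseudocount = 1) {
  stopifnot(is(matrixT2, "SignalMatrix"), is(matrixT1, "SignalMatrix"))
  if (!identical(dim(matrixT2@values), dim(matrixT1@values)) ||
      !identical(rownames(matrixT2@values), rownames(matrixT1@values)) ||
      matrixT2@flank != matrixT1@flank || matrixT2@bin != matrixT1@bin)
    stop("matrices differ in shape, row order, flank or bin")
  lfc <- log2((matrixT2@values + pseudocount) /
              (matrixT1@values + pseudocount))
  out <- new("SignalMatrix", values = lfc, flank = matrixT2@flank,
             bin = matrixT2@bin,
             clipped = matrixT2@clipped | matrixT1@clipped)
  list(lfc = out,
       rowMeanChange = stats::setNames(rowMeans(lfc), rownames(lfc)))
}

#' Average score profile around peak summits
#'
#' [computeMatrix()] followed by [meanProfile()]; suitable for score tracks
#' (e.g. sequence-conservation probabilities) which may be negative.
#'
#' @inheritParams computeMatrix
#' @return Numeric vector of per-bin mean scores.
#' @export
averageScore <- function(track, x, flank = 1000, bin = 25) {
  meanProfile(computeMatrix(track, x, flank = flank, bin = bin))
}

#' Persist / load a SignalMatrix as TSV with a JSON sidecar
#'
#' The TSV holds the matrix with a `peakId` first column; the sidecar records
#' flank, bin, row order and clipped flags.
#'
#' @param x A [SignalMatrix-class].
#' @param file TSV path; the sidecar is `<file>.json`.
#' @export
writeSignalMatrix <- function(x, file) {
  df <- data.frame(peakId = rownames(x@values), x@values,
                   check.names = FALSE)
  .writeTsv(df, file)
  jsonlite::write_json(
    list(flank = x@flank, bin = x@bin, rowOrder = rownames(x@values),
         clipped = x@clipped),
    paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname writeSignalMatrix
#' @export
readSignalMatrix <- function(file) {
  meta <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  df <- utils::read.delim(file, check.names = FALSE)
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- df$peakId
  dimnames(v) <- list(df$peakId, NULL)
  new("SignalMatrix", values = v[meta$rowOrder, , drop = FALSE],
      flank = as.integer(meta$flank), bin = as.integer(meta$bin),
      clipped = as.logical(meta$clipped))
}
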