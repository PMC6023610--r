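# Peak-level operations: fold-enrichment filtering, summit colocalization,
# stage-specific subtraction, nearest-summit distances and random baselines.
# All distance thresholds are inclusive.

#' Filter peaks by fold enrichment
#'
#' Retains peaks whose fold enrichment is greater than or equal to `minFE`
#' (boundary inclusive), preserving order.
#'
#' @param x A [PeakSet-class].
#' @param minFE Minimum fold enrichment (default 10).
#' @return A filtered [PeakSet-class].
#' @export
filterByFoldEnrichment <- function(x, minFE = 10) {
  stopifnot(is(x, "PeakSet"))
  .subsetPeakSet(x, mcols(x@peaks)$foldEnrichment >= minFE)
}

# For every query summit, the minimum |query - reference| over reference
# summits on the same chromosome (NA when the chromosome has none).
.nearestDist <- function(qChrom, qSummit, rChrom, rSummit) {
  out <- rep(NA_real_, length(qSummit))
  refByChrom <- split(rSummit, rChrom)
  qIdxByChrom <- split(seq_along(qSummit), qChrom)
  for (chrom in intersect(names(qIdxByChrom), names(refByChrom))) {
    refs <- sort(refByChrom[[chrom]])
    idx <- qIdxByChrom[[chrom]]
    q <- qSummit[idx]
    pos <- findInterval(q, refs)
    dLeft <- ifelse(pos >= 1L, q - refs[pmax(pos, 1L)], Inf)
    dRight <- ifelse(pos < length(refs), refs[pmin(pos + 1L, length(refs))] - q,
                     Inf)
    out[idx] <- pmin(dLeft, dRight)
  }
  out
}

#' Summit-based colocalization of two peak sets
#'
#' A peak in `a` is colocalized iff some peak in `b` on the same chromosome
#' has a summit within `maxSummitDist` bp (inclusive), and vice versa. Each
#' peak is counted once regardless of how many partners it has; all
#' qualifying pairs are also returned.
#'
#' @param a,b [PeakSet-class] objects on the same genome.
#' @param maxSummitDist Maximum summit distance in bp (default 50).
#' @return A list with `pairs` (data.frame idA, idB, distance),
#'   `colocalizedA`/`colocalizedB` (logical per peak, named),
#'   `countA`/`countB` and `percentA`/`percentB`.
#' @export
colocalize <- function(a, b, maxSummitDist = 50) {
  stopifnot(is(a, "PeakSet"), is(b, "PeakSet"))
  .checkSameGenome(a, b)
  sa <- summits(a)
  sb <- summits(b)
  ca <- as.character(seqnames(a@peaks))
  cb <- as.character(seqnames(b@peaks))
  dA <- .nearestDist(ca, sa, cb, sb)
  dB <- .nearestDist(cb, sb, ca, sa)
  colA <- !is.na(dA) & dA <= maxSummitDist
  colB <- !is.na(dB) & dB <= maxSummitDist
  pairs <- list()
  bByChrom <- split(seq_along(sb), cb)
  for (chrom in intersect(unique(ca), names(bByChrom))) {
    bi <- bByChrom[[chrom]]
    o <- order(sb[bi])
    bi <- bi[o]
    posB <- sb[bi]
    ai <- which(ca == chrom)
    lo <- findInterval(sa[ai] - maxSummitDist - 0.5, posB) + 1L
    hi <- findInterval(sa[ai] + maxSummitDist + 0.5, posB)
    keep <- which(hi >= lo)
    if (length(keep)) {
      reps <- hi[keep] - lo[keep] + 1L
      aIdx <- rep(ai[keep], reps)
      bIdx <- bi[unlist(lapply(keep, function(k) seq(lo[k], hi[k])))]
      pairs[[chrom]] <- data.frame(
        idA = names(sa)[aIdx], idB = names(sb)[bIdx],
        distance = abs(sa[aIdx] - sb[bIdx]), row.names = NULL)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(idA = character(), idB = character(), distance = numeric())
  rownames(pairs) <- NULL
  names(colA) <- names(sa)
  names(colB) <- names(sb)
  list(pairs = pairs,
       colocalizedA = colA, colocalizedB = colB,
       countA = sum(colA), countB = sum(colB),
       percentA = if (length(colA)) 100 * mean(colA) else NA_real_,
       percentB = if (length(colB)) 100 * mean(colB) else NA_real_)
}

#' Late-stage-only peaks by summit subtraction
#'
#' Returns the peaks of `late` that have no `early` summit within
#' `maxSummitDist` bp. For a stringent subtraction, `earlyUnfiltered` should
#' be the early peak set *before* any fold-enrichment cutoff, so that weak
#' early binding evidence still disqualifies a late peak from "late-only".
#'
#' @param late Late-stage [PeakSet-class].
#' @param earlyUnfiltered Early-stage [PeakSet-class], pre-FE-filter.
#' @param maxSummitDist Maximum summit distance in bp (default 50).
#' @return A [PeakSet-class] of late-only peaks (label suffixed "_only").
#' @export
stageOnly <- function(late, earlyUnfiltered, maxSummitDist = 50) {
  stopifnot(is(late, "PeakSet"), is(earlyUnfiltered, "PeakSet"))
  .checkSameGenome(late, earlyUnfiltered)
  d <- .nearestDist(as.character(seqnames(late@peaks)), summits(late),
                    as.character(seqnames(earlyUnfiltered@peaks)),
                    summits(earlyUnfiltered))
  keep <- is.na(d) | d > maxSummitDist
  out <- .subsetPeakSet(late, keep)
  out@label <- paste0(late@label, "_only")
  out
}

#' Distance from each query summit to the nearest reference summit
#'
#' @param query,reference [PeakSet-class] objects.
#' @return Named numeric vector (bp); NA where the query chromosome has no
#'   reference peak.
#' @export
nearestSummitDistance <- function(query, reference) {
  stopifnot(is(query, "PeakSet"), is(reference, "PeakSet"))
  d <- .nearestDist(as.character(seqnames(query@peaks)), summits(query),
                    as.character(seqnames(reference@peaks)),
                    summits(reference))
  stats::setNames(d, peakIds(query))
}

#' Fraction of peaks within a distance threshold
#'
#' Percent of distances that are `<= threshold` (inclusive). Missing
#' distances (no reference peak on the chromosome) count as not-within but
#' stay in the denominator, so the percentage is over all query peaks.
#'
#' @param distances Numeric vector from [nearestSummitDistance()].
#' @param threshold Distance threshold in bp (default 40000).
#' @return Percent in `[0, 100]`.
#' @export
fractionWithin <- function(distances, threshold = 40000) {
  if (!length(distances)) return(NA_real_)
  100 * sum(!is.na(distances) & distances <= threshold) / length(distances)
}

#' Fixed-width windows centered on peak summits
#'
#' For summit s (1-based) and even width w, the window covers
#' `[s - w/2, s + w/2)` in 0-based half-open convention, i.e. the w bases
#' `s - w/2 .. s + w/2 - 1` in 1-based coordinates, clipped to chromosome
#' bounds (a warning reports how many windows were clipped).
#'
#' @param x A [PeakSet-class].
#' @param width Window width in bp, even (default 200).
#' @return A `GRanges` named by peak id.
#' @export
summitWindows <- function(x, width = 200) {
  stopifnot(is(x, "PeakSet"))
  if (width %% 2 != 0) stop("width must be even")
  gr <- x@peaks
  half <- width %/% 2L
  s <- mcols(gr)$summit
  st <- s - half
  en <- s + half - 1L
  lens <- seqlengths(gr)[as.character(seqnames(gr))]
  clipped <- st < 1L | en > lens
  if (any(clipped))
    warning(sum(clipped), " window(s) clipped at chromosome bounds")
  st <- pmax(st, 1L)
  en <- pmin(en, lens)
  out <- GRanges(seqnames(gr), IRanges(st, en), seqinfo = seqinfo(gr))
  names(out) <- mcols(gr)$peakId
  mcols(out)$clipped <- clipped
  out
}

#' Random chromosomal coordinates
#'
#' Draws `n` intervals of fixed length: the chromosome is chosen with
#' probability proportional to its length and the start uniformly within the
#' valid range. The summit is the interval midpoint. Reproducible by seed.
#'
#' @param seqlengths Named chromosome lengths.
#' @param n Number of intervals.
#' @param length Interval length in bp (must fit the shortest chromosome).
#' @param seed Integer seed.
#' @return A [PeakSet-class] labeled "random" with fold enrichment 0.
#' @export
randomCoordinates <- function(seqlengths, n, length, seed) {
  if (length > min(seqlengths)) stop("length exceeds the shortest chromosome")
  .withSeed(seed, {
    chrom <- sample(names(seqlengths), n, replace = TRUE,
                    prob = as.numeric(seqlengths))
    maxStart <- seqlengths[chrom] - length + 1L
    start <- floor(stats::runif(n, 1, maxStart + 1))
    start <- pmin(as.integer(start), as.integer(maxStart))
    PeakSet(chrom = chrom, start = start, end = start + length - 1L,
            summit = start + (length - 1L) %/% 2L,
            foldEnrichment = rep(0, n),
            peakId = sprintf("rand_%06d", seq_len(n)),
            seqlengths = seqlengths, label = "random")
  })
}
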