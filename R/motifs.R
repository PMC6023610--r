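# IUPAC consensus motif scanning on both strands, per-sequence presence with
# nested-motif exclusion (the DECA/HEXA rule), prevalence, summit-offset
# profiles, two-population Fisher enrichment and motif-motif spacing.

#' Motif registries
#'
#' A motif registry is a data.frame with columns `name`, `consensus` (IUPAC)
#' and `excludes` (NA, or the name of a parent motif whose presence in a
#' sequence suppresses counting this motif there). `defaultMotifRegistry()`
#' returns the TALE-biology registry: the 10 bp DECA site (TGATTGACAG,
#' adjacent Pbx and Prep half-sites bound by Prep:Pbx dimers), the 6 bp HEXA
#' site (TGACAG, monomeric Prep/Meis; counted only in sequences lacking a
#' DECA match), the PBX:HOX dimer site TGATTTAT and its generic half-site
#' form TGATNNAT, the NF-Y CCAAT box, and the SP/KLF and AT-rich motifs
#' recovered alongside them (M = A or C; R = A or G).
#'
#' @param name,consensus,excludes Parallel vectors defining the motifs.
#' @return A validated motif registry data.frame.
#' @export
motifRegistry <- function(name, consensus, excludes = NA_character_) {
  reg <- data.frame(name = as.character(name),
                    consensus = toupper(as.character(consensus)),
                    excludes = as.character(excludes),
                    stringsAsFactors = FALSE)
  .validateRegistry(reg)
  reg
}

#' @rdname motifRegistry
#' @export
defaultMotifRegistry <- function() {
  motifRegistry(
    name = c("DECA", "HEXA", "PBXHOX", "PBXHOX_halfsite", "NFY",
             "SPKLF", "ATRTTAA"),
    consensus = c("TGATTGACAG", "TGACAG", "TGATTTAT", "TGATNNAT", "CCAAT",
                  "CCMCRCCC", "ATRTTAA"),
    excludes = c(NA, "DECA", NA, NA, NA, NA, NA))
}

.validateRegistry <- function(reg) {
  stopifnot(is.data.frame(reg),
            all(c("name", "consensus", "excludes") %in% names(reg)))
  if (anyDuplicated(reg$name)) stop("duplicate motif names in registry")
  if (any(!nzchar(reg$consensus))) stop("empty consensus in registry")
  for (cons in reg$consensus) .iupacRegex(cons)  # errors on bad codes
  ex <- reg$excludes[!is.na(reg$excludes)]
  missing <- setdiff(ex, reg$name)
  if (length(missing))
    stop("exclusion references unknown motif(s): ",
         paste(missing, collapse = ", "))
  # detect cycles by walking each chain
  for (nm in reg$name) {
    seen <- character()
    cur <- nm
    while (!is.na(cur <- reg$excludes[match(cur, reg$name)])) {
      if (cur %in% c(seen, nm)) stop("exclusion cycle involving motif ", nm)
      seen <- c(seen, cur)
    }
  }
  invisible(reg)
}

#' Read / write a motif registry as YAML
#'
#' The YAML file is a list of entries with fields `name`, `consensus` and
#' optional `excludes`.
#'
#' @param file Path to a YAML file.
#' @return A motif registry data.frame.
#' @export
readMotifRegistry <- function(file) {
  entries <- yaml::read_yaml(file)
  motifRegistry(
    name = vapply(entries, `[[`, "", "name"),
    consensus = vapply(entries, `[[`, "", "consensus"),
    excludes = vapply(entries, function(e)
      if (is.null(e$excludes)) NA_character_ else e$excludes, ""))
}

#' @rdname readMotifRegistry
#' @param registry A motif registry data.frame.
#' @export
writeMotifRegistry <- function(registry, file) {
  .validateRegistry(registry)
  entries <- lapply(seq_len(nrow(registry)), function(i) {
    e <- list(name = registry$name[i], consensus = registry$consensus[i])
    if (!is.na(registry$excludes[i])) e$excludes <- registry$excludes[i]
    e
  })
  yaml::write_yaml(entries, file)
  invisible(file)
}

#' Scan a sequence for an IUPAC consensus on both strands
#'
#' Reports every (possibly overlapping) match of the consensus and of its
#' reverse complement, in forward-strand 1-based coordinates, ordered by
#' position with "+" before "-" at ties. An N in the subject matches only the
#' motif code N.
#'
#' @param sequence A single DNA string (A/C/G/T/N).
#' @param consensus IUPAC consensus string, or a single-row slice of a
#'   registry.
#' @param motifName Name recorded in the hit table.
#' @return data.frame with columns `start` (1-based), `end`, `center`,
#'   `strand`, `motif`.
#' @export
scanMotif <- function(sequence, consensus, motifName = consensus) {
  stopifnot(length(sequence) == 1L)
  sequence <- toupper(sequence)
  len <- nchar(consensus)
  fwd <- .regexStarts(sequence, .iupacRegex(consensus))
  rcCons <- .revcompConsensus(consensus)
  rev <- .regexStarts(sequence, .iupacRegex(rcCons))
  hits <- data.frame(
    start = c(fwd, rev),
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    stringsAsFactors = FALSE)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  hits$end <- hits$start + len - 1L
  hits$center <- hits$start + (len - 1) / 2
  hits$motif <- rep(motifName, nrow(hits))
  rownames(hits) <- NULL
  hits[, c("start", "end", "center", "strand", "motif")]
}

# Raw hit count of a named registry motif in one sequence.
.hitCount <- function(sequence, registry, motifName) {
  cons <- registry$consensus[match(motifName, registry$name)]
  if (is.na(cons)) stop("motif not in registry: ", motifName)
  nrow(scanMotif(sequence, cons, motifName))
}

#' Exclusion-aware motif presence
#'
#' TRUE iff the sequence has at least one hit of the motif AND its exclusion
#' parent (if any) has zero hits in the same sequence. This implements the
#' rule that HEXA motifs are only counted in sequences without any DECA
#' motif.
#'
#' @param sequence A single DNA string.
#' @param motifName Name of a registry motif.
#' @param registry Motif registry (default [defaultMotifRegistry()]).
#' @return Logical scalar.
#' @export
motifPresence <- function(sequence, motifName,
                          registry = defaultMotifRegistry()) {
  .validateRegistry(registry)
  i <- match(motifName, registry$name)
  if (is.na(i)) stop("motif not in registry: ", motifName)
  if (.hitCount(sequence, registry, motifName) == 0L) return(FALSE)
  parent <- registry$excludes[i]
  if (is.na(parent)) return(TRUE)
  .hitCount(sequence, registry, parent) == 0L
}

# Presence matrix (sequences x motifs) with exclusions applied. Only the
# requested motifs and their exclusion parents are scanned.
.presenceMatrix <- function(sequences, registry,
                            motifs = registry$name) {
  needed <- unique(c(motifs,
                     registry$excludes[match(motifs, registry$name)]))
  needed <- needed[!is.na(needed)]
  raw <- vapply(needed, function(nm) {
    cons <- registry$consensus[match(nm, registry$name)]
    re <- .iupacRegex(cons)
    reRc <- .iupacRegex(.revcompConsensus(cons))
    vapply(sequences, function(s) {
      s <- toupper(s)
      length(.regexStarts(s, re)) + length(.regexStarts(s, reRc)) > 0L
    }, TRUE, USE.NAMES = FALSE)
  }, logical(length(sequences)))
  if (length(sequences) == 1L) raw <- matrix(raw, nrow = 1L,
                                             dimnames = list(NULL, needed))
  out <- raw
  for (nm in needed) {
    parent <- registry$excludes[match(nm, registry$name)]
    if (!is.na(parent))
      out[, nm] <- raw[, nm] & !raw[, parent]
  }
  out[, motifs, drop = FALSE]
}

#' Extract summit-window sequences from a genome
#'
#' @param x A [PeakSet-class].
#' @param genome A [Biostrings::DNAStringSet] named by chromosome.
#' @param window Window width in bp (default 200).
#' @return Named character vector of window sequences (peak ids).
#' @export
summitWindowSequences <- function(x, genome, window = 200) {
  win <- summitWindows(x, window)
  missing <- setdiff(unique(as.character(seqnames(win))), names(genome))
  if (length(missing))
    stop("peaks on chromosomes absent from the genome: ",
         paste(missing, collapse = ", "))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  bad <- end(win) > lens[as.character(seqnames(win))]
  if (any(bad))
    stop("peak window(s) outside the genome sequence: ",
         paste(utils::head(names(win)[bad], 5L), collapse = ", "))
  out <- character(length(win))
  for (chrom in unique(as.character(seqnames(win)))) {
    i <- which(as.character(seqnames(win)) == chrom)
    v <- Biostrings::extractAt(genome[[chrom]],
                               IRanges(start(win)[i], end(win)[i]))
    out[i] <- as.character(v)
  }
  stats::setNames(out, names(win))
}

#' Per-motif prevalence over peak summit windows
#'
#' Extracts the summit windows, evaluates exclusion-aware presence for every
#' registry motif and reports the percent of peaks containing each motif.
#'
#' @inheritParams summitWindowSequences
#' @param registry Motif registry.
#' @param motifs Motif names to report (default: all).
#' @return data.frame with columns `motif`, `count`, `total`, `percent`.
#' @export
motifPrevalence <- function(x, genome, registry = defaultMotifRegistry(),
                            window = 200, motifs = registry$name) {
  .validateRegistry(registry)
  seqs <- summitWindowSequences(x, genome, window)
  pm <- .presenceMatrix(seqs, registry, motifs)
  data.frame(motif = motifs,
             count = colSums(pm),
             total = length(seqs),
             percent = 100 * colMeans(pm),
             row.names = NULL)
}

#' Histogram of motif-center offsets from peak summits
#'
#' Takes hits produced by scanning summit-window sequences (coordinates local
#' to the window, summit at the window center) and bins the signed offsets
#' motif center - summit.
#'
#' @param hits Hit data.frame from [scanMotif()] over window sequences.
#' @param windowWidth Width of the scanned windows (default 200).
#' @param bin Histogram bin width in bp (default 10).
#' @return A list: `histogram` (data.frame lower, upper, count), `mode`
#'   (center of the fullest bin), `meanOffset`.
#' @export
summitOffsetProfile <- function(hits, windowWidth = 200, bin = 10) {
  # window covers [summit - w/2, summit + w/2); the summit base sits at
  # local 1-based position w/2 + 1
  summitPos <- windowWidth / 2 + 1
  off <- hits$center - summitPos
  breaks <- seq(-windowWidth / 2 - bin, windowWidth / 2 + bin, by = bin)
  cut <- findInterval(off, breaks)
  counts <- tabulate(cut, nbins = length(breaks) - 1L)
  hist <- data.frame(lower = breaks[-length(breaks)], upper = breaks[-1L],
                     count = counts)
  modeBin <- which.max(counts)
  list(histogram = hist,
       mode = (hist$lower[modeBin] + hist$upper[modeBin]) / 2,
       meanOffset = mean(off))
}

#' Motif enrichment between two sequence populations
#'
#' Builds the 2x2 presence/absence table of a motif (exclusions applied) in
#' two window-sequence sets and runs a two-sided Fisher's exact test. The
#' odds ratio is the sample OR with the Haldane 0.5 correction applied when
#' any cell is zero.
#'
#' @param seqsA,seqsB Character vectors of window sequences.
#' @param motifName Registry motif to test.
#' @param registry Motif registry.
#' @return A list: `table`, `oddsRatio`, `pValue`, `percentA`, `percentB`.
#' @export
enrichmentBetween <- function(seqsA, seqsB, motifName,
                              registry = defaultMotifRegistry()) {
  if (!length(seqsA) || !length(seqsB))
    stop("both sequence sets must be nonempty")
  pa <- .presenceMatrix(seqsA, registry, motifName)[, 1L]
  pb <- .presenceMatrix(seqsB, registry, motifName)[, 1L]
  tab <- matrix(c(sum(pa), sum(!pa), sum(pb), sum(!pb)), nrow = 2,
                dimnames = list(c("present", "absent"), c("A", "B")))
  p <- stats::fisher.test(tab)$p.value
  cells <- as.numeric(tab)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(table = tab, oddsRatio = or, pValue = p,
       percentA = 100 * mean(pa), percentB = 100 * mean(pb))
}

#' Minimum spacing between two motifs within sequences
#'
#' For every sequence containing at least one hit of each motif (raw hits,
#' both strands), computes the minimum absolute center-to-center distance
#' over all hit pairs. Sequences lacking either motif are excluded and
#' counted.
#'
#' @param sequences Named character vector of sequences.
#' @param motifA,motifB Registry motif names.
#' @param registry Motif registry.
#' @return A list: `perSequence` (named numeric), `mean`, `nWithBoth`,
#'   `nExcluded`.
#' @export
motifSpacing <- function(sequences, motifA, motifB,
                         registry = defaultMotifRegistry()) {
  .validateRegistry(registry)
  consA <- registry$consensus[match(motifA, registry$name)]
  consB <- registry$consensus[match(motifB, registry$name)]
  if (is.na(consA) || is.na(consB)) stop("motif not in registry")
  dist <- vapply(sequences, function(s) {
    ha <- scanMotif(s, consA, motifA)
    hb <- scanMotif(s, consB, motifB)
    if (!nrow(ha) || !nrow(hb)) return(NA_real_)
    min(abs(outer(ha$center, hb$center, "-")))
  }, 0)
  with <- !is.na(dist)
  list(perSequence = dist[with],
       mean = if (any(with)) mean(dist[with]) else NA_real_,
       nWithBoth = sum(with),
       nExcluded = sum(!with))
}

#' Write motif hits as BED6
#'
#' Converts window-local hits to genomic coordinates given the windows they
#' came from, writing 0-based half-open BED with the strand column used and
#' score 0.
#'
#' @param hits Data.frame of hits with a `seqId` column naming the window.
#' @param windows `GRanges` of the scanned windows (named).
#' @param file Output path.
#' @export
writeMotifHitsBed <- function(hits, windows, file) {
  w <- windows[hits$seqId]
  gStart0 <- start(w) - 1L + hits$start - 1L
  df <- data.frame(chrom = as.character(seqnames(w)),
                   start = gStart0,
                   end = gStart0 + (hits$end - hits$start + 1L),
                   name = hits$motif, score = 0L, strand = hits$strand)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
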