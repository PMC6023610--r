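# Peak-to-gene association by TSS windows, differential-expression filtering,
# class-wise expression summaries (Kruskal-Wallis + Dunn) and permutation
# enrichment of gene sets near peaks.

#' Read TSS annotation from BED6
#'
#' One TSS per gene; the interval start (1-based after import) is taken as
#' the TSS position, the `name` column as the gene id.
#'
#' @param file Path to a BED6 file.
#' @return data.frame with columns `geneId`, `chrom`, `tss`, `strand`.
#' @export
readTssBed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  data.frame(geneId = mcols(gr)$name,
             chrom = as.character(seqnames(gr)),
             tss = start(gr),
             strand = as.character(strand(gr)),
             stringsAsFactors = FALSE)
}

#' Associate peaks with genes by TSS distance
#'
#' Links peak p and gene g iff the gene's TSS lies within `window` bp
#' (inclusive) of the peak center on the same chromosome. The peak center is
#' `floor((start0 + end0) / 2)` in 0-based coordinates, per the windowed
#' peak-center convention. Many-to-many links are allowed.
#'
#' @param x A [PeakSet-class].
#' @param genes data.frame as from [readTssBed()].
#' @param window Association window in bp, typically 5000 or 30000.
#' @return A list: `links` (data.frame peakId, geneId, distance),
#'   `genesPerPeak` (named list), `distances` (TSS distance of every link,
#'   for histogramming).
#' @export
associatePeaksToGenes <- function(x, genes, window = 30000) {
  stopifnot(is(x, "PeakSet"))
  gr <- x@peaks
  # 0-based center: floor((start0 + end0)/2) with start0 = start-1, end0 = end
  center <- (start(gr) - 1L + end(gr)) %/% 2L
  chromP <- as.character(seqnames(gr))
  ids <- mcols(gr)$peakId
  links <- list()
  geneByChrom <- split(seq_len(nrow(genes)), genes$chrom)
  for (chrom in intersect(unique(chromP), names(geneByChrom))) {
    gi <- geneByChrom[[chrom]]
    o <- order(genes$tss[gi])
    gi <- gi[o]
    tss0 <- genes$tss[gi] - 1L
    pi <- which(chromP == chrom)
    lo <- findInterval(center[pi] - window - 0.5, tss0) + 1L
    hi <- findInterval(center[pi] + window + 0.5, tss0)
    keep <- which(hi >= lo)
    if (length(keep)) {
      reps <- hi[keep] - lo[keep] + 1L
      pIdx <- rep(pi[keep], reps)
      gIdx <- gi[unlist(lapply(keep, function(k) seq(lo[k], hi[k])))]
      links[[chrom]] <- data.frame(
        peakId = ids[pIdx], geneId = genes$geneId[gIdx],
        distance = abs(center[pIdx] - (genes$tss[gIdx] - 1L)),
        row.names = NULL)
    }
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(peakId = character(), geneId = character(),
               distance = numeric())
  rownames(links) <- NULL
  list(links = links,
       genesPerPeak = split(links$geneId, links$peakId),
       distances = links$distance)
}

#' Filter a differential-expression table
#'
#' A gene passes iff `padj <= maxPadj` and its linear fold-change magnitude
#' is `>= minFC` (both boundaries inclusive). `fold_change` is interpreted as
#' a linear ratio; values below 1 are inverted to a magnitude. Direction is
#' taken from a `direction` column when present, otherwise from whether the
#' ratio exceeds 1.
#'
#' @param de data.frame with columns `gene_id`, `fold_change`, `padj` and
#'   optionally `direction` ("up"/"down").
#' @param maxPadj Adjusted-p cutoff (default 0.01).
#' @param minFC Linear fold-change cutoff (default 1.5).
#' @return A list: `up`, `down` (character vectors of gene ids).
#' @export
deFilter <- function(de, maxPadj = 0.01, minFC = 1.5) {
  if (!nrow(de)) return(list(up = character(), down = character()))
  magnitude <- ifelse(de$fold_change >= 1, de$fold_change,
                      1 / de$fold_change)
  dir <- if ("direction" %in% names(de)) de$direction else
    ifelse(de$fold_change >= 1, "up", "down")
  pass <- de$padj <= maxPadj & magnitude >= minFC
  list(up = de$gene_id[pass & dir == "up"],
       down = de$gene_id[pass & dir == "down"])
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks of the pooled sample with the standard
#' tie correction; two-sided p-values with Bonferroni adjustment over all
#' pairs.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor/vector parallel to `values`.
#' @return data.frame with columns `group1`, `group2`, `z`, `p`, `padj`.
#' @export
pairwiseDunn <- function(values, groups) {
  groups <- as.factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(groups[ok])
  n <- length(values)
  r <- rank(values)
  meanRank <- tapply(r, groups, mean)
  ni <- table(groups)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- apply(pairs, 2, function(p) {
    (meanRank[[p[1]]] - meanRank[[p[2]]]) /
      sqrt((n * (n + 1) / 12 - tieCorr) *
             (1 / ni[[p[1]]] + 1 / ni[[p[2]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             padj = pmin(1, p * ncol(pairs)), row.names = NULL)
}

#' Class-wise expression summary with nonparametric tests
#'
#' For every gene linked to at least one peak of a class, computes either
#' `log2(mean TPM + pseudocount)` across the selected samples ("level") or
#' the log2 ratio of two sample-group means ("foldChange"). Classes are then
#' compared with a global Kruskal-Wallis test and pairwise Dunn tests with
#' Bonferroni correction. A gene linked to peaks of several classes
#' contributes to each. Classes with fewer than 2 genes are excluded from the
#' tests and reported.
#'
#' @param assignment A [ClassAssignment-class] (or named label vector).
#' @param links data.frame `peakId`, `geneId` from [associatePeaksToGenes()].
#' @param expression data.frame with a `gene_id` column and TPM sample
#'   columns.
#' @param samples Sample columns used for "level" (or the numerator of
#'   "foldChange").
#' @param denominatorSamples Sample columns for the denominator when
#'   `statistic = "foldChange"`.
#' @param statistic "level" or "foldChange".
#' @param pseudocount Added to mean TPM before log2 (default 1).
#' @return A list: `values` (data.frame geneId, class, value), `kruskal`
#'   (htest or NULL), `dunn` (data.frame or NULL), `excludedClasses`.
#' @export
classExpressionSummary <- function(assignment, links, expression, samples,
                                   denominatorSamples = NULL,
                                   statistic = c("level", "foldChange"),
                                   pseudocount = 1) {
  statistic <- match.arg(statistic)
  labels <- if (is(assignment, "ClassAssignment")) classLabels(assignment)
            else assignment
  miss <- setdiff(links$peakId, names(labels))
  links <- links[links$peakId %in% names(labels), , drop = FALSE]
  if (length(miss))
    message(length(unique(miss)), " linked peak(s) without a class label ",
            "were ignored")
  expr <- expression[match(links$geneId, expression$gene_id), , drop = FALSE]
  if (anyNA(expr$gene_id))
    stop("linked gene(s) missing from the expression table: ",
         paste(utils::head(unique(links$geneId[is.na(expr$gene_id)]), 5L),
               collapse = ", "))
  num <- rowMeans(as.matrix(expr[, samples, drop = FALSE]))
  value <- if (statistic == "level") {
    log2(num + pseudocount)
  } else {
    if (is.null(denominatorSamples))
      stop("denominatorSamples required for statistic = 'foldChange'")
    den <- rowMeans(as.matrix(expr[, denominatorSamples, drop = FALSE]))
    log2((num + pseudocount) / (den + pseudocount))
  }
  values <- unique(data.frame(geneId = links$geneId,
                              class = labels[links$peakId],
                              value = value, row.names = NULL))
  counts <- table(values$class)
  excluded <- names(counts)[counts < 2]
  testable <- values[!(values$class %in% excluded), , drop = FALSE]
  kruskal <- NULL
  dunn <- NULL
  if (length(unique(testable$class)) >= 2) {
    kruskal <- stats::kruskal.test(testable$value,
                                   as.factor(testable$class))
    dunn <- pairwiseDunn(testable$value, testable$class)
  }
  list(values = values, kruskal = kruskal, dunn = dunn,
       excludedClasses = excluded)
}

#' Permutation enrichment of a gene set near peaks
#'
#' Observed statistic: size of the intersection of `target` with
#' `associated`. Null: overlaps of `nPerm` uniform draws of `|target|` genes
#' from `universe` without replacement. Empirical p-value:
#' `(1 + #(null >= observed)) / (1 + nPerm)`.
#'
#' @param target Gene set of interest (subset of `universe`).
#' @param associated Genes associated with peaks (subset of `universe`).
#' @param universe All genes.
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A list: `observed`, `expected` (null mean), `p`.
#' @export
enrichmentVsRandom <- function(target, associated, universe, nPerm = 1000,
                               seed = 1) {
  target <- unique(target)
  associated <- unique(associated)
  universe <- unique(universe)
  if (length(target) > length(universe))
    stop("target larger than universe")
  if (length(setdiff(target, universe)))
    stop("target contains genes outside the universe")
  if (length(setdiff(associated, universe)))
    stop("associated contains genes outside the universe")
  observed <- length(intersect(target, associated))
  isAssoc <- universe %in% associated
  nullOverlap <- .withSeed(seed, vapply(seq_len(nPerm), function(i)
    sum(isAssoc[sample.int(length(universe), length(target))]), 0L))
  list(observed = observed,
       expected = mean(nullOverlap),
       p = (1 + sum(nullOverlap >= observed)) / (1 + nPerm))
}
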