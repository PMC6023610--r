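# End-to-end orchestration: generate (or ingest) a dataset, filter peaks,
# colocalize/subtract stages, profile motifs, build signal matrices, classify
# chromatin states, associate genes and test expression, quantify qPCR, and
# aggregate everything into a single report bundle.

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes every stage in dependency order and writes, under `outDir`, the
#' generated input data (`data/`), per-stage TSV outputs and a top-level
#' `report.json`. Re-running with the same configuration reproduces
#' byte-identical outputs.
#'
#' @param config A [SyntheticConfig-class]; its seed drives every stochastic
#'   stage.
#' @param outDir Output directory.
#' @param minFE Fold-enrichment cutoff for analysis peaks (default 10).
#' @param colocDist Summit colocalization distance in bp (default 50).
#' @param proximity Proximity threshold for the distance analysis (default
#'   40000).
#' @param geneWindow TSS association window in bp (default 30000).
#' @param dePadj,deFC Differential-expression cutoffs (defaults 0.01, 1.5).
#' @param flank,bin Signal-matrix geometry (defaults 1000, 25).
#' @param k Number of k-means clusters (default 4).
#' @param nPerm Permutations for the gene-set enrichment test (default 1000).
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
runPipeline <- function(config, outDir, minFE = 10, colocDist = 50,
                        proximity = 40000, geneWindow = 30000,
                        dePadj = 0.01, deFC = 1.5, flank = 1000, bin = 25,
                        k = 4, nPerm = 1000) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dataDir <- file.path(outDir, "data")
  message("stage: generate")
  gen <- generateDataset(config, dataDir)
  seqlengths <- gen$seqlengths
  seed <- config@seed

  message("stage: peaks")
  genome <- Biostrings::readDNAStringSet(file.path(dataDir, "genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  early <- readNarrowPeak(file.path(dataDir, "peaks_early.narrowPeak"),
                          seqlengths, label = "early")
  late <- readNarrowPeak(file.path(dataDir, "peaks_late.narrowPeak"),
                         seqlengths, label = "late")
  earlyF <- filterByFoldEnrichment(early, minFE)
  coloc <- colocalize(earlyF, late, colocDist)
  lateOnly <- stageOnly(late, early, colocDist)
  dist <- nearestSummitDistance(lateOnly, earlyF)
  fracWithin <- fractionWithin(dist, proximity)
  .writeTsv(data.frame(peakId = names(dist), distance = unname(dist)),
            file.path(outDir, "late_only_distances.tsv"))

  message("stage: motifs")
  registry <- defaultMotifRegistry()
  core <- c("DECA", "HEXA", "PBXHOX", "NFY")
  prevEarly <- motifPrevalence(earlyF, genome, registry, motifs = core)
  prevLate <- motifPrevalence(lateOnly, genome, registry, motifs = core)
  prev <- rbind(cbind(set = "early", prevEarly),
                cbind(set = "late_only", prevLate))
  .writeTsv(prev, file.path(outDir, "motif_prevalence.tsv"))
  seqsE <- summitWindowSequences(earlyF, genome)
  seqsL <- summitWindowSequences(lateOnly, genome)
  enrDeca <- enrichmentBetween(seqsE, seqsL, "DECA", registry)
  enrHexa <- enrichmentBetween(seqsL, seqsE, "HEXA", registry)
  spacing <- motifSpacing(seqsE, "NFY", "DECA", registry)

  message("stage: signal + classify")
  marks <- c("H3K4me1", "H3K27ac_early", "H3K27ac_late", "H3K27me3")
  tracks <- lapply(marks, function(m)
    readBedGraph(file.path(dataDir, paste0("track_", m, ".bedGraph")),
                 seqlengths))
  names(tracks) <- marks
  mats <- lapply(tracks, computeMatrix, x = earlyF, flank = flank, bin = bin)
  assignment <- classifyChromatin(mats$H3K4me1, mats$H3K27ac_early,
                                  mats$H3K27me3, k = k, seed = seed)
  writeClassAssignment(assignment, file.path(outDir, "class_assignment.tsv"))
  labels <- classLabels(assignment)
  classCounts <- as.list(table(labels))
  mpadIds <- names(labels)[labels != "nonMPAD"]
  acChange <- log2Change(
    new("SignalMatrix",
        values = matrixValues(mats$H3K27ac_late)[mpadIds, , drop = FALSE],
        flank = as.integer(flank), bin = as.integer(bin),
        clipped = logical(length(mpadIds))),
    new("SignalMatrix",
        values = matrixValues(mats$H3K27ac_early)[mpadIds, , drop = FALSE],
        flank = as.integer(flank), bin = as.integer(bin),
        clipped = logical(length(mpadIds))))
  classChange <- tapply(acChange$rowMeanChange, labels[mpadIds], mean)

  message("stage: genes")
  genes <- readTssBed(file.path(dataDir, "tss.bed"))
  assoc <- associatePeaksToGenes(earlyF, genes, geneWindow)
  .writeTsv(assoc$links, file.path(outDir, "peak_gene_links.tsv"))
  tpm <- utils::read.delim(file.path(dataDir, "tpm.tsv"))
  exprSummary <- classExpressionSummary(
    assignment, assoc$links, tpm,
    samples = c("ctrl_1", "ctrl_2", "ctrl_3"))
  kdSummary <- classExpressionSummary(
    assignment, assoc$links, tpm,
    samples = c("kd_1", "kd_2", "kd_3"),
    denominatorSamples = c("ctrl_1", "ctrl_2", "ctrl_3"),
    statistic = "foldChange")
  de <- utils::read.delim(file.path(dataDir, "de.tsv"))
  deSets <- deFilter(de, dePadj, deFC)
  class4Peaks <- names(labels)[labels == "Class4"]
  class4Genes <- unique(
    assoc$links$geneId[assoc$links$peakId %in% class4Peaks])
  enrich <- enrichmentVsRandom(deSets$down, class4Genes, genes$geneId,
                               nPerm = nPerm, seed = seed)

  message("stage: qpcr")
  ctExpr <- readCtTable(file.path(dataDir, "ct_expression.tsv"))
  qpcrExpr <- summarizeCtTable(ctExpr, experimental = "kd",
                               control = "control")
  .writeTsv(qpcrExpr, file.path(outDir, "qpcr_expression.tsv"))
  ctChip <- readCtTable(file.path(dataDir, "ct_chip.tsv"))
  ctChip$ratio <- chipEnrichment(ctChip$ct, ctChip$reference_ct)
  qpcrChip <- do.call(rbind, lapply(split(ctChip, ctChip$target),
                                    function(d) {
    fc <- foldChangeWithTest(d$ratio[d$condition == "specific"],
                             d$ratio[d$condition == "IgG"])
    data.frame(target = d$target[1L], foldChange = fc$foldChange,
               sem = fc$sem, p = fc$p, significant = fc$significant)
  }))
  rownames(qpcrChip) <- NULL
  .writeTsv(qpcrChip, file.path(outDir, "qpcr_chip.tsv"))

  report <- list(
    parameters = list(seed = seed, minFE = minFE, colocDist = colocDist,
                      proximity = proximity, geneWindow = geneWindow,
                      dePadj = dePadj, deFC = deFC, flank = flank,
                      bin = bin, k = k, nPerm = nPerm),
    peaks = list(
      nEarlyUnfiltered = length(early), nEarlyFiltered = length(earlyF),
      nLate = length(late), nLateOnly = length(lateOnly),
      percentEarlyColocalized = coloc$percentA,
      percentLateOnlyWithinProximity = fracWithin),
    motifs = list(
      prevalence = prev,
      decaEnrichmentEarlyVsLateOnly = list(oddsRatio = enrDeca$oddsRatio,
                                           p = enrDeca$pValue),
      hexaEnrichmentLateOnlyVsEarly = list(oddsRatio = enrHexa$oddsRatio,
                                           p = enrHexa$pValue),
      nfyDecaMeanSpacing = spacing$mean,
      nfyDecaSequencesWithBoth = spacing$nWithBoth),
    classes = list(
      counts = classCounts,
      percentMpad = 100 * mean(labels != "nonMPAD"),
      meanH3K27acLog2Change = as.list(classChange)),
    expression = list(
      kruskalP = if (!is.null(exprSummary$kruskal))
        exprSummary$kruskal$p.value else NA,
      kdKruskalP = if (!is.null(kdSummary$kruskal))
        kdSummary$kruskal$p.value else NA,
      nDeUp = length(deSets$up), nDeDown = length(deSets$down),
      class4Enrichment = enrich),
    qpcr = list(expression = qpcrExpr, chip = qpcrChip))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
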