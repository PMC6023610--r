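# Delta-Ct qPCR quantification: relative expression against a reference gene,
# ChIP DNA enrichment against input, replicate aggregation and the unpaired
# t-test decision rule.

#' Relative expression from Ct values
#'
#' `0.5^ctGene / 0.5^ctRef`, i.e. `2^(ctRef - ctGene)`: one cycle less on the
#' gene of interest doubles the estimate. Vectorized.
#'
#' @param ctGene Ct of the gene of interest.
#' @param ctRef Ct of the reference gene (e.g. gapdh).
#' @return Linear expression ratio(s).
#' @export
relativeExpression <- function(ctGene, ctRef) {
  0.5^ctGene / 0.5^ctRef
}

#' ChIP DNA enrichment from Ct values
#'
#' `0.5^ctIp / 0.5^ctInput`: the immunoprecipitated signal normalized to the
#' matched input chromatin.
#'
#' @param ctIp Ct of the IP sample.
#' @param ctInput Ct of the input sample.
#' @return Linear enrichment ratio(s).
#' @export
chipEnrichment <- function(ctIp, ctInput) {
  0.5^ctIp / 0.5^ctInput
}

#' Fold change between replicate groups with an unpaired t-test
#'
#' Computes per-replicate experimental/control ratios (replicates matched by
#' position), their mean and SEM (sample sd / sqrt(n)), and a two-sided
#' unpaired Student t-test (equal variance) comparing the two groups.
#' Significance is declared at `p <= alpha`.
#'
#' @param experimental,control Numeric replicate values (>= 2 each, equal
#'   length).
#' @param alpha Significance level (default 0.05).
#' @return A list: `foldChange`, `sem`, `t`, `p`, `significant`, `variant`
#'   ("student" to record the equal-variance choice).
#' @export
foldChangeWithTest <- function(experimental, control, alpha = 0.05) {
  if (length(experimental) < 2 || length(control) < 2)
    stop("at least 2 replicates per group are required")
  if (length(experimental) != length(control))
    stop("replicate groups must have equal length for matched ratios")
  ratios <- experimental / control
  tt <- tryCatch(stats::t.test(experimental, control, var.equal = TRUE),
                 error = function(e) NULL)
  if (is.null(tt)) {
    # both groups constant: the test degenerates to comparing the means
    d <- mean(experimental) - mean(control)
    tt <- if (d == 0) list(statistic = c(t = 0), p.value = 1)
          else list(statistic = c(t = sign(d) * Inf), p.value = 0)
  }
  list(foldChange = mean(ratios),
       sem = stats::sd(ratios) / sqrt(length(ratios)),
       t = unname(tt$statistic),
       p = tt$p.value,
       significant = tt$p.value <= alpha,
       variant = "student")
}

#' Read a Ct table
#'
#' TSV with header; expected columns include `target`, `condition`,
#' `replicate`, `ct` and `reference_ct`.
#'
#' @param file Path to a TSV file.
#' @return data.frame.
#' @export
readCtTable <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' Summarize a Ct table into per-target fold changes
#'
#' Converts each row to a linear ratio with [relativeExpression()] (gene vs
#' reference Ct), then, for every target, compares the `experimental`
#' condition to the `control` condition with [foldChangeWithTest()].
#'
#' @param ct data.frame as from [readCtTable()].
#' @param experimental,control Condition tags to compare.
#' @param alpha Significance level.
#' @return data.frame with one row per target: `target`, `foldChange`,
#'   `sem`, `t`, `p`, `significant`.
#' @export
summarizeCtTable <- function(ct, experimental, control, alpha = 0.05) {
  ct$ratio <- relativeExpression(ct$ct, ct$reference_ct)
  out <- lapply(split(ct, ct$target), function(d) {
    e <- d$ratio[d$condition == experimental][order(
      d$replicate[d$condition == experimental])]
    c0 <- d$ratio[d$condition == control][order(
      d$replicate[d$condition == control])]
    fc <- foldChangeWithTest(e, c0, alpha = alpha)
    data.frame(target = d$target[1L], foldChange = fc$foldChange,
               sem = fc$sem, t = fc$t, p = fc$p,
               significant = fc$significant)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
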