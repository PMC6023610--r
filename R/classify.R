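# Two-level chromatin-state classification of peaks: k-means on the H3K4me1
# signal matrix separates MPADs (modified, histone-marked sites) from
# non-MPADs; a second k-means on the joint H3K27ac/H3K27me3 matrix orders
# MPADs into Class 1 (highest H3K27ac) through Class 4 (lowest H3K27ac,
# high H3K27me3).

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
.kmeansppCenters <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      # all points coincide with a center; fall back to distinct rows
      cand <- which(!duplicated(x))
      i <- cand[sample.int(length(cand), 1L)]
    } else {
      i <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

#' K-means clustering of signal-matrix rows
#'
#' Lloyd's algorithm with k-means++ seeding on the raw (unscaled) bin values,
#' Euclidean distance, best of `restarts` runs by total within-cluster sum of
#' squares. Deterministic given `seed`.
#'
#' @param x A [SignalMatrix-class] or a plain numeric matrix with rownames.
#' @param k Number of clusters (default 4).
#' @param seed Integer seed.
#' @param restarts Number of independent restarts (default 10).
#' @return A list: `cluster` (named integer per row), `centers`,
#'   `totWithinss`.
#' @export
kmeansRows <- function(x, k = 4, seed = 1, restarts = 10) {
  v <- if (is(x, "SignalMatrix")) x@values else x
  stopifnot(is.matrix(v), !is.null(rownames(v)))
  if (nrow(v) < k) stop("fewer rows (", nrow(v), ") than clusters (", k, ")")
  if (nrow(unique(v)) < k)
    stop("fewer distinct rows than clusters")
  .withSeed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      km <- NULL
      for (attempt in 1:5) {
        centers <- .kmeansppCenters(v, k)
        km <- tryCatch(
          suppressWarnings(stats::kmeans(v, centers = centers,
                                         iter.max = 100L,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(km)) break
      }
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("k-means failed on every restart")
    list(cluster = stats::setNames(as.integer(best$cluster), rownames(v)),
         centers = best$centers,
         totWithinss = best$tot.withinss)
  })
}

#' MPAD vs non-MPAD assignment from an H3K4me1 signal matrix
#'
#' Clusters rows with [kmeansRows()] and ranks the clusters by mean row
#' signal. Clusters whose mean falls below `lowFraction` times the top
#' cluster's mean are non-MPAD; if none does, the single lowest-mean cluster
#' is non-MPAD (so the "marked clusters + one unmarked cluster" topology is
#' reproduced on any input). An all-zero matrix yields all non-MPAD.
#'
#' @param x H3K4me1 [SignalMatrix-class] (or matrix with rownames).
#' @param k Number of clusters (default 4).
#' @param seed Integer seed.
#' @param restarts K-means restarts (default 10).
#' @param lowFraction Cutoff relative to the top cluster mean (default 0.25).
#' @return A [ClassAssignment-class] with labels "MPAD"/"nonMPAD".
#' @export
assignMpad <- function(x, k = 4, seed = 1, restarts = 10,
                       lowFraction = 0.25) {
  v <- if (is(x, "SignalMatrix")) x@values else x
  params <- list(step = "mpad", k = k, seed = seed, restarts = restarts,
                 lowFraction = lowFraction)
  if (all(v == 0)) {
    return(new("ClassAssignment",
               labels = stats::setNames(rep("nonMPAD", nrow(v)), rownames(v)),
               cluster = stats::setNames(rep(0L, nrow(v)), rownames(v)),
               clusterMeans = matrix(0, 1, 1,
                                     dimnames = list("0", "meanSignal")),
               params = params))
  }
  km <- kmeansRows(v, k = k, seed = seed, restarts = restarts)
  rowMean <- rowMeans(v)
  clMean <- vapply(seq_len(k), function(j) mean(rowMean[km$cluster == j]), 0)
  top <- max(clMean)
  low <- if (top <= 0) seq_len(k) else which(clMean < lowFraction * top)
  if (!length(low)) low <- which.min(clMean)
  labels <- ifelse(km$cluster %in% low, "nonMPAD", "MPAD")
  new("ClassAssignment",
      labels = stats::setNames(labels, names(km$cluster)),
      cluster = km$cluster,
      clusterMeans = matrix(clMean, ncol = 1,
                            dimnames = list(seq_len(k), "meanSignal")),
      params = params)
}

#' Class 1-4 assignment of MPADs from H3K27ac and H3K27me3
#'
#' Clusters the column-concatenated `[H3K27ac | H3K27me3]` matrix (rows
#' restricted to MPAD peaks, identical row order in both inputs) and labels
#' the clusters by mean H3K27ac descending: Class1 has the highest H3K27ac;
#' ties are broken by mean H3K27me3 ascending, so higher H3K27me3 pushes a
#' cluster toward Class 4.
#'
#' @param h3k27ac,h3k27me3 [SignalMatrix-class] objects over the same MPAD
#'   peaks in the same row order.
#' @param k Number of classes (default 4).
#' @param seed Integer seed.
#' @param restarts K-means restarts (default 10).
#' @return A [ClassAssignment-class] with labels "Class1".."Class<k>".
#' @export
assignClasses <- function(h3k27ac, h3k27me3, k = 4, seed = 1, restarts = 10) {
  va <- if (is(h3k27ac, "SignalMatrix")) h3k27ac@values else h3k27ac
  vm <- if (is(h3k27me3, "SignalMatrix")) h3k27me3@values else h3k27me3
  if (!identical(rownames(va), rownames(vm)))
    stop("H3K27ac and H3K27me3 matrices differ in row order")
  joint <- cbind(va, vm)
  km <- kmeansRows(joint, k = k, seed = seed, restarts = restarts)
  acMean <- vapply(seq_len(k), function(j)
    mean(rowMeans(va)[km$cluster == j]), 0)
  me3Mean <- vapply(seq_len(k), function(j)
    mean(rowMeans(vm)[km$cluster == j]), 0)
  rank <- order(-acMean, me3Mean)
  classOf <- integer(k)
  classOf[rank] <- seq_len(k)
  labels <- paste0("Class", classOf[km$cluster])
  new("ClassAssignment",
      labels = stats::setNames(labels, names(km$cluster)),
      cluster = km$cluster,
      clusterMeans = cbind(meanH3K27ac = acMean, meanH3K27me3 = me3Mean),
      params = list(step = "classes", k = k, seed = seed,
                    restarts = restarts))
}

#' Full two-level chromatin classification
#'
#' Runs [assignMpad()] on the H3K4me1 matrix, then [assignClasses()] on the
#' H3K27ac/H3K27me3 matrices restricted to the MPAD peaks, and merges the
#' labels: every peak ends up "nonMPAD" or "Class1".."Class4".
#'
#' @param h3k4me1,h3k27ac,h3k27me3 [SignalMatrix-class] objects over the same
#'   peaks in the same row order.
#' @inheritParams assignClasses
#' @param lowFraction Passed to [assignMpad()].
#' @return A [ClassAssignment-class].
#' @export
classifyChromatin <- function(h3k4me1, h3k27ac, h3k27me3, k = 4, seed = 1,
                              restarts = 10, lowFraction = 0.25) {
  mp <- assignMpad(h3k4me1, k = k, seed = seed, restarts = restarts,
                   lowFraction = lowFraction)
  labels <- classLabels(mp)
  mpadIds <- names(labels)[labels == "MPAD"]
  cluster <- mp@cluster
  if (length(mpadIds) >= k) {
    sub <- function(m) {
      v <- if (is(m, "SignalMatrix")) m@values else m
      v[mpadIds, , drop = FALSE]
    }
    cls <- assignClasses(sub(h3k27ac), sub(h3k27me3), k = k,
                         seed = seed + 1L, restarts = restarts)
    labels[mpadIds] <- classLabels(cls)
  } else if (length(mpadIds)) {
    labels[mpadIds] <- "Class1"
  }
  new("ClassAssignment", labels = labels, cluster = cluster,
      clusterMeans = mp@clusterMeans,
      params = list(step = "full", k = k, seed = seed, restarts = restarts,
                    lowFraction = lowFraction))
}

#' @describeIn classifyChromatin Accessor: named label vector.
#' @param x A [ClassAssignment-class].
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname classifyChromatin
#' @export
setMethod("classLabels", "ClassAssignment", function(x) x@labels)

setMethod("show", "ClassAssignment", function(object) {
  tab <- table(object@labels)
  cat("ClassAssignment for ", length(object@labels), " peaks:\n", sep = "")
  for (nm in names(tab))
    cat("  ", nm, ": ", tab[[nm]], " (",
        sprintf("%.1f", 100 * tab[[nm]] / length(object@labels)), "%)\n",
        sep = "")
})

#' Write a ClassAssignment as TSV (+ JSON parameter sidecar)
#'
#' @param x A [ClassAssignment-class].
#' @param file TSV path.
#' @export
writeClassAssignment <- function(x, file) {
  df <- data.frame(peakId = names(x@labels), label = unname(x@labels),
                   cluster = unname(x@cluster))
  .writeTsv(df, file)
  jsonlite::write_json(x@params, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}
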