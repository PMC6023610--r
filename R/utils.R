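# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# IUPAC nucleotide codes -> the set of concrete bases each code stands for.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T"))

# Regex character class per code. An N in the subject sequence (assembly gap)
# is matched only by the motif code N; every other code matches concrete
# bases exclusively.
.iupacRegex <- function(consensus) {
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  bad <- setdiff(chars, names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC code in consensus: ", paste(unique(bad), collapse = ", "))
  cls <- vapply(chars, function(ch) {
    opts <- .IUPAC[[ch]]
    if (ch == "N") opts <- c(opts, "N")
    if (length(opts) == 1L) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, "")
  paste(cls, collapse = "")
}

.revcompConsensus <- function(consensus) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
}

# All (overlapping) 1-based start positions of an IUPAC consensus on the
# forward strand of `sequence`.
.regexStarts <- function(sequence, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), sequence, perl = TRUE)[[1L]]
  if (length(m) == 1L && m[1L] == -1L) integer() else as.integer(m)
}

.checkSameGenome <- function(a, b) {
  sa <- seqlengths(a@peaks)
  sb <- seqlengths(b@peaks)
  common <- intersect(names(sa), names(sb))
  if (!identical(sa[common], sb[common]) ||
      (!length(common) && length(sa) && length(sb)))
    stop("peak sets are on different genomes (seqlengths disagree)")
  invisible(TRUE)
}

.writeTsv <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
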