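## Low-level sequence helpers shared across modules.
## All genomic coordinates inside the package are 0-based half-open on the
## forward strand; GenBank I/O converts to/from 1-based inclusive.

#' Reverse complement of a nucleotide string
#'
#' Accepts the 4-letter alphabet plus `N`.
#'
#' @param s character scalar (A/C/G/T/N).
#' @return character scalar.
#' @export
revcomp <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## substring extraction with 0-based half-open coordinates
seq_slice <- function(s, start0, end0) {
  substr(s, start0 + 1L, end0)
}

## random nucleotide sequence with a target AT fraction (GC split evenly,
## AT split evenly, so expected GC skew ~ 0)
random_seq <- function(n, at = 0.71) {
  if (n <= 0L) return("")
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

## substitute a fraction of positions with a different random base;
## `protect` = 1-based positions never touched
mutate_seq <- function(s, rate, protect = integer(0)) {
  n <- nchar(s)
  if (n == 0L || rate <= 0) return(s)
  k <- rpois(1L, rate * n)
  if (k == 0L) return(s)
  pos <- sample.int(n, min(k, n))
  pos <- setdiff(pos, protect)
  if (length(pos) == 0L) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  alt <- c(A = "GCT", C = "AGT", G = "ACT", T = "ACG")
  ch[pos] <- vapply(ch[pos], function(b) {
    a <- alt[[b]]
    substr(a, i <- sample.int(3L, 1L), i)
  }, character(1))
  paste(ch, collapse = "")
}

## Global pairwise alignment of two nucleotide strings.
## Returns list(pattern=, subject=, matches=, alen=, identity=) where
## identity = matches / alignment length (gap columns included).
align_global <- function(a, b, gap_open = 12, gap_ext = 0.5) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext)
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- sum(pc == sc & pc != "-")
  list(pattern = p, subject = s, matches = m, alen = nchar(p),
       identity = m / nchar(p))
}

#' Global alignment identity between two sequences
#'
#' Identity is the number of identical aligned bases divided by the
#' alignment length (gap columns count against identity).
#'
#' @param a,b nucleotide strings.
#' @return fraction in \[0, 1\].
#' @export
align_identity <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 12, gapExtension = 0.5)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

## deterministic integer hash of a string (for per-leaf RNG streams)
str_seed <- function(s, base) {
  (base + sum(utf8ToInt(s) * seq_along(utf8ToInt(s)))) %% .Machine$integer.max
}
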