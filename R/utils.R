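#' @importFrom stats rbinom rgeom rnorm runif setNames dnorm median
#' @importFrom utils read.table write.table head tail
#' @importFrom methods is
NULL

# CIGAR helpers -----------------------------------------------------------

# reference-space width of each CIGAR string
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

# soft-clip lengths on each side; returns matrix with columns left, right
cigar_clips <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  left <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]
    if (length(o) && o[1] == "S") lens[[i]][1] else 0L
  }, integer(1))
  right <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]
    n <- length(o)
    if (n && o[n] == "S") lens[[i]][n] else 0L
  }, integer(1))
  cbind(left = left, right = right)
}

# mean phred quality of a substring of a quality string (offset 33)
mean_qual <- function(qual, from, to) {
  s <- substr(qual, from, to)
  if (!nzchar(s)) return(0)
  mean(as.integer(charToRaw(s))) - 33
}

phred_cap <- function(p, cap = 99L) {
  # phred-scale 'p' (an error probability), capped
  q <- -10 * log10(pmax(p, 10^(-(cap / 10))))
  as.integer(pmin(round(q), cap))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# deterministic random DNA of length n
random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# mutate a DNA string: substitutions at rate 'div', giving a diverged copy
mutate_dna <- function(seq, div) {
  if (div <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1, n, div)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(bases, cur), 1)
  }
  seq
}

`%||%` <- function(a, b) if (is.null(a)) b else a
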