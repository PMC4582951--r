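# Genotype likelihood engine ----------------------------------------------
#
# Shared by the deletion and insertion paths. Alleles: H0 carries the Alu
# (present in the working coordinate frame), H1 lacks it. Genotypes: G0 =
# homozygote H0, G1 = heterozygote, G2 = homozygote H1. Evidence classes:
#   I  - junction evidence for H0 (one mate inside the element)
#   S  - junction evidence for H1 (a read split across both breakpoints)
#   A  - a pair spanning the element; its insert length discriminates.

#' Probability of the Alu-carrying allele given a genotype
#'
#' Under uniform coverage the chance that a fragment at the locus originates
#' from the Alu-carrying haplotype of a heterozygote is proportional to the
#' informative length of that haplotype:
#' \deqn{P(H_0 | G_1) = (2 r + l_{Alu}) / (4 r + l_{Alu})}
#' where r is the read length. Homozygotes give probability 1 (G0) or 0 (G2).
#'
#' @param g genotype, one of 0, 1, 2 (or "G0", "G1", "G2").
#' @param read_len read length r in bp.
#' @param l_alu Alu element length in bp.
#' @return probability of allele H0.
#' @export
allele_given_genotype <- function(g, read_len, l_alu) {
  stopifnot(read_len > 0, l_alu >= 0)
  g <- as.integer(sub("^G", "", as.character(g)))
  if (is.na(g) || !(g %in% 0:2)) stop("invalid genotype label")
  switch(g + 1L,
         1,
         (2 * read_len + l_alu) / (4 * read_len + l_alu),
         0)
}

#' Per-pair allele likelihoods
#'
#' Relative likelihoods of one classified read pair under each allele.
#' Junction pairs are fixed at 1 for the allele they support and at the
#' error probability \code{pe} for the other. Spanning (type A) pairs use the
#' empirical insert-length density: \eqn{f_Y(Y)} under H0 and
#' \eqn{f_Y(Y - l_{Alu})} under H1 (the H1 insert follows Y + l_Alu).
#'
#' @param type vector in {"I","S","A"}.
#' @param y observed insert length (used for type A).
#' @param model an \code{insert_model}.
#' @param l_alu element length in bp.
#' @param library per-pair library names (type-A density lookup).
#' @param pe error probability for junction pairs supporting the wrong
#'   allele (default 0.001).
#' @return matrix with columns \code{L0}, \code{L1}.
#' @export
pair_allele_likelihoods <- function(type, y = NA_real_, model = NULL,
                                    l_alu = 300L, library = "default",
                                    pe = 0.001) {
  n <- length(type)
  y <- rep_len(y, n)
  library <- rep_len(library, n)
  L0 <- L1 <- rep(NA_real_, n)
  for (lb in unique(library)) {
    i <- which(library == lb & type == "A")
    if (length(i)) {
      L0[i] <- insert_density(model, y[i], lb)
      L1[i] <- insert_density(model, y[i] - l_alu, lb)
    }
  }
  i <- type == "I"
  L0[i] <- 1; L1[i] <- pe
  s <- type == "S"
  L0[s] <- pe; L1[s] <- 1
  if (anyNA(L0)) stop("unknown pair type; expected I, S or A")
  cbind(L0 = L0, L1 = L1)
}

#' Joint genotype log-likelihoods for a classified read set
#'
#' The relative likelihood of the read set R given genotype g is the product
#' over pairs of the allele mixture
#' \deqn{L(R|G_g) = \prod_r [ L(r|H_0) P(H_0|G_g) + L(r|H_1) (1 - P(H_0|G_g)) ]}
#' computed as a sum of per-pair log terms. An empty read set gives (0,0,0).
#'
#' @param lik matrix from [pair_allele_likelihoods()] (columns L0, L1).
#' @param read_len read length r for the heterozygote allele balance.
#' @param l_alu element length in bp.
#' @return named numeric vector \code{c(G0=, G1=, G2=)} of log-likelihoods.
#' @export
genotype_likelihoods <- function(lik, read_len = 100L, l_alu = 300L) {
  if (is.null(lik) || nrow(lik) == 0) return(c(G0 = 0, G1 = 0, G2 = 0))
  p <- vapply(0:2, allele_given_genotype, numeric(1),
              read_len = read_len, l_alu = l_alu)
  out <- vapply(p, function(ph0) {
    sum(log(lik[, "L0"] * ph0 + lik[, "L1"] * (1 - ph0)))
  }, numeric(1))
  names(out) <- c("G0", "G1", "G2")
  out
}

#' Call a genotype from log-likelihoods
#'
#' Picks the maximum-likelihood genotype and attaches a phred-scaled quality
#' from the normalized posterior under a uniform prior. Returns a no-call
#' when the evidence count is below \code{min_evidence} or all three
#' log-likelihoods are equal; exact ties are broken toward the
#' reference-supporting genotype G0.
#'
#' @param logls numeric vector of log-likelihoods (G0, G1, G2).
#' @param n_evidence number of classified pairs backing the call.
#' @param min_evidence minimum evidence for a call (default 2).
#' @return list with \code{genotype} (0, 1, 2 or NA), \code{gq}, \code{pl}
#'   (phred-scaled likelihoods, minimum 0) and \code{posterior}.
#' @export
call_genotype <- function(logls, n_evidence, min_evidence = 2L) {
  logls <- as.numeric(logls)
  pl <- as.integer(pmin(round(-10 * (logls - max(logls)) / log(10)), 9999L))
  if (n_evidence < min_evidence || diff(range(logls)) == 0) {
    return(list(genotype = NA_integer_, gq = 0L, pl = pl,
                posterior = rep(1 / 3, 3)))
  }
  post <- exp(logls - max(logls))
  post <- post / sum(post)
  g <- which(logls == max(logls))[1] - 1L  # ties toward G0
  gq <- phred_cap(1 - post[g + 1L])
  list(genotype = g, gq = gq, pl = pl, posterior = post)
}
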