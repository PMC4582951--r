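# Alu consensus panel ------------------------------------------------------

#' Generate a synthetic Alu consensus panel
#'
#' Builds a small panel of Alu-like consensus sequences: dimeric ~280 bp
#' bodies derived from a common ancestral core (mirroring the shared origin of
#' Alu subfamilies), an A-rich linker, and a poly-A tail. The panel is a
#' synthetic stand-in for a curated set of Alu subfamily consensus sequences;
#' it reproduces the structural features the caller relies on (a shared,
#' alignable body of roughly 300 bp) but not the true subfamily phylogeny.
#'
#' @param n_families number of consensus sequences to generate.
#' @param seed integer seed; the default reproduces the shipped fixture panel.
#' @param body_len length in bp of the Alu body before the poly-A tail.
#' @param family_divergence per-base substitution rate applied to the shared
#'   core to differentiate families (real Alu subfamilies differ by a few
#'   percent).
#' @return a [Biostrings::DNAStringSet] named \code{AluSyn1..n}.
#' @export
synthetic_alu_panel <- function(n_families = 8, seed = 7, body_len = 281,
                                family_divergence = 0.06) {
  stopifnot(n_families >= 1, body_len > 60)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  half <- body_len %/% 2
  core_left <- random_dna(half, gc = 0.55)
  linker <- paste(rep("A", 12), collapse = "")
  core_right <- random_dna(body_len - half - 12, gc = 0.55)
  core <- paste0(core_left, linker, core_right)
  seqs <- vapply(seq_len(n_families), function(i) {
    body <- mutate_dna(core, family_divergence)
    tail_len <- sample(14:28, 1)
    paste0(body, strrep("A", tail_len))
  }, character(1))
  names(seqs) <- paste0("AluSyn", seq_len(n_families))
  Biostrings::DNAStringSet(seqs)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Load an Alu consensus panel from FASTA
#'
#' @param path FASTA file of consensus sequences; defaults to the synthetic
#'   panel shipped with the package.
#' @return a [Biostrings::DNAStringSet].
#' @export
load_alu_panel <- function(path = system.file("extdata", "alu_panel_synthetic.fa",
                                              package = "aluscan")) {
  if (!file.exists(path)) stop("Alu panel FASTA not found: ", path)
  panel <- Biostrings::readDNAStringSet(path)
  if (length(panel) < 1) stop("Alu panel is empty: ", path)
  panel
}
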