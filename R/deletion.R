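# Alu deletion caller ------------------------------------------------------
#
# For every annotated reference Alu, nearby read pairs are classified into
# three evidence classes and fed to the genotype likelihood engine:
#   I  - one mate maps inside the element (supports Alu presence, H0)
#   S  - a soft-clipped read realigns across the element (supports H1)
#   A  - mates in the two flanks; the insert length discriminates.

.sw_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = FALSE)
}

# Batched split realignment of clipped reads across an Alu.
# cand: data.frame(seq, side ("R" = clip on the right of the read, at AL;
#       "L" = clip on the left, at AR), clip_len, mapped_len, clip_pos)
# Returns cand with columns accepted, score, aligned.
realign_clips_batch <- function(cand, window, ref_chrom_seq,
                                min_score = 25, min_flank = 20, pad = 8L) {
  cand$accepted <- FALSE
  cand$score <- NA_real_
  cand$aligned <- NA_integer_
  if (nrow(cand) == 0) return(cand)
  submat <- .sw_submat()
  chrom_len <- length(ref_chrom_seq)
  for (side in c("R", "L")) {
    idx <- which(cand$side == side & cand$mapped_len >= min_flank &
                   cand$clip_len >= min_flank)
    if (!length(idx)) next
    maxc <- max(cand$clip_len[idx])
    if (side == "R") {
      # clipped tail should continue from AR rightwards
      s1 <- window$AR + 1L
      s2 <- min(chrom_len, window$AR + maxc + pad)
      clips <- substr(cand$seq[idx], nchar(cand$seq[idx]) - cand$clip_len[idx] + 1L,
                      nchar(cand$seq[idx]))
    } else {
      # clipped head should end at AL
      s1 <- max(1L, window$AL - maxc - pad + 1L)
      s2 <- window$AL
      clips <- substr(cand$seq[idx], 1L, cand$clip_len[idx])
    }
    if (s2 <= s1) next
    subject <- Biostrings::subseq(ref_chrom_seq, s1, s2)
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(clips),
                                         subject, type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = 3, gapExtension = 1)
    sc <- Biostrings::score(aln)
    prng <- Biostrings::pattern(aln)
    srng <- Biostrings::subject(aln)
    pstart <- Biostrings::start(prng); pend <- Biostrings::end(prng)
    sstart <- Biostrings::start(srng); send <- Biostrings::end(srng)
    alen <- pend - pstart + 1L
    if (side == "R") {
      anchored <- pstart <= 5L & sstart <= 5L
    } else {
      anchored <- (cand$clip_len[idx] - pend) <= 5L &
        ((s2 - s1 + 1L) - send) <= 5L
    }
    ok <- sc >= min_score & alen >= min_flank & anchored
    cand$accepted[idx] <- ok
    cand$score[idx] <- sc
    cand$aligned[idx] <- alen
  }
  cand
}

#' Split-realign a clipped read across an Alu element
#'
#' Takes a read with a soft-clipped segment whose aligned part ends near one
#' breakpoint, and realigns the clipped part locally (Smith-Waterman; match
#' +1, mismatch -2, gap open -3, gap extend -1) on the far side of the
#' element. The split is accepted when at least \code{min_flank} bp align on
#' each side of the Alu and the realignment score reaches \code{min_score}.
#'
#' @param read list or one-row data.frame with \code{seq}, \code{cigar} and
#'   \code{pos0} (0-based leftmost aligned position).
#' @param window an analysis window from [build_window()].
#' @param reference a [Biostrings::DNAString] (the window's chromosome) or a
#'   named [Biostrings::DNAStringSet].
#' @param min_score minimum local alignment score of the clipped part.
#' @param min_flank minimum aligned bp on each side of the element.
#' @param pos_tol maximum distance (bp) between the clip position and the
#'   breakpoint it is tested against.
#' @return a list with \code{clip_pos}, \code{side}, \code{score},
#'   \code{aligned} for an accepted split, else \code{NULL}.
#' @export
split_realign <- function(read, window, reference, min_score = 25,
                          min_flank = 20, pos_tol = 10L) {
  ref_chrom_seq <- if (is(reference, "DNAStringSet"))
    reference[[window$chrom]] else reference
  clips <- cigar_clips(read$cigar)
  end0 <- read$pos0 + cigar_ref_width(read$cigar)
  mapped_len <- nchar(read$seq) - clips[1, "left"] - clips[1, "right"]
  cand <- data.frame(seq = read$seq, side = NA_character_,
                     clip_len = 0L, mapped_len = mapped_len,
                     clip_pos = NA_integer_, stringsAsFactors = FALSE)
  if (clips[1, "right"] > 0 && abs(end0 - window$AL) <= pos_tol) {
    cand$side <- "R"; cand$clip_len <- clips[1, "right"]; cand$clip_pos <- end0
  } else if (clips[1, "left"] > 0 && abs(read$pos0 - window$AR) <= pos_tol) {
    cand$side <- "L"; cand$clip_len <- clips[1, "left"]; cand$clip_pos <- read$pos0
  } else {
    return(NULL)
  }
  res <- realign_clips_batch(cand, window, ref_chrom_seq,
                             min_score = min_score, min_flank = min_flank)
  if (!res$accepted[1]) return(NULL)
  list(clip_pos = res$clip_pos[1], side = res$side[1],
       score = res$score[1], aligned = res$aligned[1])
}

# Pair up the reads fetched for one window. Returns list(pairs=, singles=)
# where pairs is a data.frame of properly oriented (+/-) two-mate rows.
window_pair_table <- function(reads) {
  if (nrow(reads) == 0)
    return(list(pairs = NULL, singles = reads))
  cnt <- table(reads$qname)
  dup <- names(cnt)[cnt == 2L]
  singles <- reads[!(reads$qname %in% dup), , drop = FALSE]
  rd <- reads[reads$qname %in% dup, , drop = FALSE]
  if (nrow(rd) == 0) return(list(pairs = NULL, singles = singles))
  rd <- rd[order(rd$qname, rd$pos0), ]
  iL <- seq(1, nrow(rd), by = 2)
  iR <- iL + 1L
  pairs <- data.frame(qname = rd$qname[iL],
                      bL = rd$pos0[iL], eL = rd$end0[iL],
                      bR = rd$pos0[iR], eR = rd$end0[iR],
                      strandL = rd$strand[iL], strandR = rd$strand[iR],
                      iL = iL, iR = iR, stringsAsFactors = FALSE)
  list(pairs = pairs, rd = rd, singles = singles)
}

#' Select and classify the read pairs of one deletion analysis window
#'
#' Fetches pairs with at least one mate overlapping \code{[FL, FR)}, keeps
#' those in forward/reverse orientation regardless of the aligner's
#' proper-pair flag (spanning pairs of a deleted haplotype exceed the
#' expected insert and are flagged discordant), and classifies each pair as
#' type I, S or A; pairs matching no class are dropped. A confirmed split
#' takes precedence over I and A.
#'
#' @param bam indexed BAM path.
#' @param window from [build_window()].
#' @param reference named [Biostrings::DNAStringSet].
#' @param min_clip minimum soft-clip length to attempt split realignment.
#' @param min_score,min_flank split realignment acceptance thresholds.
#' @param rg2lib named map from read-group ID to library name.
#' @return data.frame of classified pairs: type, y (insert length), library.
#' @export
classify_window_pairs <- function(bam, window, reference, min_clip = 10L,
                                  min_score = 25, min_flank = 20,
                                  rg2lib = character(0)) {
  reads <- scan_reads(bam, window$chrom, window$FL, window$FR)
  reads <- assign_lib(reads, rg2lib)
  classify_window_pairs_from_reads(reads, window, reference,
                                   min_clip = min_clip,
                                   min_score = min_score,
                                   min_flank = min_flank)
}

classify_window_pairs_from_reads <- function(reads, window, reference,
                                             min_clip = 10L, min_score = 25,
                                             min_flank = 20) {
  ref_chrom_seq <- reference[[window$chrom]]
  pt <- window_pair_table(reads)
  out <- data.frame(qname = character(), type = character(), y = numeric(),
                    library = character(), clip_pos = integer(),
                    stringsAsFactors = FALSE)

  # split candidates among all fetched reads (paired or singleton)
  split_ok <- rep(FALSE, nrow(reads))
  cand_idx <- which((reads$clipR >= min_clip &
                       abs(reads$end0 - window$AL) <= 10L) |
                      (reads$clipL >= min_clip &
                         abs(reads$pos0 - window$AR) <= 10L))
  if (length(cand_idx)) {
    right_side <- reads$clipR[cand_idx] >= min_clip &
      abs(reads$end0[cand_idx] - window$AL) <= 10L
    cand <- data.frame(
      seq = reads$seq[cand_idx],
      side = ifelse(right_side, "R", "L"),
      clip_len = ifelse(right_side, reads$clipR[cand_idx], reads$clipL[cand_idx]),
      mapped_len = nchar(reads$seq[cand_idx]) - reads$clipL[cand_idx] -
        reads$clipR[cand_idx],
      clip_pos = ifelse(right_side, reads$end0[cand_idx], reads$pos0[cand_idx]),
      stringsAsFactors = FALSE)
    cand <- realign_clips_batch(cand, window, ref_chrom_seq,
                                min_score = min_score, min_flank = min_flank)
    split_ok[cand_idx] <- cand$accepted
  }

  lib_of <- function(i) if (!is.null(reads$lib)) reads$lib[i] else "default"

  if (!is.null(pt$pairs) && nrow(pt$pairs) > 0) {
    p <- pt$pairs
    ok_orient <- p$strandL == "+" & p$strandR == "-"
    s_pair <- split_ok[p$iL] | split_ok[p$iR]
    FL <- window$FL; FR <- window$FR; AL <- window$AL; AR <- window$AR
    in_lf <- p$bL >= FL & p$eL <= AL
    in_rf <- p$bR >= AR & p$eR <= FR
    typeI <- (in_lf & p$bR >= AL & p$eR <= AR) |
      (p$bL >= AL & p$eL <= AR & in_rf)
    typeA <- in_lf & in_rf
    type <- rep(NA_character_, nrow(p))
    type[ok_orient & typeA] <- "A"
    type[ok_orient & typeI] <- "I"
    type[s_pair] <- "S"
    keep <- which(!is.na(type))
    if (length(keep)) {
      cp <- ifelse(split_ok[p$iL[keep]], pt$rd$end0[p$iL[keep]],
                   pt$rd$end0[p$iR[keep]])
      out <- rbind(out, data.frame(
        qname = p$qname[keep], type = type[keep],
        y = p$eR[keep] - p$bL[keep],
        library = vapply(p$iL[keep], function(i)
          if (!is.null(pt$rd$lib)) pt$rd$lib[i] else "default", character(1)),
        clip_pos = ifelse(type[keep] == "S", cp, NA_integer_),
        stringsAsFactors = FALSE))
    }
  }
  # singletons can only contribute split evidence
  if (nrow(pt$singles) > 0) {
    sidx <- match(pt$singles$qname, reads$qname)
    s_ok <- split_ok[sidx]
    if (any(s_ok)) {
      s <- pt$singles[s_ok, , drop = FALSE]
      out <- rbind(out, data.frame(
        qname = s$qname, type = "S", y = NA_real_,
        library = if (!is.null(s$lib)) s$lib else rep("default", nrow(s)),
        clip_pos = s$end0, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Genotype Alu deletions at annotated loci
#'
#' Runs the full deletion path for one or more individuals: estimates each
#' sample's insert-length model, builds the analysis window of every
#' annotated Alu, classifies read pairs and computes genotype likelihoods.
#'
#' @param reference reference FASTA path or a named
#'   [Biostrings::DNAStringSet].
#' @param bams character vector of indexed BAM paths, one per individual.
#' @param alu_bed BED path of annotated Alu elements (or a data.frame from
#'   [read_alu_bed()]).
#' @param pe junction-read error probability (default 0.001).
#' @param min_evidence minimum classified pairs for a genotype call.
#' @param min_clip,min_flank,min_score split realignment parameters.
#' @param min_pairs minimum concordant pairs for the insert model.
#' @param samples sample names; default read from the BAM read groups.
#' @return an object of class \code{alu_deletion_calls}: the locus table and
#'   per-sample genotype (event dosage 0/1/2), GQ, PL and evidence-count
#'   matrices, ready for [write_calls_vcf()].
#' @export
alu_deletion_call <- function(reference, bams, alu_bed, pe = 0.001,
                              min_evidence = 2L, min_clip = 10L,
                              min_flank = 20, min_score = 25,
                              min_pairs = 1000L, samples = NULL) {
  ref <- if (is.character(reference)) Biostrings::readDNAStringSet(reference)
         else reference
  names(ref) <- sub("\\s.*", "", names(ref))
  loci <- if (is.character(alu_bed)) read_alu_bed(alu_bed) else alu_bed
  if (is.null(samples)) samples <- unname(vapply(bams, bam_sample_name, character(1)))
  nL <- nrow(loci); nS <- length(bams)
  gt <- gq <- matrix(NA_integer_, nL, nS, dimnames = list(loci$name, samples))
  nI <- nS_ <- nA <- matrix(0L, nL, nS, dimnames = list(loci$name, samples))
  pl <- array(0L, c(nL, nS, 3))
  models <- list()
  for (s in seq_len(nS)) {
    model <- estimate_insert_model(bams[s], min_pairs = min_pairs)
    models[[samples[s]]] <- model
    chrlen <- bam_chrom_lengths(bams[s])
    rg2lib <- rg_library_map(Rsamtools::scanBamHeader(bams[s])[[1]]$text, bams[s])
    for (i in seq_len(nL)) {
      locus <- loci[i, ]
      window <- build_window(locus, model, chrom_len = chrlen[[locus$chrom]])
      cp <- classify_window_pairs(bams[s], window, ref, min_clip = min_clip,
                                  min_score = min_score, min_flank = min_flank,
                                  rg2lib = rg2lib)
      lik <- pair_allele_likelihoods(cp$type, cp$y, model,
                                     l_alu = window$l_alu,
                                     library = cp$library, pe = pe)
      ll <- genotype_likelihoods(lik, read_len = model$read_len,
                                 l_alu = window$l_alu)
      call <- call_genotype(ll, n_evidence = nrow(cp),
                            min_evidence = min_evidence)
      gt[i, s] <- call$genotype
      gq[i, s] <- call$gq
      pl[i, s, ] <- call$pl
      nI[i, s] <- sum(cp$type == "I")
      nS_[i, s] <- sum(cp$type == "S")
      nA[i, s] <- sum(cp$type == "A")
    }
  }
  structure(list(loci = loci, samples = samples, genotype = gt, gq = gq,
                 pl = pl, n_I = nI, n_S = nS_, n_A = nA, models = models,
                 type = "DEL"),
            class = c("alu_deletion_calls", "alu_calls"))
}

#' @export
print.alu_calls <- function(x, ...) {
  cat(sprintf("Alu %s calls: %d loci x %d samples\n",
              if (x$type == "DEL") "deletion" else "insertion",
              nrow(x$loci), length(x$samples)))
  called <- sum(!is.na(x$genotype))
  cat(sprintf("  genotypes called: %d / %d (%.1f%%)\n", called,
              length(x$genotype), 100 * called / max(1, length(x$genotype))))
  carriers <- sum(x$genotype > 0, na.rm = TRUE)
  cat(sprintf("  carrier genotypes: %d\n", carriers))
  invisible(x)
}
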