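# Alu insertion caller -----------------------------------------------------
#
# Discovery of Alu insertion sites absent from the reference, pooled across
# individuals: discordant pairs with one mate in a known Alu (D) localize
# candidate regions, soft-clipped reads (C) pin the precise breakpoints via
# a two-level voting scheme, and genotypes are called by in-silico insertion
# through the shared likelihood engine.

#' Collect insertion-informative reads from one sample
#'
#' Emits the two evidence classes of the insertion path. D read pairs are
#' discordant pairs with exactly one read overlapping an annotated Alu; the
#' non-Alu mate becomes the anchor, classed \code{la} if it maps forward
#' (insertion expected to its right) or \code{ra} if reverse. C reads are
#' soft-clipped reads passing quality filters (clip length, clipped-segment
#' base quality, anchor MAPQ). Anchors lying inside annotated Alus are
#' discarded.
#'
#' @param reads read table from [scan_reads()] (one sample).
#' @param alu_ranges [GenomicRanges::GRanges] of annotated Alu elements.
#' @param model the sample's \code{insert_model}.
#' @param min_clip minimum soft-clip length for a C read (bp).
#' @param min_clip_qual minimum mean base quality of the clipped segment.
#' @param min_anchor_mapq minimum anchor mapping quality.
#' @param unmapped_mates optional data.frame from [scan_unmapped_mates()];
#'   when supplied together with \code{panel}, unmapped mates whose sequence
#'   aligns to the consensus panel are accepted as Alu evidence.
#' @param panel consensus panel for unmapped-mate rescue.
#' @param min_score minimum panel alignment score for rescued mates.
#' @return list with data.frames \code{D} (anchor coordinates and class) and
#'   \code{C} (clip side, clip position, clipped sequence).
#' @export
collect_informative <- function(reads, alu_ranges, model, min_clip = 10L,
                                min_clip_qual = 20, min_anchor_mapq = 20L,
                                unmapped_mates = NULL, panel = NULL,
                                min_score = 25) {
  if (nrow(reads) == 0) {
    return(list(D = data.frame(), C = data.frame()))
  }
  gr_read <- GenomicRanges::GRanges(reads$chrom,
                                    IRanges::IRanges(reads$pos0 + 1L, reads$end0))
  in_alu <- IRanges::overlapsAny(gr_read, alu_ranges)
  # mate interval approximated by mate position + read length
  mate_ok <- !is.na(reads$mrnm) & !reads$mate_unmapped
  gr_mate <- GenomicRanges::GRanges(
    ifelse(mate_ok, reads$mrnm, reads$chrom[1]),
    IRanges::IRanges(pmax(reads$mpos0, 0L) + 1L,
                     pmax(reads$mpos0, 0L) + reads$qwidth))
  mate_in_alu <- mate_ok & IRanges::overlapsAny(gr_mate, alu_ranges)

  disc <- !reads_concordant(reads, model)
  d_idx <- which(disc & mate_in_alu & !in_alu &
                   reads$mapq >= min_anchor_mapq)
  D <- data.frame(qname = reads$qname[d_idx], chrom = reads$chrom[d_idx],
                  begin = reads$pos0[d_idx], end = reads$end0[d_idx],
                  class = ifelse(reads$strand[d_idx] == "+", "la", "ra"),
                  stringsAsFactors = FALSE)

  # unmapped-mate rescue: anchors whose mate is unmapped but Alu-like
  if (!is.null(unmapped_mates) && !is.null(panel) && nrow(unmapped_mates)) {
    anchors <- which(reads$mate_unmapped & !in_alu &
                       reads$mapq >= min_anchor_mapq)
    m <- match(reads$qname[anchors], unmapped_mates$qname)
    anchors <- anchors[!is.na(m)]
    m <- m[!is.na(m)]
    if (length(anchors)) {
      hit <- panel_best_hit(unmapped_mates$seq[m], panel)
      ok <- hit$score >= min_score
      if (any(ok)) {
        a <- anchors[ok]
        D <- rbind(D, data.frame(
          qname = reads$qname[a], chrom = reads$chrom[a],
          begin = reads$pos0[a], end = reads$end0[a],
          class = ifelse(reads$strand[a] == "+", "la", "ra"),
          stringsAsFactors = FALSE))
      }
    }
  }

  clip_side <- ifelse(reads$clipR >= pmax(reads$clipL, min_clip), "R",
                      ifelse(reads$clipL >= min_clip, "L", NA))
  c_idx <- which(!is.na(clip_side) & !in_alu & reads$mapq >= min_anchor_mapq)
  if (length(c_idx)) {
    side <- clip_side[c_idx]
    clen <- ifelse(side == "R", reads$clipR[c_idx], reads$clipL[c_idx])
    rl <- nchar(reads$seq[c_idx])
    from <- ifelse(side == "R", rl - clen + 1L, 1L)
    to <- ifelse(side == "R", rl, clen)
    cq <- vapply(seq_along(c_idx), function(k)
      mean_qual(reads$qual[c_idx[k]], from[k], to[k]), numeric(1))
    keep <- cq >= min_clip_qual
    c_idx <- c_idx[keep]; side <- side[keep]; clen <- clen[keep]
    from <- from[keep]; to <- to[keep]
    C <- data.frame(qname = reads$qname[c_idx], chrom = reads$chrom[c_idx],
                    side = side,
                    clip_pos = ifelse(side == "R", reads$end0[c_idx],
                                      reads$pos0[c_idx]),
                    clip_len = clen,
                    clip_seq = substr(reads$seq[c_idx], from, to),
                    anchor_len = nchar(reads$seq[c_idx]) -
                      reads$clipL[c_idx] - reads$clipR[c_idx],
                    stringsAsFactors = FALSE)
  } else {
    C <- data.frame(qname = character(), chrom = character(),
                    side = character(), clip_pos = integer(),
                    clip_len = integer(), clip_seq = character(),
                    anchor_len = integer(), stringsAsFactors = FALSE)
  }
  list(D = D, C = C)
}

# best local alignment of each query against any panel sequence (both strands)
panel_best_hit <- function(queries, panel) {
  submat <- .sw_submat()
  n <- length(queries)
  best <- rep(-Inf, n); fam <- rep(NA_character_, n)
  qs <- Biostrings::DNAStringSet(queries)
  subjects <- c(panel, Biostrings::reverseComplement(panel))
  nm <- c(names(panel), names(panel))
  for (j in seq_along(subjects)) {
    sc <- Biostrings::pairwiseAlignment(qs, subjects[[j]], type = "local",
                                        substitutionMatrix = submat,
                                        gapOpening = 3, gapExtension = 1,
                                        scoreOnly = TRUE)
    upd <- sc > best
    best[upd] <- sc[upd]
    fam[upd] <- nm[j]
  }
  data.frame(score = best, family = fam, stringsAsFactors = FALSE)
}

#' Scan a chromosome for positions supported by la/ra anchors
#'
#' A position p covers an \code{la} anchor when
#' \code{p in [end(r), begin(r) + w]} and an \code{ra} anchor when
#' \code{p in [end(r) - w, begin(r)]}, with \code{w = E[Y] + 3 sd(Y)}.
#' Only candidate positions \code{p = end(la)} or \code{p = end(ra)} are
#' evaluated; positions with \code{support(p) > n} are returned in
#' increasing order. The sorted-sweep implementation is equivalent to the
#' brute-force count over all candidate positions.
#'
#' @param anchors data.frame with columns begin, end, class ("la"/"ra") from
#'   one chromosome.
#' @param w window width in bp (from [flank_width()]).
#' @param n support threshold; positions must exceed it.
#' @return data.frame(pos, support), sorted by position.
#' @export
scan_support <- function(anchors, w, n = 4L) {
  if (nrow(anchors) == 0)
    return(data.frame(pos = integer(), support = integer()))
  la <- anchors[anchors$class == "la", , drop = FALSE]
  ra <- anchors[anchors$class == "ra", , drop = FALSE]
  cand <- sort(unique(anchors$end))
  support <- integer(length(cand))
  if (nrow(la)) {
    lo <- sort(la$end); hi <- sort(la$begin + w)
    support <- support + findInterval(cand, lo) -
      findInterval(cand - 1L, hi)
  }
  if (nrow(ra)) {
    lo <- sort(ra$end - w); hi <- sort(ra$begin)
    support <- support + findInterval(cand, lo) -
      findInterval(cand - 1L, hi)
  }
  keep <- support > n
  data.frame(pos = cand[keep], support = support[keep])
}

#' Group supported positions into candidate regions
#'
#' Greedy left-to-right construction: a region starts at the first position
#' and is extended by each next position \code{p} while \code{p - b < len};
#' otherwise a new region starts at \code{p}. Every region spans less than
#' \code{len} bp.
#'
#' @param positions sorted ascending integer positions.
#' @param len maximum region length (default 200 bp).
#' @return data.frame(b, e).
#' @export
build_regions <- function(positions, len = 200L) {
  if (length(positions) == 0)
    return(data.frame(b = integer(), e = integer()))
  stopifnot(!is.unsorted(positions))
  b <- e <- positions[1]
  out_b <- out_e <- integer(0)
  for (p in positions[-1]) {
    if (p - b < len) {
      e <- p
    } else {
      out_b <- c(out_b, b); out_e <- c(out_e, e)
      b <- e <- p
    }
  }
  data.frame(b = c(out_b, b), e = c(out_e, e))
}

#' Merge per-sample candidate regions across individuals
#'
#' Pools all samples' regions, traverses them by increasing begin position
#' and incrementally merges two adjacent regions (b_k, e_k), (b_l, e_l) when
#' \code{b_l < e_k} and \code{e_l - b_k < len}; contributing-sample sets are
#' unioned.
#'
#' @param region_list named list (by sample) of data.frames from
#'   [build_regions()].
#' @param len maximum region length.
#' @return data.frame(b, e, samples) with comma-separated sample sets.
#' @export
merge_regions_multi <- function(region_list, len = 200L) {
  rows <- do.call(rbind, lapply(names(region_list), function(s) {
    r <- region_list[[s]]
    if (is.null(r) || nrow(r) == 0) return(NULL)
    data.frame(b = r$b, e = r$e, sample = s, stringsAsFactors = FALSE)
  }))
  if (is.null(rows) || nrow(rows) == 0)
    return(data.frame(b = integer(), e = integer(), samples = character()))
  rows <- rows[order(rows$b, rows$e), , drop = FALSE]
  out <- list()
  cur_b <- rows$b[1]; cur_e <- rows$e[1]; cur_s <- rows$sample[1]
  for (i in seq_len(nrow(rows))[-1]) {
    if (rows$b[i] < cur_e && rows$e[i] - cur_b < len) {
      cur_e <- max(cur_e, rows$e[i])
      cur_s <- union(cur_s, rows$sample[i])
    } else {
      out[[length(out) + 1]] <- list(b = cur_b, e = cur_e, s = cur_s)
      cur_b <- rows$b[i]; cur_e <- rows$e[i]; cur_s <- rows$sample[i]
    }
  }
  out[[length(out) + 1]] <- list(b = cur_b, e = cur_e, s = cur_s)
  data.frame(b = vapply(out, `[[`, numeric(1), "b"),
             e = vapply(out, `[[`, numeric(1), "e"),
             samples = vapply(out, function(x)
               paste(sort(x$s), collapse = ","), character(1)),
             stringsAsFactors = FALSE)
}

#' Split-map a clipped read against the Alu consensus panel
#'
#' For a C read inside a candidate region, the soft-clipped part is aligned
#' locally to every panel sequence on both strands (the anchored part is
#' taken from its reference alignment). A valid split requires at least
#' \code{min_flank} bp on each side (anchor and clipped part) and a clipped
#' alignment scoring at least 60\% of its maximum. A read clipped on its
#' right side votes for a left breakpoint AL at its clip position; a read
#' clipped on its left side votes for AR.
#'
#' @param c_read one row of the \code{C} table from [collect_informative()].
#' @param panel [Biostrings::DNAStringSet] consensus panel (or a single
#'   pre-selected family).
#' @param min_flank minimum aligned bp on each side.
#' @return list(side, ref_breakpoint, alu_hit, score) or \code{NULL}.
#' @export
split_map_c_read <- function(c_read, panel, min_flank = 20L) {
  if (c_read$anchor_len < min_flank || c_read$clip_len < min_flank)
    return(NULL)
  hit <- panel_best_hit(c_read$clip_seq, panel)
  if (hit$score[1] < 0.6 * c_read$clip_len) return(NULL)
  list(side = if (c_read$side == "R") "left" else "right",
       ref_breakpoint = c_read$clip_pos,
       alu_hit = hit$family[1], score = hit$score[1])
}

# batched variant: returns C table with vote columns
split_map_c_batch <- function(C, panel, min_flank = 20L) {
  C$vote <- FALSE
  C$family <- NA_character_
  C$score <- NA_real_
  ok <- which(C$anchor_len >= min_flank & C$clip_len >= min_flank)
  if (!length(ok)) return(C)
  hit <- panel_best_hit(C$clip_seq[ok], panel)
  acc <- hit$score >= 0.6 * C$clip_len[ok]
  C$vote[ok] <- acc
  C$family[ok] <- hit$family
  C$score[ok] <- hit$score
  C
}

# Split-map every C read of one candidate region (all samples pooled).
# The Alu family is elected from a subsample of the longest clips against
# the full panel; the remaining reads are confirmed against that family
# only, which keeps the alignment work per region small.
region_split_votes <- function(C, panel, min_flank = 20L,
                               family_probe = 24L) {
  C$vote <- FALSE
  C$family <- NA_character_
  ok <- which(C$anchor_len >= min_flank & C$clip_len >= min_flank)
  if (!length(ok)) return(C)
  probe <- ok[order(-C$clip_len[ok])][seq_len(min(family_probe, length(ok)))]
  probe_hit <- panel_best_hit(C$clip_seq[probe], panel)
  good <- probe_hit$score >= 0.6 * C$clip_len[probe]
  if (!any(good)) return(C)
  fam <- names(sort(table(probe_hit$family[good]), decreasing = TRUE))[1]
  hit <- panel_best_hit(C$clip_seq[ok], panel[fam])
  acc <- hit$score >= 0.6 * C$clip_len[ok]
  C$vote[ok] <- acc
  C$family[ok][acc] <- fam
  C
}

#' Elect breakpoints by two-level voting
#'
#' AL and AR are voted independently. Level 1: within each individual, the
#' modal split position per side (ties toward the smaller position). Level
#' 2: across individuals' level-1 positions, the modal position (ties toward
#' the larger total read support, then the smaller position). If both sides
#' are elected but differ by more than \code{bp_tol}, only the side with
#' more level-2 votes is kept. Returns \code{NULL} when no side receives a
#' vote (the region is excluded).
#'
#' @param votes data.frame with columns sample, side ("left"/"right"),
#'   pos, family.
#' @param bp_tol maximum |AL - AR| (default 50 bp; target-site duplications
#'   and deletions displace the two ends).
#' @return list(AL, AR, tsd_len, family, votes_l, votes_r) or \code{NULL};
#'   unset sides are NA.
#' @export
vote_breakpoints <- function(votes, bp_tol = 50L) {
  if (is.null(votes) || nrow(votes) == 0) return(NULL)
  elect <- function(v) {
    if (nrow(v) == 0) return(list(pos = NA_integer_, n = 0L))
    lvl1 <- lapply(split(v, v$sample), function(d) {
      t <- table(d$pos)
      best <- max(t)
      pos <- min(as.integer(names(t)[t == best]))
      list(pos = pos, reads = sum(d$pos == pos))
    })
    pos1 <- vapply(lvl1, `[[`, numeric(1), "pos")
    reads1 <- vapply(lvl1, `[[`, numeric(1), "reads")
    t2 <- table(pos1)
    best <- max(t2)
    cands <- as.integer(names(t2)[t2 == best])
    if (length(cands) > 1) {
      support <- vapply(cands, function(p) sum(reads1[pos1 == p]), numeric(1))
      cands <- cands[support == max(support)]
    }
    list(pos = min(cands), n = as.integer(best))
  }
  L <- elect(votes[votes$side == "left", , drop = FALSE])
  R <- elect(votes[votes$side == "right", , drop = FALSE])
  if (L$n == 0 && R$n == 0) return(NULL)
  AL <- L$pos; AR <- R$pos
  if (!is.na(AL) && !is.na(AR) && abs(AL - AR) > bp_tol) {
    if (L$n >= R$n) AR <- NA_integer_ else AL <- NA_integer_
  }
  fam <- votes$family[!is.na(votes$family)]
  fam <- if (length(fam)) names(sort(table(fam), decreasing = TRUE))[1]
         else NA_character_
  tsd <- if (!is.na(AL) && !is.na(AR) && AL > AR) AL - AR else 0L
  list(AL = AL, AR = AR, tsd_len = tsd, family = fam,
       votes_l = L$n, votes_r = R$n)
}

#' Genotype an Alu insertion site in one sample
#'
#' Reduction to the deletion likelihood engine by in-silico insertion: in
#' the frame where the Alu is present, D pairs and split-confirmed C reads
#' are junction evidence for the Alu-carrying allele (engine type I), and
#' concordant pairs spanning the breakpoint are type A with their observed
#' insert shifted by \code{delta} (a spanning pair of a carrier haplotype
#' has insert Y - delta on the Alu-less reference). The engine genotype is
#' mapped to insertion dosage: engine G0 (homozygote Alu) = homozygous
#' carrier.
#'
#' @param n_junction number of D-pair + split-confirmed C-read fragments.
#' @param span_y insert lengths of concordant pairs spanning the breakpoint.
#' @param span_lib their libraries.
#' @param model the sample's \code{insert_model}.
#' @param delta assumed inserted length in bp (default 300).
#' @param pe junction error probability.
#' @param min_evidence minimum fragments for a call.
#' @return list from [call_genotype()] plus \code{dosage} (0/1/2 copies of
#'   the insertion) and evidence counts.
#' @export
genotype_insertion <- function(n_junction, span_y, span_lib = "default",
                               model, delta = 300L, pe = 0.001,
                               min_evidence = 2L) {
  type <- c(rep("I", n_junction), rep("A", length(span_y)))
  y <- c(rep(NA_real_, n_junction), span_y + delta)
  lib <- c(rep("default", n_junction), rep_len(span_lib, length(span_y)))
  lik <- pair_allele_likelihoods(type, y, model, l_alu = delta,
                                 library = lib, pe = pe)
  ll <- genotype_likelihoods(lik, read_len = model$read_len, l_alu = delta)
  call <- call_genotype(ll, n_evidence = length(type),
                        min_evidence = min_evidence)
  call$dosage <- if (is.na(call$genotype)) NA_integer_ else 2L - call$genotype
  call$n_I <- n_junction
  call$n_A <- length(span_y)
  call
}

#' Detect candidate insertion regions from per-sample anchor sets
#'
#' The discovery stage of the insertion path, separated from alignment
#' handling. Per sample: support scan of la/ra anchors and greedy region
#' construction; across samples: region merging and a pooled support check.
#' In multi-sample mode the per-sample scan runs at the permissive
#' \code{n_pre} and the full threshold \code{n} is applied to the pooled
#' support, so sites below the per-sample threshold in every individual are
#' recovered when the combined evidence suffices (the pooling gain of
#' joint calling). A single sample is scanned directly at \code{n}.
#'
#' @param anchors_by_sample named list of data.frames (begin, end, class,
#'   chrom) of D-read anchors, one per sample.
#' @param w_by_sample numeric vector of per-sample window widths
#'   (E[Y] + 3 sd(Y)).
#' @param n support threshold (pooled in multi-sample mode).
#' @param n_pre per-sample prescan threshold in multi-sample mode.
#' @param region_len maximum region length (bp).
#' @return data.frame(chrom, b, e, support) of candidate regions passing
#'   the pooled check.
#' @export
detect_insertion_regions <- function(anchors_by_sample, w_by_sample,
                                     n = 4L, n_pre = 1L, region_len = 200L) {
  nSamp <- length(anchors_by_sample)
  pre_n <- if (nSamp > 1) n_pre else n
  regions <- lapply(seq_len(nSamp), function(s) {
    a <- anchors_by_sample[[s]]
    if (is.null(a) || nrow(a) == 0) return(NULL)
    out <- lapply(unique(a$chrom), function(chrom) {
      anch <- a[a$chrom == chrom, , drop = FALSE]
      sup <- scan_support(anch, w_by_sample[s], n = pre_n)
      r <- build_regions(sup$pos, len = region_len)
      if (nrow(r)) r$chrom <- chrom
      r
    })
    do.call(rbind, out)
  })
  names(regions) <- names(anchors_by_sample)
  chroms <- unique(unlist(lapply(regions, function(r)
    if (!is.null(r) && nrow(r)) r$chrom else character(0))))
  sites <- list()
  for (chrom in chroms) {
    rl <- lapply(regions, function(r) {
      if (is.null(r) || nrow(r) == 0) return(NULL)
      r <- r[r$chrom == chrom, c("b", "e"), drop = FALSE]
      if (nrow(r)) r else NULL
    })
    rl <- rl[!vapply(rl, is.null, logical(1))]
    merged <- merge_regions_multi(rl, len = region_len)
    if (nrow(merged) == 0) next
    pooled <- do.call(rbind, lapply(anchors_by_sample, function(a)
      a[a$chrom == chrom, , drop = FALSE]))
    w_pool <- max(w_by_sample)
    sup_pool <- scan_support(pooled, w_pool, n = n)
    for (i in seq_len(nrow(merged))) {
      hit <- sup_pool$pos >= merged$b[i] & sup_pool$pos <= merged$e[i]
      if (!any(hit)) next
      sites[[length(sites) + 1]] <- data.frame(
        chrom = chrom, b = merged$b[i], e = merged$e[i],
        support = max(sup_pool$support[hit]), stringsAsFactors = FALSE)
    }
  }
  if (length(sites) == 0)
    return(data.frame(chrom = character(), b = integer(), e = integer(),
                      support = integer(), stringsAsFactors = FALSE))
  do.call(rbind, sites)
}

#' Discover and genotype Alu insertions across individuals
#'
#' The full insertion path: per-sample informative-read collection and
#' support scanning, candidate-region construction, cross-sample merging
#' with a pooled support check, two-level breakpoint voting against the
#' consensus panel, and per-sample genotyping by in-silico insertion.
#'
#' In multi-sample mode, per-sample candidate positions are pre-scanned at
#' the permissive threshold \code{n_pre} and the full threshold \code{n} is
#' applied to the pooled support of the merged region, so sites below the
#' per-sample threshold in every individual are still recovered when their
#' combined support suffices.
#'
#' @param reference reference FASTA path or named [Biostrings::DNAStringSet].
#' @param bams indexed BAM paths, one per individual.
#' @param alu_bed annotated Alu elements (BED path or data.frame).
#' @param panel Alu consensus panel (FASTA path or DNAStringSet); default is
#'   the synthetic panel shipped with the package.
#' @param n support threshold (positions need support > n).
#' @param n_pre per-sample prescan threshold in multi-sample mode.
#' @param region_len maximum candidate-region length (bp).
#' @param delta assumed inserted Alu length for genotyping (bp).
#' @param bp_tol maximum |AL - AR| (bp).
#' @param min_clip,min_clip_qual,min_anchor_mapq C-read filters.
#' @param min_flank minimum aligned bp on each side of a split.
#' @param pe junction error probability.
#' @param min_evidence minimum fragments for a genotype call.
#' @param min_pairs minimum pairs for the insert model.
#' @param use_unmapped_mates accept unmapped mates that align to the panel
#'   as Alu evidence.
#' @param samples sample names (default from read groups).
#' @return object of class \code{alu_insertion_calls} / \code{alu_calls}
#'   with the called site table (chrom, pos, AL, AR, tsd_len, family) and
#'   per-sample genotype/GQ/evidence matrices.
#' @export
alu_insertion_call <- function(reference, bams, alu_bed,
                               panel = load_alu_panel(), n = 4L, n_pre = 1L,
                               region_len = 200L, delta = 300L, bp_tol = 50L,
                               min_clip = 10L, min_clip_qual = 20,
                               min_anchor_mapq = 20L, min_flank = 20L,
                               pe = 0.001, min_evidence = 2L,
                               min_pairs = 1000L,
                               use_unmapped_mates = FALSE, samples = NULL) {
  ref <- if (is.character(reference)) Biostrings::readDNAStringSet(reference)
         else reference
  names(ref) <- sub("\\s.*", "", names(ref))
  loci <- if (is.character(alu_bed)) read_alu_bed(alu_bed) else alu_bed
  if (is.character(panel)) panel <- load_alu_panel(panel)
  if (is.null(samples)) samples <- unname(vapply(bams, bam_sample_name, character(1)))
  nSamp <- length(bams)
  alu_ranges <- GenomicRanges::GRanges(loci$chrom,
                                       IRanges::IRanges(loci$AL + 1L, loci$AR))

  per <- vector("list", nSamp)
  names(per) <- samples
  for (s in seq_len(nSamp)) {
    reads <- scan_reads(bams[s])
    rg2lib <- rg_library_map(Rsamtools::scanBamHeader(bams[s])[[1]]$text,
                             bams[s])
    reads <- assign_lib(reads, rg2lib)
    model <- estimate_insert_model(bams[s], min_pairs = min_pairs)
    um <- if (use_unmapped_mates) scan_unmapped_mates(bams[s]) else NULL
    info <- collect_informative(reads, alu_ranges, model,
                                min_clip = min_clip,
                                min_clip_qual = min_clip_qual,
                                min_anchor_mapq = min_anchor_mapq,
                                unmapped_mates = um,
                                panel = if (use_unmapped_mates) panel else NULL)
    conc <- reads_concordant(reads, model)
    # per-chromosome position index for fast spanning-pair lookup
    by_chrom <- lapply(split(seq_len(nrow(reads)), reads$chrom), function(i) {
      o <- i[order(reads$pos0[i])]
      list(idx = o, pos = reads$pos0[o])
    })
    per[[s]] <- list(model = model, reads = reads, info = info,
                     conc = conc, by_chrom = by_chrom,
                     w = flank_width(model))
  }

  site_tab <- detect_insertion_regions(
    lapply(per, function(p) p$info$D),
    vapply(per, `[[`, numeric(1), "w"),
    n = n, n_pre = n_pre, region_len = region_len)
  if (nrow(site_tab) == 0) {
    return(empty_insertion_calls(samples))
  }
  sites <- split(site_tab, seq_len(nrow(site_tab)))

  # breakpoint voting and genotyping per site
  calls <- list()
  for (site in sites) {
    Cpool <- do.call(rbind, lapply(seq_len(nSamp), function(s) {
      C <- per[[s]]$info$C
      if (nrow(C) == 0) return(NULL)
      inreg <- C$chrom == site$chrom &
        C$clip_pos >= site$b - 2L * region_len &
        C$clip_pos <= site$e + 2L * region_len
      C <- C[inreg, , drop = FALSE]
      if (nrow(C) == 0) return(NULL)
      # cap the split-mapping work per sample; the longest clips carry the
      # most alignment information
      if (nrow(C) > 40L) C <- C[order(-C$clip_len)[1:40], , drop = FALSE]
      C$sample <- samples[s]
      C
    }))
    votes <- NULL
    if (!is.null(Cpool) && nrow(Cpool)) {
      Cpool <- region_split_votes(Cpool, panel, min_flank = min_flank)
      Cacc <- Cpool[Cpool$vote, , drop = FALSE]
      if (nrow(Cacc))
        votes <- data.frame(
          sample = Cacc$sample,
          side = ifelse(Cacc$side == "R", "left", "right"),
          pos = Cacc$clip_pos, family = Cacc$family, qname = Cacc$qname,
          stringsAsFactors = FALSE)
    }
    bp <- vote_breakpoints(votes, bp_tol = bp_tol)
    if (is.null(bp)) next  # region excluded: no determinable breakpoint
    P <- if (!is.na(bp$AL)) bp$AL else bp$AR
    site_call <- list(chrom = site$chrom, pos = P, AL = bp$AL, AR = bp$AR,
                      tsd_len = bp$tsd_len, family = bp$family,
                      support = site$support)
    gts <- vector("list", nSamp)
    for (s in seq_len(nSamp)) {
      p <- per[[s]]
      # junction fragments: D anchors whose admissible window covers P,
      # plus this sample's split-confirmed votes (counted once per fragment)
      D <- p$info$D
      d_cov <- D$chrom == site$chrom &
        ((D$class == "la" & P >= D$end & P <= D$begin + p$w) |
           (D$class == "ra" & P >= D$end - p$w & P <= D$begin))
      d_q <- unique(D$qname[d_cov])
      c_q <- if (!is.null(votes))
        unique(votes$qname[votes$sample == samples[s]]) else character(0)
      junction_q <- union(d_q, c_q)
      # spanning concordant pairs, excluding junction fragments; the
      # position index narrows the search to reads starting within one
      # window upstream of the breakpoint
      rd <- p$reads
      bc <- p$by_chrom[[site$chrom]]
      span <- integer(0)
      if (!is.null(bc)) {
        lo <- findInterval(P - p$w - 1L, bc$pos) + 1L
        hi <- findInterval(P - 1L, bc$pos)
        if (hi >= lo) {
          span <- bc$idx[lo:hi]
          span <- span[rd$strand[span] == "+" & p$conc[span] &
                         rd$pos0[span] + rd$isize[span] > P &
                         !(rd$qname[span] %in% junction_q)]
          # drop pairs clipped at the breakpoint that failed confirmation
          span <- span[rd$clipL[span] < min_clip &
                         rd$clipR[span] < min_clip]
        }
      }
      gts[[s]] <- genotype_insertion(length(junction_q),
                                     rd$isize[span], rd$lib[span],
                                     p$model, delta = delta, pe = pe,
                                     min_evidence = min_evidence)
    }
    site_call$genotypes <- gts
    calls[[length(calls) + 1]] <- site_call
  }
  if (length(calls) == 0) return(empty_insertion_calls(samples))

  # adjacent regions can elect (nearly) the same breakpoint; keep the
  # best-supported call per breakpoint cluster
  ord0 <- order(vapply(calls, `[[`, character(1), "chrom"),
                vapply(calls, function(x) as.integer(x$pos), integer(1)))
  calls <- calls[ord0]
  dedup <- list(calls[[1]])
  for (k in seq_along(calls)[-1]) {
    last <- dedup[[length(dedup)]]
    cur <- calls[[k]]
    if (cur$chrom == last$chrom && abs(cur$pos - last$pos) <= bp_tol) {
      if (cur$support > last$support) dedup[[length(dedup)]] <- cur
    } else {
      dedup[[length(dedup) + 1]] <- cur
    }
  }
  calls <- dedup

  site_df <- data.frame(
    chrom = vapply(calls, `[[`, character(1), "chrom"),
    pos = vapply(calls, function(x) as.integer(x$pos), integer(1)),
    AL = vapply(calls, function(x) as.integer(x$AL %||% NA), integer(1)),
    AR = vapply(calls, function(x) as.integer(x$AR %||% NA), integer(1)),
    tsd_len = vapply(calls, function(x) as.integer(x$tsd_len), integer(1)),
    family = vapply(calls, function(x) x$family %||% NA_character_,
                    character(1)),
    support = vapply(calls, function(x) as.integer(x$support), integer(1)),
    stringsAsFactors = FALSE)
  ord <- order(site_df$chrom, site_df$pos)
  site_df <- site_df[ord, , drop = FALSE]
  calls <- calls[ord]
  site_df$name <- paste0("ins_", seq_len(nrow(site_df)))
  nSite <- nrow(site_df)
  gt <- gq <- matrix(NA_integer_, nSite, nSamp,
                     dimnames = list(site_df$name, samples))
  nI <- nA <- matrix(0L, nSite, nSamp, dimnames = list(site_df$name, samples))
  pl <- array(0L, c(nSite, nSamp, 3))
  for (i in seq_len(nSite)) {
    for (s in seq_len(nSamp)) {
      g <- calls[[i]]$genotypes[[s]]
      gt[i, s] <- g$dosage
      gq[i, s] <- g$gq
      pl[i, s, ] <- rev(g$pl)  # engine G0 = hom carrier; report 0/0 first
      nI[i, s] <- g$n_I
      nA[i, s] <- g$n_A
    }
  }
  structure(list(loci = site_df, samples = samples, genotype = gt, gq = gq,
                 pl = pl, n_I = nI, n_S = nI * 0L, n_A = nA, type = "INS"),
            class = c("alu_insertion_calls", "alu_calls"))
}

empty_insertion_calls <- function(samples) {
  structure(list(loci = data.frame(chrom = character(), pos = integer(),
                                   AL = integer(), AR = integer(),
                                   tsd_len = integer(), family = character(),
                                   support = integer(), name = character(),
                                   stringsAsFactors = FALSE),
                 samples = samples,
                 genotype = matrix(NA_integer_, 0, length(samples)),
                 gq = matrix(NA_integer_, 0, length(samples)),
                 pl = array(0L, c(0, length(samples), 3)),
                 n_I = matrix(0L, 0, length(samples)),
                 n_S = matrix(0L, 0, length(samples)),
                 n_A = matrix(0L, 0, length(samples)),
                 type = "INS"),
            class = c("alu_insertion_calls", "alu_calls"))
}
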