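# Truth-known population simulator ----------------------------------------
#
# Emulates the recurring-Alu benchmark design: Alu loci planted in a
# reference with >= 600 bp spacing, per-locus allele frequencies uniform on
# (0,1), haplotypes carrying each event independently at its frequency and
# paired consecutively into diploids, and truth-aware paired-end alignments
# (soft-clipped junction reads, shifted inserts, discordant Alu mates)
# written directly as sorted, indexed BAM - no external aligner involved.

#' Simulation configuration
#'
#' Defaults mirror the recurring-Alu benchmark design: 100 loci at
#' frequencies uniform on (0,1), 200 haplotypes paired into 100 diploids,
#' >= 600 bp between Alu elements. The reference itself is a seeded
#' synthetic background with diverged decoy Alu copies rather than a human
#' chromosome, so no download is needed; SNP/indel/error rates are our own
#' documented defaults.
#'
#' @param mode \code{"SimDel"} (Alus present in the reference, deleted from
#'   haplotypes) or \code{"SimIns"} (Alus absent from the working reference,
#'   inserted into haplotypes).
#' @param ref_length background reference length (bp).
#' @param n_loci number of polymorphic Alu loci.
#' @param n_decoys fixed (non-polymorphic) diverged Alu copies, the mapping
#'   targets for mates inside inserted elements.
#' @param min_spacing minimum distance between any two Alu elements (bp).
#' @param n_haplotypes even number of haplotypes (paired into diploids).
#' @param coverage mean per-individual coverage (10 or 25 in the benchmark).
#' @param read_len read length (bp).
#' @param insert_mean,insert_sd fragment length distribution (bp).
#' @param snp_rate,indel_rate per-bp haplotype variant rates.
#' @param indel_geom geometric length parameter for indels.
#' @param error_rate per-base sequencing substitution error rate.
#' @param base_qual constant base quality (phred).
#' @param target_divergence substitutions/bp of planted polymorphic Alus
#'   from their consensus.
#' @param decoy_divergence range of decoy divergence from consensus.
#' @param chrom chromosome name.
#' @param sample_prefix prefix for sample names.
#' @param map_alu_mates how reads fully inside an inserted Alu are emitted:
#'   \code{"decoy"} maps them to a decoy copy (what an aligner does with a
#'   repetitive read), \code{"unmapped"} leaves them unmapped with a mapped
#'   mate.
#' @param seed integer seed governing every random draw.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(mode = c("SimDel", "SimIns"), ref_length = 1e6,
                       n_loci = 100L, n_decoys = 40L, min_spacing = 600L,
                       n_haplotypes = 200L, coverage = 25, read_len = 100L,
                       insert_mean = 400, insert_sd = 40, snp_rate = 1e-3,
                       indel_rate = 1e-4, indel_geom = 0.7,
                       error_rate = 1e-3, base_qual = 35L,
                       target_divergence = 0.02,
                       decoy_divergence = c(0.05, 0.15), chrom = "chrS",
                       sample_prefix = "ind", map_alu_mates = c("decoy",
                                                                "unmapped"),
                       seed = 1L) {
  mode <- match.arg(mode)
  map_alu_mates <- match.arg(map_alu_mates)
  if (n_haplotypes %% 2 != 0) stop("n_haplotypes must be even")
  cfg <- list(mode = mode, ref_length = as.integer(ref_length),
              n_loci = as.integer(n_loci), n_decoys = as.integer(n_decoys),
              min_spacing = as.integer(min_spacing),
              n_haplotypes = as.integer(n_haplotypes), coverage = coverage,
              read_len = as.integer(read_len), insert_mean = insert_mean,
              insert_sd = insert_sd, snp_rate = snp_rate,
              indel_rate = indel_rate, indel_geom = indel_geom,
              error_rate = error_rate, base_qual = as.integer(base_qual),
              target_divergence = target_divergence,
              decoy_divergence = decoy_divergence, chrom = chrom,
              sample_prefix = sample_prefix, map_alu_mates = map_alu_mates,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Build the simulated reference and Alu placement
#'
#' Generates a seeded random background, plants \code{n_decoys} diverged
#' decoy Alu copies and \code{n_loci} polymorphic target Alus with at least
#' \code{min_spacing} bp between any two elements, and writes the working
#' reference FASTA plus target and decoy BED files. In SimIns mode the
#' working reference contains only the decoys; targets collapse to their
#' insertion points (AL == AR).
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @param panel Alu consensus panel.
#' @return list of class \code{alu_sim_ref} with the working reference
#'   (DNAStringSet and FASTA path), target and decoy tables, and BED paths.
#' @export
make_reference <- function(cfg, dir = tempfile("simref"),
                           panel = load_alu_panel()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  n_sites <- cfg$n_loci + cfg$n_decoys
  max_alu <- max(Biostrings::width(panel)) + 5L
  gap <- cfg$min_spacing + max_alu
  margin <- 2L * (cfg$min_spacing + 200L)
  avail <- cfg$ref_length - 2 * margin - n_sites * gap
  if (avail <= 0)
    stop("placement infeasible: reference too short for ", n_sites,
         " Alu sites with ", cfg$min_spacing, " bp spacing")
  bg <- random_dna(cfg$ref_length)
  x <- sort(runif(n_sites, 0, avail))
  pos_bg <- as.integer(round(margin + x + (seq_len(n_sites) - 1L) * gap))
  is_target <- rep(FALSE, n_sites)
  is_target[sort(sample.int(n_sites, cfg$n_loci))] <- TRUE
  fam <- sample(names(panel), n_sites, replace = TRUE)
  div <- ifelse(is_target, cfg$target_divergence,
                runif(n_sites, cfg$decoy_divergence[1], cfg$decoy_divergence[2]))
  seqs <- vapply(seq_len(n_sites), function(i)
    mutate_dna(as.character(panel[[fam[i]]]), div[i]), character(1))

  insert_all <- cfg$mode == "SimDel"
  present <- if (insert_all) rep(TRUE, n_sites) else !is_target
  lens <- nchar(seqs)
  offset <- c(0, cumsum(ifelse(present, lens, 0L)))[seq_len(n_sites)]
  work_start <- pos_bg + as.integer(offset)   # 0-based on working reference

  pieces <- character(0)
  prev <- 0L
  for (i in seq_len(n_sites)) {
    pieces <- c(pieces, substr(bg, prev + 1L, pos_bg[i]))
    if (present[i]) pieces <- c(pieces, seqs[i])
    prev <- pos_bg[i]
  }
  pieces <- c(pieces, substr(bg, prev + 1L, cfg$ref_length))
  working <- paste(pieces, collapse = "")

  targets <- data.frame(
    chrom = cfg$chrom,
    AL = work_start[is_target],
    AR = work_start[is_target] + if (insert_all) lens[is_target] else 0L,
    name = sprintf("aluT%03d", seq_len(cfg$n_loci)),
    family = fam[is_target], seq = seqs[is_target],
    stringsAsFactors = FALSE)
  targets$l_alu <- nchar(targets$seq)
  decoys <- data.frame(
    chrom = cfg$chrom,
    AL = work_start[!is_target],
    AR = work_start[!is_target] + lens[!is_target],
    name = sprintf("aluD%03d", seq_len(cfg$n_decoys)),
    family = fam[!is_target],
    stringsAsFactors = FALSE)

  ref <- Biostrings::DNAStringSet(setNames(working, cfg$chrom))
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(ref, fasta)
  Rsamtools::indexFa(fasta)
  target_bed <- file.path(dir, "alu_targets.bed")
  decoy_bed <- file.path(dir, "alu_decoys.bed")
  write_bed <- function(df, path) {
    write.table(data.frame(df$chrom, df$AL, pmax(df$AR, df$AL + 1L), df$name),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  write_bed(targets, target_bed)
  write_bed(decoys, decoy_bed)
  structure(list(cfg = cfg, dir = dir, fasta = fasta, reference = ref,
                 targets = targets, decoys = decoys,
                 target_bed = target_bed, decoy_bed = decoy_bed),
            class = "alu_sim_ref")
}

#' Draw a truth population over the simulated loci
#'
#' Each locus receives a frequency p ~ U(0,1); every haplotype carries the
#' event independently with probability p; consecutive haplotype pairs form
#' diploid individuals. SNPs and small indels are injected per haplotype at
#' the configured rates.
#'
#' @param simref from [make_reference()].
#' @param cfg the same [sim_config()].
#' @return list of class \code{alu_truth}: locus frequencies, per-haplotype
#'   carrier matrix, per-individual genotype (event dosage) matrix, sample
#'   names, and per-haplotype variant tables.
#' @export
simulate_population <- function(simref, cfg = simref$cfg) {
  set.seed(cfg$seed + 1L)
  n_hap <- cfg$n_haplotypes
  n_ind <- n_hap %/% 2L
  n_loci <- nrow(simref$targets)
  freqs <- runif(n_loci)
  carry <- matrix(rbinom(n_hap * n_loci, 1L, rep(freqs, each = n_hap)),
                  nrow = n_hap)
  genotypes <- carry[seq(1, n_hap, 2), , drop = FALSE] +
    carry[seq(2, n_hap, 2), , drop = FALSE]
  samples <- sprintf("%s%03d", cfg$sample_prefix, seq_len(n_ind))
  dimnames(genotypes) <- list(samples, simref$targets$name)
  L <- cfg$ref_length_working <- Biostrings::width(simref$reference)[1]
  bases <- c("A", "C", "G", "T")
  variants <- lapply(seq_len(n_hap), function(h) {
    n_snp <- rbinom(1, L, cfg$snp_rate)
    snp_pos <- sort(sample.int(L, n_snp)) - 1L
    snp_alt <- sample(bases, n_snp, replace = TRUE)
    n_ind_ <- rbinom(1, L, cfg$indel_rate)
    ind_pos <- sort(sample.int(L, n_ind_)) - 1L
    ind_len <- rgeom(n_ind_, cfg$indel_geom) + 1L
    ind_ins <- runif(n_ind_) < 0.5
    ind_seq <- vapply(seq_len(n_ind_), function(i)
      if (ind_ins[i]) paste(sample(bases, ind_len[i], replace = TRUE),
                            collapse = "") else "", character(1))
    list(snp = data.frame(pos = snp_pos, alt = snp_alt,
                          stringsAsFactors = FALSE),
         indel = data.frame(pos = ind_pos, len = ind_len, ins = ind_ins,
                            seq = ind_seq, stringsAsFactors = FALSE))
  })
  structure(list(freqs = freqs, carry = carry, genotypes = genotypes,
                 samples = samples, variants = variants, mode = cfg$mode),
            class = "alu_truth")
}

# blocks of one haplotype: data.frame(type, hap_start, len, ref_start, big,
# locus) in haplotype order; ref gaps appear implicitly between ref blocks
haplotype_blocks <- function(simref, truth, hap, cfg = simref$cfg) {
  tg <- simref$targets
  carried <- which(truth$carry[hap, ] == 1L)
  v <- truth$variants[[hap]]
  ev <- data.frame(pos = integer(), end = integer(), ins_seq = character(),
                   big = logical(), locus = integer(),
                   stringsAsFactors = FALSE)
  if (cfg$mode == "SimDel" && length(carried)) {
    ev <- rbind(ev, data.frame(pos = tg$AL[carried], end = tg$AR[carried],
                               ins_seq = "", big = TRUE, locus = carried,
                               stringsAsFactors = FALSE))
  }
  if (cfg$mode == "SimIns" && length(carried)) {
    ev <- rbind(ev, data.frame(pos = tg$AL[carried], end = tg$AL[carried],
                               ins_seq = tg$seq[carried], big = TRUE,
                               locus = carried, stringsAsFactors = FALSE))
  }
  if (nrow(v$indel)) {
    ins <- v$indel$ins
    ev <- rbind(ev, data.frame(
      pos = v$indel$pos,
      end = ifelse(ins, v$indel$pos, v$indel$pos + v$indel$len),
      ins_seq = ifelse(ins, v$indel$seq, ""),
      big = FALSE, locus = NA_integer_, stringsAsFactors = FALSE))
  }
  ev <- ev[order(ev$pos), , drop = FALSE]
  # drop small events that fall inside or straddle a big event
  if (nrow(ev) > 1) {
    bigs <- ev[ev$big, , drop = FALSE]
    if (nrow(bigs)) {
      bad <- !ev$big & vapply(seq_len(nrow(ev)), function(i)
        any(ev$pos[i] < bigs$end + 5L & ev$end[i] > bigs$pos - 5L),
        logical(1))
      ev <- ev[!bad, , drop = FALSE]
    }
  }
  L <- Biostrings::width(simref$reference)[1]
  type <- character(0); ref_start <- integer(0); len <- integer(0)
  big <- logical(0); locus <- integer(0); ins_seq <- character(0)
  cur <- 0L
  add <- function(t, rs, l, b, lo, sq) {
    type <<- c(type, t); ref_start <<- c(ref_start, rs); len <<- c(len, l)
    big <<- c(big, b); locus <<- c(locus, lo); ins_seq <<- c(ins_seq, sq)
  }
  for (i in seq_len(nrow(ev))) {
    if (ev$pos[i] < cur) next  # overlapping events: keep the first
    if (ev$pos[i] > cur)
      add("ref", cur, ev$pos[i] - cur, FALSE, NA_integer_, "")
    if (nzchar(ev$ins_seq[i]))
      add("ins", NA_integer_, nchar(ev$ins_seq[i]), ev$big[i], ev$locus[i],
          ev$ins_seq[i])
    cur <- ev$end[i]
  }
  if (cur < L) add("ref", cur, L - cur, FALSE, NA_integer_, "")
  hap_start <- c(0L, cumsum(len))[seq_along(len)]
  data.frame(type = type, hap_start = hap_start, len = len,
             ref_start = ref_start, big = big, locus = locus,
             ins_seq = ins_seq, stringsAsFactors = FALSE)
}

# haplotype sequence (character) from its blocks and the SNP-substituted
# working reference string
haplotype_sequence <- function(schar, blocks) {
  pieces <- ifelse(blocks$type == "ref",
                   substring(schar, blocks$ref_start + 1L,
                             blocks$ref_start + blocks$len),
                   blocks$ins_seq)
  paste(pieces, collapse = "")
}

# convert a blocks data.frame to a plain list of vectors (fast access in
# the per-read mapping loop)
blocks_env <- function(blocks) {
  list(hap_start = blocks$hap_start, len = blocks$len,
       is_ref = blocks$type == "ref", ref_start = blocks$ref_start,
       big = blocks$big, locus = blocks$locus)
}

# Map one read (0-based haplotype begin, length rl) through the block list.
# Returns list(pos0, cigar, mapped, decoy_block) where decoy_block is the
# block index when the read lies fully inside a big insertion.
map_read_blocks <- function(bl, h_begin, rl, small_max = 40L) {
  h_end <- h_begin + rl
  bi <- findInterval(h_begin, bl$hap_start)
  pieces <- list()
  pos <- h_begin
  while (pos < h_end) {
    take <- min(bl$hap_start[bi] + bl$len[bi], h_end) - pos
    pieces[[length(pieces) + 1]] <-
      list(block = bi, off = pos - bl$hap_start[bi], len = take)
    pos <- pos + take
    bi <- bi + 1L
  }
  # read fully inside one block
  if (length(pieces) == 1) {
    b <- pieces[[1]]$block
    if (bl$is_ref[b]) {
      return(list(pos0 = bl$ref_start[b] + pieces[[1]]$off,
                  cigar = paste0(rl, "M"), mapped = TRUE, decoy_block = NA))
    }
    return(list(pos0 = NA, cigar = "*", mapped = FALSE,
                decoy_block = if (bl$big[b]) b else NA))
  }
  # does the read cross a big junction? (big ins block or big ref gap)
  seg <- lapply(pieces, function(p) {
    b <- p$block
    list(ref = bl$is_ref[b],
         ref_pos = if (bl$is_ref[b]) bl$ref_start[b] + p$off else NA,
         len = p$len, big = !bl$is_ref[b] && bl$big[b])
  })
  gaps <- integer(length(seg))  # ref gap preceding segment k
  for (k in seq_along(seg)[-1]) {
    if (seg[[k]]$ref && seg[[k - 1]]$ref)
      gaps[k] <- seg[[k]]$ref_pos - (seg[[k - 1]]$ref_pos + seg[[k - 1]]$len)
  }
  big_break <- vapply(seg, `[[`, logical(1), "big") | gaps > small_max
  if (any(big_break)) {
    j <- which(big_break)[1]
    left <- seg[seq_len(j - 1L)]
    ri <- if (seg[[j]]$big) j + 1L else j
    right <- if (ri <= length(seg)) seg[ri:length(seg)] else list()
    lm <- sum(vapply(left, function(s) if (s$ref) s$len else 0L, numeric(1)))
    rm <- sum(vapply(right, function(s) if (s$ref) s$len else 0L, numeric(1)))
    if (lm == 0 && rm == 0)
      return(list(pos0 = NA, cigar = "*", mapped = FALSE, decoy_block = NA))
    if (lm >= rm) {
      anchor <- left; clip <- rl - sum(vapply(left, `[[`, numeric(1), "len"))
      cig <- segs_to_cigar(anchor, small_max)
      return(list(pos0 = cig$pos0, cigar = paste0(cig$cigar, clip, "S"),
                  mapped = TRUE, decoy_block = NA))
    } else {
      anchor <- right
      clip <- rl - sum(vapply(right, `[[`, numeric(1), "len"))
      cig <- segs_to_cigar(anchor, small_max)
      return(list(pos0 = cig$pos0, cigar = paste0(clip, "S", cig$cigar),
                  mapped = TRUE, decoy_block = NA))
    }
  }
  cig <- segs_to_cigar(seg, small_max)
  list(pos0 = cig$pos0, cigar = cig$cigar, mapped = TRUE, decoy_block = NA)
}

# build a CIGAR from contiguous segments (small events only); leading or
# trailing insertion segments become soft clips
segs_to_cigar <- function(seg, small_max) {
  ops <- character(0); lens <- integer(0); pos0 <- NA
  push <- function(op, l) {
    if (l <= 0) return()
    n <- length(ops)
    if (n && ops[n] == op) lens[n] <<- lens[n] + l
    else { ops <<- c(ops, op); lens <<- c(lens, l) }
  }
  prev_ref_end <- NA
  for (s in seg) {
    if (s$ref) {
      if (is.na(pos0)) pos0 <- s$ref_pos
      if (!is.na(prev_ref_end)) push("D", s$ref_pos - prev_ref_end)
      push("M", s$len)
      prev_ref_end <- s$ref_pos + s$len
    } else {
      push(if (is.na(pos0)) "S" else "I", s$len)
    }
  }
  # trailing insertion becomes a soft clip
  n <- length(ops)
  if (n && ops[n] == "I") ops[n] <- "S"
  list(pos0 = pos0, cigar = paste0(lens, ops, collapse = ""))
}

#' Simulate truth-aware alignments for every individual
#'
#' Draws fragments uniformly along each haplotype with insert lengths
#' Normal(mean, sd) truncated above 2x read length, maps each read back to
#' working-reference coordinates through the haplotype's variant blocks
#' (small indels become I/D CIGAR operations, reads crossing an Alu
#' junction are soft-clipped on the shorter side, reads fully inside an
#' inserted Alu map to a decoy copy or stay unmapped), injects base errors,
#' and writes one sorted, indexed BAM per individual.
#'
#' @param simref from [make_reference()].
#' @param truth from [simulate_population()].
#' @param dir output directory for BAMs.
#' @param cfg the [sim_config()].
#' @return character vector of BAM paths, one per individual.
#' @export
simulate_alignments <- function(simref, truth, dir = simref$dir,
                                cfg = simref$cfg) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed + 2L)
  refdna <- simref$reference[[1]]
  L <- length(refdna)
  chrom <- cfg$chrom
  rl <- cfg$read_len
  qual <- strrep(rawToChar(as.raw(33L + cfg$base_qual)), rl)
  n_ind <- length(truth$samples)
  decoys <- simref$decoys
  bams <- character(n_ind)
  for (ind in seq_len(n_ind)) {
    rows <- list()
    for (hp in 1:2) {
      hap <- 2L * (ind - 1L) + hp
      v <- truth$variants[[hap]]
      schar <- {
        if (nrow(v$snp)) {
          at <- v$snp$pos + 1L
          cur <- substring(as.character(refdna), at, at)
          alt <- v$snp$alt
          same <- alt == cur
          if (any(same))
            alt[same] <- vapply(cur[same], function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
          as.character(Biostrings::replaceLetterAt(refdna, at, alt))
        } else as.character(refdna)
      }
      blocks <- haplotype_blocks(simref, truth, hap, cfg)
      bl <- blocks_env(blocks)
      hseq <- haplotype_sequence(schar, blocks)
      Lh <- nchar(hseq)
      n_frag <- round(cfg$coverage / 2 * Lh / (2 * rl))
      fl <- pmax(2L * rl + 10L,
                 as.integer(round(rnorm(n_frag, cfg$insert_mean,
                                        cfg$insert_sd))))
      start0 <- as.integer(floor(runif(n_frag) * (Lh - fl)))
      keep <- start0 >= 0 & start0 + fl <= Lh
      start0 <- start0[keep]; fl <- fl[keep]
      n_frag <- length(start0)
      hb <- c(start0, start0 + fl - rl)          # left reads then right reads
      is_right <- rep(c(FALSE, TRUE), each = n_frag)
      # fast path: read entirely within one ref block
      b1 <- findInterval(hb, bl$hap_start)
      b2 <- findInterval(hb + rl - 1L, bl$hap_start)
      simple <- b1 == b2 & bl$is_ref[b1]
      pos0 <- rep(NA_integer_, length(hb))
      cigar <- rep("*", length(hb))
      mapped <- rep(FALSE, length(hb))
      decoy_block <- rep(NA_integer_, length(hb))
      pos0[simple] <- bl$ref_start[b1[simple]] +
        (hb[simple] - bl$hap_start[b1[simple]])
      cigar[simple] <- paste0(rl, "M")
      mapped[simple] <- TRUE
      for (i in which(!simple)) {
        m <- map_read_blocks(bl, hb[i], rl)
        pos0[i] <- if (is.na(m$pos0)) NA_integer_ else as.integer(m$pos0)
        cigar[i] <- m$cigar
        mapped[i] <- m$mapped
        decoy_block[i] <- if (is.na(m$decoy_block)) NA_integer_
                          else as.integer(m$decoy_block)
      }
      mapq <- rep(60L, length(hb))
      # reads fully inside an inserted Alu: decoy remap or unmapped
      din <- which(!is.na(decoy_block))
      if (length(din)) {
        if (cfg$map_alu_mates == "decoy" && nrow(decoys)) {
          for (i in din) {
            b <- decoy_block[i]
            fam_b <- simref$targets$family[bl$locus[b]]
            famd <- decoys[decoys$family %in% fam_b, , drop = FALSE]
            famd <- if (nrow(famd)) famd else decoys
            d <- famd[sample.int(nrow(famd), 1L), ]
            off <- hb[i] - bl$hap_start[b]
            pos0[i] <- d$AL + min(off, max(0L, (d$AR - d$AL) - rl))
            cigar[i] <- paste0(rl, "M")
            mapped[i] <- TRUE
            mapq[i] <- 30L
          }
        }
      }
      seqs <- substring(hseq, hb + 1L, hb + rl)
      rows[[hp]] <- data.frame(
        frag = rep(seq_len(n_frag), 2), hp = hp, is_right = is_right,
        pos0 = pos0, cigar = cigar, mapped = mapped, mapq = mapq,
        seq = seqs, stringsAsFactors = FALSE)
    }
    bams[ind] <- write_individual_bam(rows, truth$samples[ind], chrom, L,
                                      cfg, dir, qual)
  }
  bams
}

# vectorized uniform substitution errors: one pass per error rank
inject_errors <- function(seqs, rl, rate) {
  nerr <- rbinom(length(seqs), rl, rate)
  bases <- c("A", "C", "G", "T")
  k <- 1L
  while (any(nerr >= k)) {
    i <- which(nerr >= k)
    p <- sample.int(rl, length(i), replace = TRUE)
    cur <- substr(seqs[i], p, p)
    shift <- sample.int(3L, length(i), replace = TRUE)
    new <- bases[((match(cur, bases) - 1L + shift) %% 4L) + 1L]
    new[is.na(new)] <- "N"
    substr(seqs[i], p, p) <- new
    k <- k + 1L
  }
  seqs
}

# assemble SAM records for one individual and write sorted+indexed BAM
write_individual_bam <- function(rows, sample, chrom, chrom_len, cfg, dir,
                                 qual) {
  rl <- cfg$read_len
  recs <- list()
  for (hp in 1:2) {
    d <- rows[[hp]]
    n_frag <- max(d$frag)
    left <- d[!d$is_right, ]; right <- d[d$is_right, ]
    left$seq <- inject_errors(left$seq, rl, cfg$error_rate)
    right$seq <- inject_errors(right$seq, rl, cfg$error_rate)
    both <- left$mapped & right$mapped
    endL <- endR <- rep(NA_integer_, nrow(left))
    endL[left$mapped] <- left$pos0[left$mapped] +
      cigar_ref_width(left$cigar[left$mapped])
    endR[right$mapped] <- right$pos0[right$mapped] +
      cigar_ref_width(right$cigar[right$mapped])
    lo <- pmin(left$pos0, right$pos0)
    hi <- pmax(endL, endR)
    tlen <- ifelse(both, hi - lo, 0L)
    w3 <- cfg$insert_mean + 3 * cfg$insert_sd
    proper <- both & (endR - left$pos0) > 0 & (endR - left$pos0) <= w3 &
      left$pos0 <= right$pos0
    proper[is.na(proper)] <- FALSE
    qn <- sprintf("%s_h%d_%d", sample, hp, left$frag)
    mk <- function(d, mate, first) {
      # flags: paired + proper + strand bits + mate strand + unmapped bits
      fl <- 1L + 2L * proper + 4L * (!d$mapped) + 8L * (!mate$mapped) +
        (if (first) 32L + 64L else 16L + 128L)
      pos <- d$pos0
      pos[!d$mapped] <- mate$pos0[!d$mapped]
      pos[is.na(pos)] <- 0L
      pnext <- mate$pos0
      pnext[!mate$mapped] <- pos[!mate$mapped]
      tl <- integer(length(pos))
      tl[both] <- (2L * (d$pos0[both] <= mate$pos0[both]) - 1L) * tlen[both]
      mapq <- d$mapq
      mapq[!d$mapped] <- 0L
      cig <- d$cigar
      cig[!d$mapped] <- "*"
      data.frame(qname = qn, flag = fl, pos0 = pos, mapq = mapq,
                 cigar = cig, pnext0 = pnext, tlen = tl, seq = d$seq,
                 ok = d$mapped | mate$mapped,
                 stringsAsFactors = FALSE)
    }
    recs[[2 * hp - 1]] <- mk(left, right, TRUE)
    recs[[2 * hp]] <- mk(right, left, FALSE)
  }
  recs <- do.call(rbind, recs)
  keep <- recs$ok & !is.na(recs$pos0) & recs$pos0 >= 0
  recs <- recs[keep, , drop = FALSE]
  recs <- recs[order(recs$pos0), , drop = FALSE]  # coordinate-sorted SAM
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len),
           sprintf("@RG\tID:%s\tSM:%s\tLB:%s.lib1", sample, sample, sample))
  rg <- paste0("RG:Z:", sample)
  lines <- paste(recs$qname, recs$flag, chrom, recs$pos0 + 1L, recs$mapq,
                 recs$cigar, "=", recs$pnext0 + 1L, recs$tlen, recs$seq,
                 qual, rg, sep = "\t")
  sam <- file.path(dir, paste0(sample, ".sam"))
  writeLines(c(hdr, lines), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, sample), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Run the full simulation: reference, population, truth VCF, alignments
#'
#' @param cfg a [sim_config()].
#' @param dir output directory.
#' @param panel Alu consensus panel.
#' @return list with paths (\code{fasta}, \code{alu_bed} = the annotation
#'   the caller should use, \code{target_bed}, \code{truth_vcf},
#'   \code{bams}) and the in-memory \code{simref} and \code{truth} objects.
#' @export
simulate_dataset <- function(cfg, dir = tempfile("aludata"),
                             panel = load_alu_panel()) {
  simref <- make_reference(cfg, dir, panel)
  truth <- simulate_population(simref, cfg)
  truth_vcf <- file.path(dir, "truth.vcf")
  write_truth_vcf(simref, truth, truth_vcf)
  bams <- simulate_alignments(simref, truth, dir, cfg)
  list(fasta = simref$fasta,
       alu_bed = if (cfg$mode == "SimDel") simref$target_bed
                 else simref$decoy_bed,
       target_bed = simref$target_bed, decoy_bed = simref$decoy_bed,
       truth_vcf = truth_vcf, bams = bams, simref = simref, truth = truth,
       cfg = cfg)
}

#' @export
print.alu_truth <- function(x, ...) {
  het <- rowSums(x$genotypes == 1L)
  hom <- rowSums(x$genotypes == 2L)
  cat(sprintf("Simulated truth (%s): %d loci x %d individuals\n", x$mode,
              ncol(x$genotypes), nrow(x$genotypes)))
  cat(sprintf("  heterozygotes per individual: mean %.2f (min %d, max %d)\n",
              mean(het), min(het), max(het)))
  cat(sprintf("  homozygotes per individual:   mean %.2f (min %d, max %d)\n",
              mean(hom), min(hom), max(hom)))
  invisible(x)
}
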