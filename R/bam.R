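# BAM scanning helpers -----------------------------------------------------

.bam_what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
               "mpos", "isize", "seq", "qual", "qwidth")

# scan primary mapped records, optionally restricted to a region
# (0-based half-open begin/end); returns a plain data.frame
scan_reads <- function(bam, chrom = NULL, begin = NULL, end = NULL) {
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  if (is.null(chrom)) {
    param <- Rsamtools::ScanBamParam(flag = flag, what = .bam_what, tag = "RG")
  } else {
    which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(begin + 1L, end))
    param <- Rsamtools::ScanBamParam(flag = flag, what = .bam_what,
                                     tag = "RG", which = which)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  tags <- lapply(res, function(r) {
    rg <- r$tag$RG
    if (is.null(rg)) rep(NA_character_, length(r$qname)) else as.character(rg)
  })
  res <- if (length(res) == 1) res[[1]] else {
    nm <- setdiff(names(res[[1]]), "tag")
    setNames(lapply(nm, function(f) {
      if (f == "seq" || f == "qual") do.call(c, lapply(res, `[[`, f))
      else unlist(lapply(res, `[[`, f), use.names = FALSE)
    }), nm)
  }
  rg <- unlist(tags, use.names = FALSE)
  n <- length(res$qname)
  if (n == 0) return(empty_read_df())
  fl <- res$flag
  cig <- as.character(res$cigar)
  clips <- cigar_clips(cig)
  data.frame(qname = res$qname, flag = fl, rg = rg,
             chrom = as.character(res$rname),
             pos0 = res$pos - 1L,
             end0 = res$pos - 1L + cigar_ref_width(cig),
             strand = ifelse(bitwAnd(fl, 16L) > 0L, "-", "+"),
             mapq = res$mapq, cigar = cig,
             mrnm = as.character(res$mrnm), mpos0 = res$mpos - 1L,
             isize = res$isize, qwidth = res$qwidth,
             seq = as.character(res$seq), qual = as.character(res$qual),
             clipL = clips[, "left"], clipR = clips[, "right"],
             proper = bitwAnd(fl, 2L) > 0L,
             mate_rev = bitwAnd(fl, 32L) > 0L,
             mate_unmapped = bitwAnd(fl, 8L) > 0L,
             first = bitwAnd(fl, 64L) > 0L,
             stringsAsFactors = FALSE)
}

empty_read_df <- function() {
  data.frame(qname = character(), flag = integer(), rg = character(),
             chrom = character(),
             pos0 = integer(), end0 = integer(), strand = character(),
             mapq = integer(), cigar = character(), mrnm = character(),
             mpos0 = integer(), isize = integer(), qwidth = integer(),
             seq = character(), qual = character(), clipL = integer(),
             clipR = integer(), proper = logical(), mate_rev = logical(),
             mate_unmapped = logical(), first = logical(),
             stringsAsFactors = FALSE)
}

# scan unmapped records whose mate is mapped (for --unmapped-mates mode)
scan_unmapped_mates <- function(bam) {
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = TRUE, hasUnmappedMate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("qname", "seq", "mrnm", "mpos"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  data.frame(qname = res$qname, seq = as.character(res$seq),
             mrnm = as.character(res$mrnm), mpos0 = res$mpos - 1L,
             stringsAsFactors = FALSE)
}

bam_chrom_lengths <- function(bam) {
  Rsamtools::scanBamHeader(bam)[[1]]$targets
}

bam_sample_name <- function(bam) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$text
  rgs <- hdr[names(hdr) == "@RG"]
  for (f in rgs) {
    sm <- grep("^SM:", f, value = TRUE)
    if (length(sm)) return(sub("^SM:", "", sm[1]))
  }
  sub("\\.bam$", "", basename(bam))
}

# attach a 'lib' column mapping each read's RG tag to its library
assign_lib <- function(reads, rg2lib = character(0)) {
  lib <- rep("default", nrow(reads))
  if (length(rg2lib) && nrow(reads)) {
    m <- rg2lib[reads$rg]
    lib[!is.na(m)] <- m[!is.na(m)]
  }
  reads$lib <- lib
  reads
}

# model-based concordance for a table of reads (vectorized); mate interval
# is approximated as [mpos0, mpos0 + qwidth)
reads_concordant <- function(reads, model) {
  w <- flank_width(model)
  same <- !is.na(reads$mrnm) & reads$mrnm == reads$chrom & !reads$mate_unmapped
  opp <- (reads$strand == "-") != reads$mate_rev  # opposite strands
  # forward mate leftmost: for the forward read pos <= mpos, for reverse >=
  fwd_left <- ifelse(reads$strand == "+", reads$pos0 <= reads$mpos0,
                     reads$pos0 >= reads$mpos0)
  y <- abs(reads$isize)
  same & opp & fwd_left & !is.na(y) & y > 0 & y <= w
}
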