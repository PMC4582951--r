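# VCF output and input -----------------------------------------------------
#
# Calls and truth sets are written directly as VCF 4.2 text (full control
# over the SV INFO/FORMAT fields, byte-identical across runs); files are
# read back through VariantAnnotation.

vcf_header <- function(chroms, chrom_lens, samples, type, params = NULL) {
  c("##fileformat=VCFv4.2",
    "##source=aluscan",
    sprintf("##contig=<ID=%s,length=%d>", chroms, chrom_lens),
    "##ALT=<ID=DEL,Description=\"Alu deletion relative to the reference\">",
    "##ALT=<ID=INS,Description=\"Alu insertion absent from the reference\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the event\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed event length\">",
    "##INFO=<ID=AL,Number=1,Type=Integer,Description=\"Left breakpoint (1-based)\">",
    "##INFO=<ID=AR,Number=1,Type=Integer,Description=\"Right breakpoint (1-based)\">",
    "##INFO=<ID=TSD,Number=1,Type=Integer,Description=\"Target-site duplication length\">",
    "##INFO=<ID=FAM,Number=1,Type=String,Description=\"Best-matching Alu family\">",
    "##INFO=<ID=SUP,Number=1,Type=Integer,Description=\"Pooled discordant support\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled likelihoods\">",
    "##FORMAT=<ID=EV,Number=3,Type=Integer,Description=\"Evidence counts: internal, split, across\">",
    if (!is.null(params))
      sprintf("##aluscan_params=%s",
              paste(names(params), unlist(params), sep = "=", collapse = ";")),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

gt_string <- function(dosage) {
  ifelse(is.na(dosage), "./.", c("0/0", "0/1", "1/1")[dosage + 1L])
}

#' Write a multi-sample call set to VCF 4.2
#'
#' One record per locus with SVTYPE, END, SVLEN (deletions) or AL/AR, TSD
#' and Alu family (insertions); per-sample GT (event-allele dosage), GQ,
#' phred-scaled likelihoods and evidence counts.
#'
#' @param calls an \code{alu_calls} object.
#' @param path output file.
#' @param chrom_lens named vector of chromosome lengths.
#' @param params optional named list recorded in the header.
#' @return \code{path}, invisibly.
#' @export
write_calls_vcf <- function(calls, path, chrom_lens, params = NULL) {
  loci <- calls$loci
  chroms <- unique(loci$chrom)
  if (is.null(names(chrom_lens))) names(chrom_lens) <- chroms
  hdr <- vcf_header(chroms, chrom_lens[chroms], calls$samples, calls$type,
                    params)
  lines <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (calls$type == "DEL") {
      pos1 <- loci$AL[i] + 1L
      info <- sprintf("SVTYPE=DEL;END=%d;SVLEN=-%d", loci$AR[i],
                      loci$l_alu[i])
      id <- loci$name[i]
    } else {
      pos1 <- loci$pos[i] + 1L
      info <- paste0("SVTYPE=INS",
                     if (!is.na(loci$AL[i]))
                       sprintf(";AL=%d", loci$AL[i] + 1L) else "",
                     if (!is.na(loci$AR[i]))
                       sprintf(";AR=%d", loci$AR[i] + 1L) else "",
                     sprintf(";TSD=%d", loci$tsd_len[i]),
                     if (!is.na(loci$family[i]))
                       sprintf(";FAM=%s", loci$family[i]) else "",
                     sprintf(";SUP=%d", loci$support[i]))
      id <- loci$name[i]
    }
    fmt <- vapply(seq_along(calls$samples), function(s) {
      sprintf("%s:%d:%s:%s", gt_string(calls$genotype[i, s]),
              calls$gq[i, s] %||% 0L,
              paste(calls$pl[i, s, ], collapse = ","),
              paste(c(calls$n_I[i, s], calls$n_S[i, s], calls$n_A[i, s]),
                    collapse = ","))
    }, character(1))
    alt <- if (calls$type == "DEL") "<DEL>" else "<INS>"
    lines[i] <- paste(c(loci$chrom[i], pos1, id, "N", alt, ".", "PASS",
                        info, "GT:GQ:PL:EV", fmt), collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write the simulated truth set to VCF
#'
#' @param simref from [make_reference()].
#' @param truth from [simulate_population()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_truth_vcf <- function(simref, truth, path) {
  tg <- simref$targets
  chrom_lens <- setNames(Biostrings::width(simref$reference),
                         names(simref$reference))
  hdr <- vcf_header(unique(tg$chrom), chrom_lens[unique(tg$chrom)],
                    truth$samples, truth$mode)
  is_del <- truth$mode == "SimDel"
  lines <- character(nrow(tg))
  for (i in seq_len(nrow(tg))) {
    info <- if (is_del)
      sprintf("SVTYPE=DEL;END=%d;SVLEN=-%d", tg$AR[i], tg$l_alu[i])
    else sprintf("SVTYPE=INS;SVLEN=%d;FAM=%s", tg$l_alu[i], tg$family[i])
    gts <- gt_string(truth$genotypes[, i])
    lines[i] <- paste(c(tg$chrom[i], tg$AL[i] + 1L, tg$name[i], "N",
                        if (is_del) "<DEL>" else "<INS>", ".", "PASS",
                        info, "GT", gts), collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read genotype dosages from a VCF written by this package
#'
#' @param path VCF file.
#' @return list with \code{loci} (chrom, pos0, name, svtype) and
#'   \code{dosage} (loci x samples matrix; 0/1/2 event-allele copies, NA for
#'   no-calls).
#' @export
read_genotype_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
  dosage[gt == "0/0"] <- 0L
  dosage[gt == "0/1" | gt == "1/0"] <- 1L
  dosage[gt == "1/1"] <- 2L
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  loci <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos0 = GenomicRanges::start(rr) - 1L,
                     name = names(rr),
                     svtype = as.character(info$SVTYPE),
                     stringsAsFactors = FALSE)
  list(loci = loci, dosage = dosage)
}
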