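# Alu loci and analysis windows -------------------------------------------

#' Read an Alu annotation from BED
#'
#' Expects BED3+ (chrom, start, end, optional name); coordinates are kept
#' 0-based half-open internally.
#'
#' @param path BED file.
#' @return data.frame with columns chrom, AL, AR, name, l_alu.
#' @export
read_alu_bed <- function(path) {
  if (!file.exists(path)) stop("Alu annotation not found: ", path)
  if (file.size(path) == 0 ||
        length(readLines(path, n = 1L, warn = FALSE)) == 0) {
    return(data.frame(chrom = character(), AL = integer(), AR = integer(),
                      name = character(), l_alu = integer(),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm))) nm <- paste0("alu_", seq_along(gr))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    AL = GenomicRanges::start(gr) - 1L,
                    AR = GenomicRanges::end(gr),
                    name = nm, stringsAsFactors = FALSE)
  out$l_alu <- out$AR - out$AL
  if (any(out$l_alu <= 0)) stop("malformed Alu annotation: start >= end")
  out
}

#' Alu locus record
#'
#' @param chrom chromosome.
#' @param AL,AR left/right breakpoint, 0-based half-open.
#' @param name locus name.
#' @return one-row data.frame with l_alu = AR - AL.
#' @export
alu_locus <- function(chrom, AL, AR, name = "alu") {
  stopifnot(AL < AR)
  data.frame(chrom = chrom, AL = AL, AR = AR, name = name, l_alu = AR - AL,
             stringsAsFactors = FALSE)
}

#' Build the analysis window around an Alu locus
#'
#' Flanks of width \code{round(E[Y] + 3*sd(Y))} are added on both sides of
#' the annotated element and clipped at the chromosome bounds:
#' \code{FL = AL - w}, \code{FR = AR + w}.
#'
#' @param locus one-row data.frame from [alu_locus()] or [read_alu_bed()].
#' @param model an \code{insert_model} (or an integer flank width).
#' @param chrom_len chromosome length for clipping (bp), or \code{Inf}.
#' @return list with locus fields plus FL, FR and the width w.
#' @export
build_window <- function(locus, model, chrom_len = Inf) {
  w <- if (is.numeric(model)) as.integer(round(model)) else flank_width(model)
  FL <- max(0L, as.integer(locus$AL) - w)
  FR <- as.integer(min(chrom_len, locus$AR + w))
  list(chrom = locus$chrom, AL = as.integer(locus$AL), AR = as.integer(locus$AR),
       l_alu = as.integer(locus$AR - locus$AL), name = locus$name,
       FL = FL, FR = FR, w = w)
}
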