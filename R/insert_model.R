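# Insert-length model (per-library empirical distribution) ----------------

#' Insert length of a read pair
#'
#' The insert length of a pair, measured on the reference, is the distance
#' from the start of the left read to the end of the right read:
#' \code{end_r - begin_l}. All coordinates are 0-based half-open.
#'
#' @param pair a read-pair record as returned by [read_pair()].
#' @return integer insert length in bp.
#' @export
insert_length <- function(pair) {
  if (isTRUE(pair$mate_unmapped) || pair$chrom_l != pair$chrom_r)
    stop("insert length undefined: mate unmapped or on a different chromosome")
  pair$end_r - pair$begin_l
}

#' Construct a read-pair record
#'
#' A lightweight container for the fields of an aligned paired-end fragment
#' used by the classification and likelihood code. Coordinates are 0-based
#' half-open; the left read is the mate with the smaller begin position.
#'
#' @param begin_l,end_l,begin_r,end_r mate coordinates (bp).
#' @param strand_l,strand_r \code{"+"} or \code{"-"}.
#' @param chrom_l,chrom_r chromosome of each mate.
#' @param proper_flag aligner's proper-pair flag (used before an insert model
#'   exists).
#' @param mate_unmapped is one mate unmapped?
#' @param library sequencing library (read-group LB).
#' @param pair_id fragment name.
#' @return a list of class \code{read_pair}.
#' @export
read_pair <- function(begin_l, end_l, begin_r, end_r,
                      strand_l = "+", strand_r = "-",
                      chrom_l = "chr1", chrom_r = chrom_l,
                      proper_flag = NA, mate_unmapped = FALSE,
                      library = "default", pair_id = "pair") {
  stopifnot(end_l >= begin_l || mate_unmapped,
            end_r >= begin_r || mate_unmapped)
  structure(list(begin_l = begin_l, end_l = end_l, begin_r = begin_r,
                 end_r = end_r, strand_l = strand_l, strand_r = strand_r,
                 chrom_l = chrom_l, chrom_r = chrom_r,
                 proper_flag = proper_flag, mate_unmapped = mate_unmapped,
                 library = library, pair_id = pair_id),
            class = "read_pair")
}

#' Classify a read pair as concordant or discordant
#'
#' A pair is concordant when both mates map to the same chromosome on
#' opposite strands with the forward mate leftmost, and the insert length is
#' positive and at most \eqn{E[Y] + 3\sigma(Y)}. When no insert-length model
#' is available yet (the bootstrap pass), the aligner's proper-pair flag is
#' used instead.
#'
#' @param pair a [read_pair()].
#' @param model an [insert_model] or \code{NULL}.
#' @return \code{"concordant"} or \code{"discordant"}.
#' @export
classify_concordance <- function(pair, model = NULL) {
  if (isTRUE(pair$mate_unmapped)) return("discordant")
  if (pair$chrom_l != pair$chrom_r) return("discordant")
  if (is.null(model)) {
    return(if (isTRUE(pair$proper_flag)) "concordant" else "discordant")
  }
  ok <- pair$strand_l == "+" && pair$strand_r == "-"
  if (!ok) return("discordant")
  y <- pair$end_r - pair$begin_l
  lib <- model_library(model, pair$library)
  if (y > 0 && y <= lib$mean + 3 * lib$sd) "concordant" else "discordant"
}

#' Build an insert-length model from observed insert lengths
#'
#' Estimates, per sequencing library, the mean and standard deviation of the
#' insert length Y and a smoothed empirical probability mass for Y: a
#' normalized 1-bp histogram over \code{[max(0, E-5s), E+5s]} with add-one
#' smoothing inside the support and a floor of \code{1e-6} outside it, so
#' outlying inserts never receive zero likelihood. A degenerate library with
#' \code{sd == 0} has its sd replaced by 1 bp so downstream windows stay
#' non-empty.
#'
#' @param lengths integer vector of insert lengths from concordant pairs.
#' @param library parallel vector of library names (recycled).
#' @param read_len modal read length of the sample (bp).
#' @param min_pairs minimum pairs required per library.
#' @return an object of class \code{insert_model}: per-library entries with
#'   \code{mean}, \code{sd}, \code{count} and the histogram density, plus
#'   pooled statistics used for flank widths.
#' @export
insert_model_from_lengths <- function(lengths, library = "default",
                                      read_len = 100L, min_pairs = 1000L) {
  stopifnot(length(lengths) > 0)
  library <- rep_len(as.character(library), length(lengths))
  libs <- list()
  for (lb in sort(unique(library))) {
    y <- as.numeric(lengths[library == lb])
    if (length(y) < min_pairs)
      stop(sprintf("library '%s': only %d concordant pairs (need >= %d)",
                   lb, length(y), min_pairs))
    m <- mean(y)
    s <- stats::sd(y)
    if (!is.finite(s) || s == 0) s <- 1
    lo <- max(0, floor(m - 5 * s))
    hi <- ceiling(m + 5 * s)
    inside <- y[y >= lo & y <= hi]
    cnt <- tabulate(round(inside) - lo + 1L, nbins = hi - lo + 1L)
    dens <- (cnt + 1) / (length(inside) + length(cnt))
    libs[[lb]] <- list(mean = m, sd = s, count = length(y),
                       lo = lo, hi = hi, dens = dens)
  }
  pooled_mean <- mean(as.numeric(lengths))
  pooled_sd <- stats::sd(as.numeric(lengths))
  if (!is.finite(pooled_sd) || pooled_sd == 0) pooled_sd <- 1
  structure(list(libraries = libs,
                 pooled = list(mean = pooled_mean, sd = pooled_sd),
                 read_len = as.integer(read_len),
                 floor = 1e-6),
            class = "insert_model")
}

#' Estimate the insert-length model from a BAM file
#'
#' Streams proper-pair records from a coordinate-sorted indexed BAM,
#' stratifies insert lengths by read-group library (LB, falling back to the
#' sample name, falling back to \code{"default"}) and fits
#' [insert_model_from_lengths()]. Only the leftmost mate of each pair (TLEN >
#' 0) contributes, so each pair is counted once.
#'
#' @param bam path to an indexed BAM file.
#' @param min_pairs minimum concordant pairs per library.
#' @param max_pairs cap on pairs used per library (a single streaming pass
#'   over at most this many records per library).
#' @return an \code{insert_model}.
#' @export
estimate_insert_model <- function(bam, min_pairs = 1000L, max_pairs = 1e6L) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$text
  rg2lib <- rg_library_map(hdr, bam)
  flag <- Rsamtools::scanBamFlag(isProperPair = TRUE, isMinusStrand = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("isize", "qwidth"),
                                   tag = "RG")
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  isize <- res$isize
  keep <- which(!is.na(isize) & isize > 0)
  if (length(keep) == 0) stop("no concordant pairs found in ", bam)
  rg <- res$tag$RG
  lib <- if (is.null(rg)) rep("default", length(keep)) else {
    l <- rg2lib[as.character(rg[keep])]
    l[is.na(l)] <- "default"
    l
  }
  isize <- isize[keep]
  # per-library cap, first-come order
  sel <- unlist(lapply(split(seq_along(isize), lib),
                       function(i) head(i, max_pairs)), use.names = FALSE)
  sel <- sort(sel)
  read_len <- modal_int(res$qwidth[keep][seq_len(min(length(keep), 20000L))])
  insert_model_from_lengths(isize[sel], lib[sel], read_len = read_len,
                            min_pairs = min_pairs)
}

rg_library_map <- function(header_text, bam) {
  rgs <- header_text[names(header_text) == "@RG"]
  if (length(rgs) == 0) return(character(0))
  ids <- libs <- character(length(rgs))
  for (i in seq_along(rgs)) {
    f <- rgs[[i]]
    id <- sub("^ID:", "", grep("^ID:", f, value = TRUE)[1])
    lb <- grep("^LB:", f, value = TRUE)
    sm <- grep("^SM:", f, value = TRUE)
    ids[i] <- id
    libs[i] <- if (length(lb)) sub("^LB:", "", lb[1]) else
      if (length(sm)) sub("^SM:", "", sm[1]) else "default"
  }
  setNames(libs, ids)
}

modal_int <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(100L)
  t <- table(x)
  as.integer(names(t)[which.max(t)])
}

model_library <- function(model, library) {
  model$libraries[[library]] %||% model$libraries[[1]]
}

#' Evaluate the insert-length density
#'
#' @param model an \code{insert_model}.
#' @param y insert lengths (bp), vectorized.
#' @param library library name; unknown libraries fall back to the first.
#' @return smoothed empirical probability mass \eqn{f_Y(y) > 0}.
#' @export
insert_density <- function(model, y, library = "default") {
  lib <- model_library(model, library)
  out <- rep(model$floor, length(y))
  idx <- round(y) - lib$lo + 1L
  ok <- which(!is.na(idx) & idx >= 1L & idx <= length(lib$dens))
  out[ok] <- lib$dens[idx[ok]]
  out
}

#' Flank width implied by an insert-length model
#'
#' The single source of truth for every window in the caller:
#' \code{round(E[Y] + 3*sd(Y))} of the pooled insert-length distribution.
#'
#' @param model an \code{insert_model}.
#' @return integer width in bp.
#' @export
flank_width <- function(model) {
  as.integer(round(model$pooled$mean + 3 * model$pooled$sd))
}

#' @export
print.insert_model <- function(x, ...) {
  cat("Insert-length model (", length(x$libraries), " librar",
      if (length(x$libraries) == 1) "y" else "ies", ")\n", sep = "")
  for (lb in names(x$libraries)) {
    l <- x$libraries[[lb]]
    cat(sprintf("  %-12s E[Y] = %.1f bp  sd(Y) = %.1f bp  (n = %d)\n",
                lb, l$mean, l$sd, l$count))
  }
  cat(sprintf("  read length %d bp, flank width %d bp\n",
              x$read_len, flank_width(x)))
  invisible(x)
}
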