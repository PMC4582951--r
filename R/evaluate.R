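# Evaluation against a truth set ------------------------------------------

#' Build a 3x3 genotype confusion matrix
#'
#' Counts \eqn{C_{tp}}: the number of genotype-p predictions whose true
#' genotype is t, over every (sample, locus) pair. A truth event with no
#' matching call is counted as predicted G0, and a call at a position with
#' no truth event as true G0. Genotypes are event-allele dosages (G0
#' non-carrier, G1 heterozygote, G2 homozygote carrier); no-calls count as
#' G0.
#'
#' @param truth data.frame(sample, locus, genotype).
#' @param calls data.frame(sample, locus, genotype); \code{locus} values
#'   must be comparable with the truth's (use [match_insertion_loci()] to
#'   map called positions onto truth loci first).
#' @return matrix of class \code{alu_confusion} with dimnames true G0..G2 x
#'   predicted G0..G2.
#' @export
confusion_matrix <- function(truth, calls) {
  key_t <- paste(truth$sample, truth$locus)
  key_c <- paste(calls$sample, calls$locus)
  if (anyDuplicated(key_c))
    stop("duplicate (sample, locus) call")
  if (anyDuplicated(key_t))
    stop("duplicate (sample, locus) truth entry")
  g_call <- calls$genotype[match(key_t, key_c)]
  g_call[is.na(g_call)] <- 0L
  g_true <- truth$genotype
  extra <- !(key_c %in% key_t) & !is.na(calls$genotype) & calls$genotype > 0L
  g_true <- c(g_true, rep(0L, sum(extra)))
  g_call <- c(g_call, calls$genotype[extra])
  cm <- table(factor(g_true, 0:2), factor(g_call, 0:2))
  cm <- matrix(as.integer(cm), 3, 3,
               dimnames = list(true = paste0("G", 0:2),
                               predicted = paste0("G", 0:2)))
  class(cm) <- c("alu_confusion", class(cm))
  cm
}

#' Assemble a confusion matrix from its counts
#'
#' @param c00,c01,c02,c10,c11,c12,c20,c21,c22 counts \eqn{C_{tp}} (true
#'   genotype t, predicted p).
#' @return an \code{alu_confusion} matrix.
#' @export
confusion_from_counts <- function(c00 = 0, c01 = 0, c02 = 0,
                                  c10 = 0, c11 = 0, c12 = 0,
                                  c20 = 0, c21 = 0, c22 = 0) {
  cm <- matrix(as.integer(c(c00, c01, c02, c10, c11, c12, c20, c21, c22)),
               3, 3, byrow = TRUE,
               dimnames = list(true = paste0("G", 0:2),
                               predicted = paste0("G", 0:2)))
  class(cm) <- c("alu_confusion", class(cm))
  cm
}

tpn <- function(cm) cm["G1", "G1"] + cm["G2", "G2"] + cm["G1", "G2"] +
  cm["G2", "G1"]

#' Sensitivity: TPN / (TPN + C10 + C20)
#'
#' True-positive calls TPN = C11 + C22 + C12 + C21 tolerate genotyping
#' errors between the two carrier classes.
#'
#' @param cm an \code{alu_confusion}.
#' @return fraction in [0, 1].
#' @export
sensitivity <- function(cm) {
  den <- tpn(cm) + cm["G1", "G0"] + cm["G2", "G0"]
  if (den == 0) stop("sensitivity undefined: no true carriers")
  unname(tpn(cm) / den)
}

#' False discovery rate: (C01 + C02) / (TPN + C01 + C02)
#'
#' @param cm an \code{alu_confusion}.
#' @return fraction in [0, 1].
#' @export
fdr <- function(cm) {
  fp <- cm["G0", "G1"] + cm["G0", "G2"]
  den <- tpn(cm) + fp
  if (den == 0) stop("FDR undefined: no positive calls")
  unname(fp / den)
}

#' @export
print.alu_confusion <- function(x, ...) {
  cat("Genotype confusion matrix (rows = truth, cols = predicted)\n")
  print(unclass(x))
  sens <- tryCatch(sensitivity(x), error = function(e) NA)
  f <- tryCatch(fdr(x), error = function(e) NA)
  cat(sprintf("TPN = %d, sensitivity = %s, FDR = %s\n", tpn(x),
              if (is.na(sens)) "undefined" else sprintf("%.1f%%", 100 * sens),
              if (is.na(f)) "undefined" else sprintf("%.1f%%", 100 * f)))
  invisible(x)
}

#' Match called insertion positions to truth loci
#'
#' Insertions are discovered, so calls and truth are matched by position
#' within a window (default +/- 50 bp, the tolerance allowed between the
#' two breakpoints of one event). Deletion calls are matched by locus name
#' and need no matching step.
#'
#' @param call_pos called 0-based positions.
#' @param truth_pos truth 0-based positions (one per locus).
#' @param truth_names truth locus names.
#' @param window maximum distance in bp.
#' @return character vector: the matched truth locus name per call, or the
#'   call's own identifier when unmatched.
#' @export
match_insertion_loci <- function(call_pos, truth_pos, truth_names,
                                 window = 50L) {
  vapply(seq_along(call_pos), function(i) {
    d <- abs(truth_pos - call_pos[i])
    j <- which.min(d)
    if (length(j) && d[j] <= window) truth_names[j]
    else paste0("unmatched_", call_pos[i])
  }, character(1))
}

#' Score a call set against the simulated truth
#'
#' @param truth an \code{alu_truth} object (or a truth VCF path).
#' @param calls an \code{alu_calls} object (or a calls VCF path).
#' @param simref the \code{alu_sim_ref} (needed for truth positions when
#'   VCF paths are given it is read from the file).
#' @param window insertion matching window (bp).
#' @return list with the confusion matrix, sensitivity, fdr, genotype
#'   concordance over called carrier-truth pairs, and for insertions the
#'   per-detected-site breakpoint errors (bp).
#' @export
evaluate_calls <- function(truth, calls, simref = NULL, window = 50L) {
  if (is.character(truth)) {
    tv <- read_genotype_vcf(truth)
    t_df <- data.frame(
      sample = rep(colnames(tv$dosage), each = nrow(tv$dosage)),
      locus = rep(tv$loci$name, ncol(tv$dosage)),
      genotype = as.vector(tv$dosage), stringsAsFactors = FALSE)
    truth_pos <- setNames(tv$loci$pos0, tv$loci$name)
  } else {
    g <- truth$genotypes
    t_df <- data.frame(sample = rep(rownames(g), ncol(g)),
                       locus = rep(colnames(g), each = nrow(g)),
                       genotype = as.vector(g), stringsAsFactors = FALSE)
    truth_pos <- setNames(simref$targets$AL, simref$targets$name)
  }
  if (is.character(calls)) {
    cv <- read_genotype_vcf(calls)
    type <- if (any(cv$loci$svtype == "INS")) "INS" else "DEL"
    c_loci <- cv$loci$name
    c_pos <- cv$loci$pos0
    dm <- cv$dosage
  } else {
    type <- calls$type
    c_loci <- calls$loci$name
    c_pos <- if (type == "INS") calls$loci$pos else calls$loci$AL
    dm <- calls$genotype
  }
  bp_err <- NULL
  if (type == "INS") {
    mapped <- match_insertion_loci(c_pos, truth_pos, names(truth_pos),
                                   window = window)
    # at most one call per truth locus: keep the closest, spill the rest
    hit <- which(!startsWith(mapped, "unmatched_"))
    if (length(hit)) {
      d <- abs(c_pos[hit] - truth_pos[mapped[hit]])
      for (nm in unique(mapped[hit][duplicated(mapped[hit])])) {
        ii <- hit[mapped[hit] == nm]
        drop <- ii[-which.min(d[mapped[hit] == nm])]
        mapped[drop] <- paste0("unmatched_", c_pos[drop], "_", drop)
      }
    }
    dupu <- duplicated(mapped)
    mapped[dupu] <- paste0(mapped[dupu], "_", which(dupu))
    hit <- !startsWith(mapped, "unmatched_")
    bp_err <- abs(c_pos[hit] - truth_pos[mapped[hit]])
    c_loci <- mapped
  }
  c_df <- data.frame(sample = rep(colnames(dm), each = nrow(dm)),
                     locus = rep(c_loci, ncol(dm)),
                     genotype = as.vector(dm), stringsAsFactors = FALSE)
  cm <- confusion_matrix(t_df, c_df)
  key_t <- paste(t_df$sample, t_df$locus)
  key_c <- paste(c_df$sample, c_df$locus)
  m <- match(key_c, key_t)
  called <- !is.na(c_df$genotype) & !is.na(m)
  conc <- mean(c_df$genotype[called] == t_df$genotype[m[called]])
  list(confusion = cm,
       sensitivity = sensitivity(cm),
       fdr = tryCatch(fdr(cm), error = function(e) NA_real_),
       concordance = conc,
       breakpoint_errors = bp_err)
}

#' Count Mendelian-inconsistent calls in a trio
#'
#' A child's event dosage must be attainable from one gamete of each
#' parent; calls private to the child are counted as violations as well
#' (de novo Alu insertions are expected about once per generation, so a
#' child-private call is almost surely a false positive). The ratio of
#' violations to child carrier calls is a lower bound on the FDR.
#'
#' @param father,mother,child data.frame(locus, genotype) with event
#'   dosages; missing loci are dosage 0.
#' @return list(violations, child_calls, fdr_bound, loci).
#' @export
mendelian_violations <- function(father, mother, child) {
  all_loci <- unique(c(father$locus, mother$locus, child$locus))
  dosage <- function(d, loci) {
    g <- d$genotype[match(loci, d$locus)]
    g[is.na(g)] <- 0L
    g
  }
  f <- dosage(father, all_loci)
  m <- dosage(mother, all_loci)
  c_ <- dosage(child, all_loci)
  gametes <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  ok <- vapply(seq_along(all_loci), function(i) {
    c_[i] %in% outer(gametes[[f[i] + 1L]], gametes[[m[i] + 1L]], `+`)
  }, logical(1))
  bad <- !ok
  child_calls <- sum(c_ > 0L)
  list(violations = sum(bad), child_calls = child_calls,
       fdr_bound = if (child_calls > 0) sum(bad & c_ > 0L) / child_calls
                   else NA_real_,
       loci = all_loci[bad])
}

#' Metrics table for a scored call set
#'
#' @param cm an \code{alu_confusion}.
#' @param dataset label for the row.
#' @return one-row data.frame with every count, TPN, sensitivity and FDR.
#' @export
metrics_row <- function(cm, dataset = "dataset") {
  data.frame(dataset = dataset,
             C11 = cm["G1", "G1"], C22 = cm["G2", "G2"],
             C10 = cm["G1", "G0"], C20 = cm["G2", "G0"],
             C01 = cm["G0", "G1"], C02 = cm["G0", "G2"],
             C12 = cm["G1", "G2"], C21 = cm["G2", "G1"],
             TPN = tpn(cm),
             sensitivity = sensitivity(cm),
             fdr = tryCatch(fdr(cm), error = function(e) NA_real_),
             stringsAsFactors = FALSE)
}
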