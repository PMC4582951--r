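# Deletion path: analysis windows, read-pair classification, split
# realignment across the element

ref_fixture <- local({
  set.seed(99)
  chars <- sample(c("A", "C", "G", "T"), 20000, replace = TRUE,
                  prob = c(.3, .2, .2, .3))
  Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""), "chrT"))
})

del_window <- function(AL = 10000L, AR = 10300L, w = 390L) {
  build_window(alu_locus("chrT", AL, AR), w, chrom_len = 20000L)
}

ref_part <- function(begin0, end0) {
  as.character(Biostrings::subseq(ref_fixture[["chrT"]], begin0 + 1, end0))
}

read_row <- function(pos0, cigar, seq, strand = "+", qname = "r1",
                     mapq = 60L) {
  clips <- aluscan:::cigar_clips(cigar)
  data.frame(qname = qname, flag = 0L, rg = NA_character_, chrom = "chrT",
             pos0 = pos0,
             end0 = pos0 + aluscan:::cigar_ref_width(cigar),
             strand = strand, mapq = mapq, cigar = cigar,
             mrnm = "chrT", mpos0 = 0L, isize = 0L, qwidth = nchar(seq),
             seq = seq, qual = strrep("I", nchar(seq)),
             clipL = clips[1, "left"], clipR = clips[1, "right"],
             proper = TRUE, mate_rev = strand == "+",
             mate_unmapped = FALSE, first = strand == "+",
             stringsAsFactors = FALSE)
}

test_that("analysis windows add symmetric flanks clipped at the bounds", {
  model <- insert_model_from_lengths(rep(c(270L, 300L, 330L), 500),
                                     min_pairs = 100)
  model$pooled <- list(mean = 300, sd = 30)
  w <- build_window(alu_locus("chrT", 10000, 10300), model,
                    chrom_len = 20000)
  expect_equal(w$FL, 9610)
  expect_equal(w$FR, 10690)
  expect_equal(w$w, 390)
  # degenerate sd was replaced by 1 bp at model build time
  m0 <- insert_model_from_lengths(rep(300L, 1500))
  expect_equal(flank_width(m0), 303L)
  near0 <- build_window(alu_locus("chrT", 100, 400), 390, chrom_len = 20000)
  expect_equal(near0$FL, 0)
})

test_that("pairs are classified I / A by mate containment, others dropped", {
  win <- del_window()
  mk_pair <- function(bL, bR, id) {
    rbind(read_row(bL, "100M", ref_part(bL, bL + 100), "+", id),
          read_row(bR, "100M", ref_part(bR, bR + 100), "-", id))
  }
  reads <- rbind(
    mk_pair(9700, 10100, "pI"),    # left mate in flank, right inside Alu
    mk_pair(9700, 10450, "pA"),    # mates in the two flanks
    mk_pair(10050, 10150, "pDrop") # both mates inside the element
  )
  cp <- aluscan:::classify_window_pairs_from_reads(reads, win, ref_fixture)
  expect_equal(sort(cp$qname), c("pA", "pI"))
  expect_equal(cp$type[cp$qname == "pI"], "I")
  expect_equal(cp$type[cp$qname == "pA"], "A")
  expect_equal(cp$y[cp$qname == "pA"], 10550 - 9700)
  # the right-side internal configuration is type I as well
  cp2 <- aluscan:::classify_window_pairs_from_reads(mk_pair(10150, 10500, "pI2"), win,
                                          ref_fixture)
  expect_equal(cp2$type, "I")
})

test_that("split realignment spans the element with 20 bp on each side", {
  win <- del_window()
  # H1 junction read: 50 bp ending at AL, then 50 bp continuing from AR
  seq_split <- paste0(ref_part(9950, 10000), ref_part(10300, 10350))
  hit <- split_realign(list(seq = seq_split, cigar = "50M50S", pos0 = 9950),
                       win, ref_fixture)
  expect_false(is.null(hit))
  expect_equal(hit$clip_pos, 10000)
  expect_equal(hit$side, "R")
  expect_gte(hit$aligned, 45)
  # mirrored orientation: clip on the left at AR, tail aligns back to AL
  seq_l <- paste0(ref_part(9960, 10000), ref_part(10300, 10360))
  hit_l <- split_realign(list(seq = seq_l, cigar = "40S60M", pos0 = 10300),
                         win, ref_fixture)
  expect_false(is.null(hit_l))
  expect_equal(hit_l$side, "L")
  # too little sequence beyond the clip: rejected
  seq_short <- paste0(ref_part(9915, 10000), ref_part(10300, 10315))
  expect_null(split_realign(list(seq = seq_short, cigar = "85M15S",
                                 pos0 = 9915), win, ref_fixture))
  # mismatches within the clipped part are tolerated while the score holds
  clip <- ref_part(10300, 10350)
  for (p in c(5L, 20L, 40L)) {
    b <- substr(clip, p, p)
    substr(clip, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  hit_mm <- split_realign(list(seq = paste0(ref_part(9950, 10000), clip),
                               cigar = "50M50S", pos0 = 9950),
                          win, ref_fixture)
  expect_false(is.null(hit_mm))
  expect_gte(hit_mm$score, 25)
  # a clip that aligns inside the element instead of beyond AR: rejected
  seq_alu <- paste0(ref_part(9950, 10000), ref_part(10100, 10150))
  expect_null(split_realign(list(seq = seq_alu, cigar = "50M50S",
                                 pos0 = 9950), win, ref_fixture))
})

test_that("a confirmed split takes precedence over mate-based classes", {
  win <- del_window()
  seq_split <- paste0(ref_part(9950, 10000), ref_part(10300, 10350))
  reads <- rbind(
    read_row(9950, "50M50S", seq_split, "+", "pS"),
    read_row(10400, "100M", ref_part(10400, 10500), "-", "pS"))
  cp <- aluscan:::classify_window_pairs_from_reads(reads, win, ref_fixture)
  expect_equal(cp$type, "S")
  expect_equal(cp$clip_pos, 10000)
})
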