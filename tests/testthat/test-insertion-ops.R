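# Insertion path primitives: support scan, region construction, merging,
# split mapping against the panel, and breakpoint voting

# brute force over all candidate positions: direct evaluation of the
# covering definition for every p = end(read)
brute_support <- function(anchors, w, n) {
  cand <- sort(unique(anchors$end))
  la <- anchors[anchors$class == "la", ]
  ra <- anchors[anchors$class == "ra", ]
  support <- vapply(cand, function(p) {
    sum(p >= la$end & p <= la$begin + w) +
      sum(p >= ra$end - w & p <= ra$begin)
  }, numeric(1))
  data.frame(pos = cand[support > n], support = support[support > n])
}

rand_anchors <- function(m, g) {
  begin <- sample.int(g, m, replace = TRUE)
  data.frame(begin = begin, end = begin + 100L,
             class = sample(c("la", "ra"), m, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("support scan matches the definition on directed cases", {
  la6 <- data.frame(begin = rep(900L, 6), end = rep(1000L, 6), class = "la")
  s <- scan_support(la6, w = 520L, n = 4L)
  expect_equal(s$pos, 1000L)
  expect_equal(s$support, 6L)
  # support must strictly exceed n
  la4 <- la6[1:4, ]
  expect_equal(nrow(scan_support(la4, w = 520L, n = 4L)), 0L)
  expect_equal(nrow(scan_support(la4[0, ], w = 520L, n = 4L)), 0L)
})

test_that("support scan equals brute force on random instances", {
  set.seed(123)
  for (i in 1:100) {
    m <- sample.int(200, 1)
    g <- sample.int(50000, 1) + 1000L
    anchors <- rand_anchors(m, g)
    w <- sample(c(300L, 520L, 700L), 1)
    n <- sample(0:6, 1)
    expect_equal(scan_support(anchors, w, n), brute_support(anchors, w, n),
                 info = sprintf("instance %d", i))
  }
})

# direct transliteration of the greedy construction: start a region at the
# first position, extend while p - b < len, else start a new one
brute_regions <- function(positions, len) {
  if (length(positions) == 0) return(data.frame(b = integer(), e = integer()))
  b <- e <- positions[1]
  out <- NULL
  for (p in positions[-1]) {
    if (p - b < len) e <- p
    else { out <- rbind(out, data.frame(b = b, e = e)); b <- e <- p }
  }
  rbind(out, data.frame(b = b, e = e))
}

test_that("region construction groups positions greedily under the cap", {
  r <- build_regions(c(100L, 150L, 290L, 600L), len = 200L)
  expect_equal(r$b, c(100L, 600L))
  expect_equal(r$e, c(290L, 600L))
  expect_equal(build_regions(42L, 200L), data.frame(b = 42L, e = 42L))
  expect_equal(nrow(build_regions(integer(0), 200L)), 0L)
  set.seed(11)
  for (i in 1:50) {
    p <- sort(sample.int(5000, sample.int(60, 1)))
    expect_equal(build_regions(p, 200L), brute_regions(p, 200L))
  }
  # every position falls in exactly one region; spans stay below the cap
  p <- sort(sample.int(10000, 200))
  r <- build_regions(p, 200L)
  expect_true(all(r$e - r$b < 200))
  covered <- vapply(p, function(x) sum(x >= r$b & x <= r$e), numeric(1))
  expect_true(all(covered == 1))
})

test_that("cross-sample merging obeys the adjacency predicate", {
  r <- merge_regions_multi(list(A = data.frame(b = 100L, e = 180L),
                                B = data.frame(b = 150L, e = 250L)),
                           len = 200L)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$b, r$e), c(100L, 250L))
  expect_equal(r$samples, "A,B")
  r2 <- merge_regions_multi(list(A = data.frame(b = 100L, e = 180L),
                                 B = data.frame(b = 400L, e = 450L)), 200L)
  expect_equal(nrow(r2), 2L)
  r3 <- merge_regions_multi(list(A = data.frame(b = 100L, e = 180L),
                                 B = data.frame(b = 100L, e = 180L),
                                 C = data.frame(b = 100L, e = 180L)), 200L)
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$samples, "A,B,C")
  # near-miss on the length cap: b_l < e_k holds but e_l - b_k >= len
  r4 <- merge_regions_multi(list(A = data.frame(b = 100L, e = 180L),
                                 B = data.frame(b = 150L, e = 330L)), 200L)
  expect_equal(nrow(r4), 2L)
})

test_that("split mapping of clipped reads finds the panel family", {
  panel <- load_alu_panel()
  alu <- as.character(panel[["AluSyn3"]])
  c_read <- data.frame(qname = "c1", chrom = "chrT", side = "R",
                       clip_pos = 5000L, clip_len = 40L,
                       clip_seq = substr(alu, 1, 40), anchor_len = 60L,
                       stringsAsFactors = FALSE)
  hit <- split_map_c_read(c_read, panel)
  expect_equal(hit$side, "left")
  expect_equal(hit$ref_breakpoint, 5000L)
  expect_equal(hit$alu_hit, "AluSyn3")
  # reverse-strand insertion: the clipped tail is a reverse complement
  c_rc <- c_read
  c_rc$clip_seq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(substr(alu, 100, 139))))
  expect_false(is.null(split_map_c_read(c_rc, panel)))
  # short clip fails the flank rule
  c_short <- c_read; c_short$clip_len <- 15L
  c_short$clip_seq <- substr(alu, 1, 15)
  expect_null(split_map_c_read(c_short, panel))
  # non-Alu clipped sequence fails the score threshold
  set.seed(5)
  c_bad <- c_read
  c_bad$clip_seq <- paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                          collapse = "")
  expect_null(split_map_c_read(c_bad, panel))
})

test_that("two-level voting elects modal positions per side", {
  votes <- rbind(
    data.frame(sample = "s1", side = "left", pos = c(5000L, 5000L, 5007L),
               family = "AluSyn1"),
    data.frame(sample = "s2", side = "left", pos = c(5000L, 4998L, 5000L),
               family = "AluSyn1"),
    data.frame(sample = "s3", side = "left", pos = 5003L,
               family = "AluSyn2"),
    data.frame(sample = "s1", side = "right", pos = c(4990L, 4990L),
               family = "AluSyn1"))
  bp <- vote_breakpoints(votes)
  expect_equal(bp$AL, 5000L)
  expect_equal(bp$AR, 4990L)
  expect_equal(bp$family, "AluSyn1")
  # AL right of AR reads as a target-site duplication
  expect_equal(bp$tsd_len, 10L)
  expect_null(vote_breakpoints(votes[0, ]))
  # one-sided case: only AL determined
  bp_l <- vote_breakpoints(votes[votes$side == "left", ])
  expect_true(is.na(bp_l$AR))
  expect_equal(bp_l$AL, 5000L)
  # sides further apart than the tolerance: keep the better-voted side
  far <- votes
  far$pos[far$side == "right"] <- 4000L
  bp_far <- vote_breakpoints(far)
  expect_equal(bp_far$AL, 5000L)
  expect_true(is.na(bp_far$AR))
})

test_that("voting is invariant to sample and read order", {
  set.seed(21)
  votes <- data.frame(
    sample = sample(paste0("s", 1:5), 40, replace = TRUE),
    side = sample(c("left", "right"), 40, replace = TRUE),
    pos = 7000L + sample(0:6, 40, replace = TRUE),
    family = sample(c("AluSyn1", "AluSyn2"), 40, replace = TRUE),
    stringsAsFactors = FALSE)
  bp <- vote_breakpoints(votes)
  for (i in 1:10) {
    perm <- votes[sample.int(nrow(votes)), ]
    expect_identical(vote_breakpoints(perm), bp)
  }
})

test_that("level-1 ties break to the smaller position", {
  votes <- data.frame(sample = "s1", side = "left",
                      pos = c(5002L, 5002L, 5001L, 5001L),
                      family = "AluSyn1")
  expect_equal(vote_breakpoints(votes)$AL, 5001L)
})
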