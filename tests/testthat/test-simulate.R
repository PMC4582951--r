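# Truth-aware simulator: placement constraints, population draws,
# alignment emission

small_cfg <- function(mode = "SimDel", ...) {
  sim_config(mode = mode, ref_length = 8e4, n_loci = 2, n_decoys = 4,
             n_haplotypes = 4, coverage = 20, seed = 31, ...)
}

test_that("planted elements respect the spacing constraint and the mode", {
  cfg <- small_cfg()
  simref <- make_reference(cfg, tempfile("ref"))
  all_el <- rbind(simref$targets[, c("AL", "AR")],
                  simref$decoys[, c("AL", "AR")])
  all_el <- all_el[order(all_el$AL), ]
  gaps <- all_el$AL[-1] - all_el$AR[-nrow(all_el)]
  expect_true(all(gaps >= 600))
  expect_equal(nrow(simref$targets), 2L)
  # SimDel: targets occupy [AL, AR) of the working reference
  expect_true(all(simref$targets$AR - simref$targets$AL > 250))
  tseq <- as.character(Biostrings::subseq(simref$reference[[1]],
                                          simref$targets$AL[1] + 1,
                                          simref$targets$AR[1]))
  expect_equal(tseq, simref$targets$seq[1])
  # SimIns: the working reference lacks the targets (AL == AR)
  simref_i <- make_reference(small_cfg("SimIns"), tempfile("ref"))
  expect_true(all(simref_i$targets$AL == simref_i$targets$AR))
  expect_lt(Biostrings::width(simref_i$reference)[1],
            Biostrings::width(simref$reference)[1])
  # infeasible placement is refused
  expect_error(make_reference(sim_config(ref_length = 1e4, n_loci = 100,
                                         seed = 1), tempfile("ref")),
               "infeasible")
})

test_that("the same seed reproduces the reference byte for byte", {
  s1 <- make_reference(small_cfg(), tempfile("ref"))
  s2 <- make_reference(small_cfg(), tempfile("ref"))
  expect_identical(as.character(s1$reference), as.character(s2$reference))
  expect_identical(s1$targets, s2$targets)
  expect_identical(readLines(s1$target_bed), readLines(s2$target_bed))
})

test_that("population draws give dosage-consistent diploid genotypes", {
  cfg <- small_cfg()
  simref <- make_reference(cfg, tempfile("ref"))
  truth <- simulate_population(simref, cfg)
  manual <- truth$carry[c(1, 3), ] + truth$carry[c(2, 4), ]
  expect_equal(unname(truth$genotypes), unname(manual))
  # frequency boundaries force monomorphic genotypes
  t2 <- truth
  t2$carry[] <- 1L
  expect_true(all(t2$carry[seq(1, 4, 2), ] + t2$carry[seq(2, 4, 2), ] == 2L))
})

test_that("heterozygote counts track the analytic expectation E[2p(1-p)] = 1/3", {
  cfg <- sim_config(mode = "SimDel", ref_length = 4e6, n_loci = 100,
                    n_decoys = 10, n_haplotypes = 200, snp_rate = 0,
                    indel_rate = 0, seed = 77)
  simref <- make_reference(cfg, tempfile("ref"))
  truth <- simulate_population(simref, cfg)
  het_per_ind <- rowSums(truth$genotypes == 1L)
  # 100 loci x E[2p(1-p)] = 33.3 expected hets per individual; the largest
  # variance term comes from the 100 frequency draws
  expect_gt(mean(het_per_ind), 33.3 - 6)
  expect_lt(mean(het_per_ind), 33.3 + 6)
  # truth genotype frequencies match the drawn p per locus (binomial error)
  p_hat <- colMeans(truth$carry)
  se <- sqrt(truth$freqs * (1 - truth$freqs) / nrow(truth$carry)) + 1e-9
  expect_lt(mean(abs(p_hat - truth$freqs) / se > 4), 0.05)
})

test_that("alignments encode the haplotype truthfully around deletions", {
  cfg <- small_cfg()
  dir <- tempfile("sim")
  simref <- make_reference(cfg, dir)
  truth <- simulate_population(simref, cfg)
  # force individual 1 homozygous non-carrier and individual 2 homozygous
  # deleted at locus 1 to probe both haplotype structures
  truth$carry[1:2, 1] <- 0L
  truth$carry[3:4, 1] <- 1L
  bams <- simulate_alignments(simref, truth, dir, cfg)
  AL <- simref$targets$AL[1]; AR <- simref$targets$AR[1]
  l_alu <- AR - AL
  g0 <- aluscan:::scan_reads(bams[1], "chrS", AL - 600L, AR + 600L)
  g2 <- aluscan:::scan_reads(bams[2], "chrS", AL - 600L, AR + 600L)
  # non-carrier: no junction clips at the breakpoints, inserts near the mean
  clip_at_bp <- function(rd) sum((rd$clipR >= 10 & abs(rd$end0 - AL) <= 2) |
                                   (rd$clipL >= 10 & abs(rd$pos0 - AR) <= 2))
  expect_equal(clip_at_bp(g0), 0L)
  expect_gt(clip_at_bp(g2), 2L)
  y0 <- g0$isize[g0$strand == "+" & g0$proper & g0$pos0 < AL &
                   g0$pos0 + g0$isize > AR]
  expect_gt(length(y0), 3)
  expect_lt(abs(mean(y0) - cfg$insert_mean), 4 * cfg$insert_sd)
  # homozygous deletion: spanning pairs are shifted by the element length
  y2 <- g2$isize[g2$strand == "+" & g2$pos0 + 100 < AL &
                   g2$mpos0 > AR & g2$isize > 0]
  expect_gt(length(y2), 3)
  expect_lt(abs(mean(y2) - (cfg$insert_mean + l_alu)), 4 * cfg$insert_sd)
})

test_that("coverage lands near its target and output is deterministic", {
  cfg <- small_cfg()
  dir1 <- tempfile("s1"); dir2 <- tempfile("s2")
  simref <- make_reference(cfg, dir1)
  truth <- simulate_population(simref, cfg)
  bams1 <- simulate_alignments(simref, truth, dir1, cfg)
  r1 <- aluscan:::scan_reads(bams1[1])
  # mean coverage = reads x read_len / genome length
  cov <- nrow(r1) * cfg$read_len / Biostrings::width(simref$reference)[1]
  expect_gt(cov, cfg$coverage * 0.85)
  expect_lt(cov, cfg$coverage * 1.1)
  simref2 <- make_reference(cfg, dir2)
  truth2 <- simulate_population(simref2, cfg)
  bams2 <- simulate_alignments(simref2, truth2, dir2, cfg)
  r2 <- aluscan:::scan_reads(bams2[1])
  expect_identical(r1$pos0, r2$pos0)
  expect_identical(r1$seq, r2$seq)
  expect_identical(r1$flag, r2$flag)
})

test_that("inserted-Alu reads are emitted as clipped anchors and Alu mates", {
  cfg <- small_cfg("SimIns")
  dir <- tempfile("simins")
  simref <- make_reference(cfg, dir)
  truth <- simulate_population(simref, cfg)
  truth$carry[, 1] <- 1L  # everyone carries insertion 1
  bams <- simulate_alignments(simref, truth, dir, cfg)
  P <- simref$targets$AL[1]
  rd <- aluscan:::scan_reads(bams[1], "chrS", P - 600L, P + 600L)
  # soft-clipped junction reads at the insertion point
  at_bp <- (rd$clipR >= 10 & abs(rd$end0 - P) <= 2) |
    (rd$clipL >= 10 & abs(rd$pos0 - P) <= 2)
  expect_gt(sum(at_bp), 2L)
  # discordant mates map inside annotated decoy elements
  disc <- rd[!rd$proper & !rd$mate_unmapped & rd$mapq >= 60, ]
  expect_gt(nrow(disc), 2L)
  dec <- simref$decoys
  mate_in_decoy <- vapply(disc$mpos0, function(mp)
    any(mp >= dec$AL - 100 & mp <= dec$AR), logical(1))
  expect_gt(mean(mate_in_decoy), 0.6)
})

test_that("unmapped-mate mode leaves fully internal reads unmapped", {
  cfg <- small_cfg("SimIns", map_alu_mates = "unmapped")
  dir <- tempfile("simum")
  simref <- make_reference(cfg, dir)
  truth <- simulate_population(simref, cfg)
  truth$carry[, 1] <- 1L
  bams <- simulate_alignments(simref, truth, dir, cfg)
  um <- aluscan:::scan_unmapped_mates(bams[1])
  expect_gt(nrow(um), 0)
  panel <- load_alu_panel()
  hit <- aluscan:::panel_best_hit(um$seq[seq_len(min(5, nrow(um)))], panel)
  expect_true(all(hit$score >= 25))
})
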