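# Genotype likelihood engine: allele balance, per-pair likelihoods,
# joint likelihoods against the exact rational oracle

test_that("heterozygote allele balance follows the length ratio", {
  expect_equal(allele_given_genotype(1, 100, 300), 500 / 700)
  expect_equal(allele_given_genotype(0, 100, 300), 1)
  expect_equal(allele_given_genotype(2, 100, 300), 0)
  expect_equal(allele_given_genotype("G1", 100, 300), 5 / 7)
  # vanishing element length: both alleles equally likely
  expect_equal(allele_given_genotype(1, 100, 0), 0.5)
  expect_error(allele_given_genotype(3, 100, 300), "invalid genotype")
})

test_that("junction pairs get fixed likelihoods, spanning pairs the density", {
  model <- insert_model_from_lengths(as.integer(round(rnorm(5000, 400, 40))))
  set.seed(1)
  likI <- pair_allele_likelihoods("I", model = model, l_alu = 300)
  expect_equal(unname(likI[1, ]), c(1, 0.001))
  likS <- pair_allele_likelihoods("S", model = model, l_alu = 300)
  expect_equal(unname(likS[1, ]), c(0.001, 1))
  # A pair at the mode: H0 mass is the density maximum, H1 at the floor
  m <- round(model$libraries$default$mean)
  likA <- pair_allele_likelihoods("A", y = m, model = model, l_alu = 300)
  expect_equal(unname(likA[1, "L0"]), insert_density(model, m))
  expect_equal(unname(likA[1, "L1"]), 1e-6)
  # shifted by l_alu: the two alleles swap roles
  likA2 <- pair_allele_likelihoods("A", y = m + 300, model = model,
                                   l_alu = 300)
  expect_equal(unname(likA2[1, "L1"]), insert_density(model, m))
  expect_equal(unname(likA2[1, "L0"]), 1e-6)
})

test_that("worked single-pair examples match hand evaluation", {
  # one split pair, read length 100, element 300 bp
  lik <- pair_allele_likelihoods("S", l_alu = 300)
  ll <- genotype_likelihoods(lik, read_len = 100, l_alu = 300)
  expect_equal(exp(ll[["G0"]]), 0.001)
  expect_equal(exp(ll[["G1"]]), 0.001 * 5 / 7 + 1 * 2 / 7)
  expect_equal(exp(ll[["G1"]]), 0.28643, tolerance = 1e-5)
  expect_equal(exp(ll[["G2"]]), 1)
  expect_equal(which.max(ll), c(G2 = 3L))
  # one internal pair: mirror image
  ll_i <- genotype_likelihoods(pair_allele_likelihoods("I", l_alu = 300),
                               read_len = 100, l_alu = 300)
  expect_equal(exp(ll_i[["G0"]]), 1)
  expect_equal(exp(ll_i[["G2"]]), 0.001)
  expect_equal(which.max(ll_i), c(G0 = 1L))
  # empty read set carries no information
  expect_equal(genotype_likelihoods(NULL), c(G0 = 0, G1 = 0, G2 = 0))
})

test_that("joint likelihoods match the exact rational oracle (<= 6 pairs)", {
  read_len <- 100L
  l_alu <- 300L
  lengths <- rep(c(390L, 400L, 410L), 500)  # point-like empirical density
  model <- insert_model_from_lengths(lengths, min_pairs = 100)
  p_het <- oracle_p_het(read_len, l_alu)
  combos <- expand.grid(nI = 0:2, nS = 0:2, nA_ref = 0:1, nA_del = 0:1)
  for (k in seq_len(nrow(combos))) {
    nI <- combos$nI[k]; nS <- combos$nS[k]
    nA0 <- combos$nA_ref[k]; nA1 <- combos$nA_del[k]
    if (nI + nS + nA0 + nA1 == 0 || nI + nS + nA0 + nA1 > 6) next
    type <- c(rep("I", nI), rep("S", nS), rep("A", nA0 + nA1))
    y <- c(rep(NA, nI + nS), rep(400, nA0), rep(400 + l_alu, nA1))
    lik <- pair_allele_likelihoods(type, y, model, l_alu = l_alu)
    ll <- genotype_likelihoods(lik, read_len = read_len, l_alu = l_alu)
    f_at <- function(yy) oracle_density(lengths, yy)
    pairs <- c(
      replicate(nI, oracle_pair("I"), simplify = FALSE),
      replicate(nS, oracle_pair("S"), simplify = FALSE),
      replicate(nA0, oracle_pair("A", f0 = f_at(400),
                                 f1 = f_at(400 - l_alu)), simplify = FALSE),
      replicate(nA1, oracle_pair("A", f0 = f_at(400 + l_alu),
                                 f1 = f_at(400)), simplify = FALSE))
    for (g in 0:2) {
      p_h0 <- switch(g + 1L, rat(1), p_het, rat(0))
      expected <- rat_num(oracle_joint_likelihood(pairs, p_h0))
      expect_equal(exp(ll[[g + 1L]]), expected, tolerance = 1e-12,
                   info = sprintf("combo %d genotype G%d", k, g))
    }
  }
})

test_that("evidence monotonicity: splits push away from G0, internals from G2", {
  model <- insert_model_from_lengths(rep(c(390L, 400L, 410L), 500),
                                     min_pairs = 100)
  base_types <- c("I", "S", "A")
  base_y <- c(NA, NA, 400)
  ll0 <- genotype_likelihoods(
    pair_allele_likelihoods(base_types, base_y, model, l_alu = 300),
    read_len = 100, l_alu = 300)
  llS <- genotype_likelihoods(
    pair_allele_likelihoods(c(base_types, "S"), c(base_y, NA), model,
                            l_alu = 300), read_len = 100, l_alu = 300)
  expect_lte(llS[["G0"]] - llS[["G2"]], ll0[["G0"]] - ll0[["G2"]])
  llI <- genotype_likelihoods(
    pair_allele_likelihoods(c(base_types, "I"), c(base_y, NA), model,
                            l_alu = 300), read_len = 100, l_alu = 300)
  expect_lte(llI[["G2"]] - llI[["G0"]], ll0[["G2"]] - ll0[["G0"]])
})

test_that("swapping I and S labels mirrors G0 and G2 exactly", {
  set.seed(3)
  for (rep_i in 1:5) {
    nI <- sample(0:3, 1); nS <- sample(0:3, 1)
    if (nI + nS == 0) nI <- 1
    type <- c(rep("I", nI), rep("S", nS))
    ll <- genotype_likelihoods(pair_allele_likelihoods(type, l_alu = 300),
                               read_len = 100, l_alu = 300)
    swapped <- ifelse(type == "I", "S", "I")
    ll_sw <- genotype_likelihoods(pair_allele_likelihoods(swapped,
                                                          l_alu = 300),
                                  read_len = 100, l_alu = 300)
    expect_equal(ll[["G0"]], ll_sw[["G2"]], tolerance = 1e-12)
    expect_equal(ll[["G2"]], ll_sw[["G0"]], tolerance = 1e-12)
    # G1 is mirrored once the allele balance is complemented: under the
    # label swap, P(H0|G1) -> 1 - P(H0|G1) restores the same mixture
    p1 <- allele_given_genotype(1, 100, 300)
    lik <- pair_allele_likelihoods(swapped, l_alu = 300)
    mix <- sum(log(lik[, "L0"] * (1 - p1) + lik[, "L1"] * p1))
    expect_equal(ll[["G1"]], mix, tolerance = 1e-12)
  }
})

test_that("genotype calls use argmax with sane tie and evidence rules", {
  ll <- log(c(0.001, 0.28643, 1))
  call <- call_genotype(ll, n_evidence = 3)
  expect_equal(call$genotype, 2L)
  expect_gt(call$gq, 0)
  expect_equal(call$pl[3], 0L)  # best genotype has PL 0
  # ties and thin evidence yield no-calls
  expect_true(is.na(call_genotype(c(0, 0, 0), n_evidence = 10)$genotype))
  expect_true(is.na(call_genotype(ll, n_evidence = 1)$genotype))
  # exact two-way tie resolves toward the reference-supporting genotype
  tie <- call_genotype(log(c(1, 0.5, 1)), n_evidence = 5)
  expect_equal(tie$genotype, 0L)
})
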