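# Exact rational arithmetic (integer numerator/denominator pairs) used by
# the brute-force likelihood oracle. Kept deliberately independent of the
# package's likelihood code: the mixture product is evaluated symbolically
# and only converted to double at the end.

rat <- function(num, den = 1) {
  g <- gcd_int(abs(num), abs(den))
  if (g > 0) { num <- num / g; den <- den / g }
  if (den < 0) { num <- -num; den <- -den }
  list(num = num, den = den)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

rat_add <- function(x, y) rat(x$num * y$den + y$num * x$den, x$den * y$den)
rat_mul <- function(x, y) rat(x$num * y$num, x$den * y$den)
rat_sub1 <- function(x) rat(x$den - x$num, x$den)  # 1 - x
rat_num <- function(x) x$num / x$den

# Brute-force evaluation of the joint genotype likelihood: the product over
# pairs of { L(r|H0) P(H0|G) + L(r|H1) (1 - P(H0|G)) }, all terms rational.
# pairs: list of list(L0 = rat, L1 = rat). p_h0: rational P(H0|G).
oracle_joint_likelihood <- function(pairs, p_h0) {
  acc <- rat(1)
  for (p in pairs) {
    term <- rat_add(rat_mul(p$L0, p_h0), rat_mul(p$L1, rat_sub1(p_h0)))
    acc <- rat_mul(acc, term)
  }
  acc
}

# Rational allele balance for a heterozygote: (2r + l) / (4r + l)
oracle_p_het <- function(read_len, l_alu) {
  rat(2 * read_len + l_alu, 4 * read_len + l_alu)
}

# Rational per-pair likelihoods under the documented conventions:
# pe as a rational (1/1000), histogram density values as (count+1)/(n+bins)
# inside the support and 1/1e6 outside it.
oracle_pair <- function(type, pe = rat(1, 1000), f0 = NULL, f1 = NULL) {
  switch(type,
         I = list(L0 = rat(1), L1 = pe),
         S = list(L0 = pe, L1 = rat(1)),
         A = list(L0 = f0, L1 = f1))
}

# Independent histogram-density oracle: the smoothed empirical mass a model
# built from `lengths` assigns to insert length y, as a rational.
oracle_density <- function(lengths, y) {
  m <- mean(lengths)
  s <- stats::sd(lengths)
  if (!is.finite(s) || s == 0) s <- 1
  lo <- max(0, floor(m - 5 * s))
  hi <- ceiling(m + 5 * s)
  if (y < lo || y > hi) return(rat(1, 1e6))
  inside <- lengths[lengths >= lo & lengths <= hi]
  cnt <- sum(round(inside) == round(y))
  rat(cnt + 1, length(inside) + (hi - lo + 1))
}
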