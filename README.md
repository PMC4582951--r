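# aluscan

Population-scale detection and genotyping of polymorphic Alu elements
from paired-end sequencing alignments.

Alu elements are ~300 bp retrotransposons comprising over 10% of the
human genome; recently inserted copies are polymorphic — present in some
individuals, absent in others. `aluscan` finds and genotypes them in two
settings: **deletions** (the element is in the reference but missing from
sequenced haplotypes; every annotated locus is genotyped) and
**insertions** (the element is absent from the reference; sites are
discovered from discordant read pairs pooled across individuals, located
base-precisely by split-read voting, and genotyped). Output is
multi-sample VCF 4.2 with genotypes, qualities and evidence counts,
ready for association testing or population genetics downstream.

## The model in brief

For a read pair r, the insert length on the reference is
Y(r) = end(r^R) − begin(r^L), with per-library empirical distribution
f_Y, mean E[Y] and standard deviation σ(Y). Around an annotated element
[AL, AR) with flanks of width w = E[Y] + 3σ(Y), read pairs classify as
**I** (one mate inside the element — supports the Alu-carrying allele
H0), **S** (a read split across both breakpoints, ≥ 20 bp aligned on
each side — supports the Alu-free allele H1), or **A** (mates in the two
flanks; insert ~ Y under H0, ~ Y + l_Alu under H1). The genotype
likelihood multiplies per-pair allele mixtures:

    L(R | G_g) = ∏_r [ L(r|H0) P(H0|G_g) + L(r|H1) (1 − P(H0|G_g)) ]

with P(H0|G0) = 1, P(H0|G2) = 0, and
P(H0|G1) = (2‖r‖ + l_Alu) / (4‖r‖ + l_Alu) for a heterozygote under
uniform coverage (read length ‖r‖). Junction classes use relative
likelihoods 1 and PE = 0.001; spanning pairs use f_Y.

For insertions, discordant pairs with one mate in a known Alu ("D",
anchors classed la/ra by orientation) are swept for positions with
support(p) > n (n = 4), grouped into regions < 200 bp, merged across
individuals, and resolved by a two-level vote of split-mapped clipped
reads ("C") against a panel of Alu consensus sequences — first the modal
breakpoint per individual, then the modal position across individuals.
Genotypes follow by in-silico insertion: the deletion engine applied in
the frame where the element is present, with spanning inserts shifted by
δ = 300 bp.

A truth-aware simulator (`simulate_dataset()`) generates benchmark
populations — planted Alu loci at frequencies uniform on (0,1), diploids
assembled from haplotypes, reads with SNP/indel noise emitted directly
as sorted BAM — and `confusion_matrix()` / `sensitivity()` / `fdr()` /
`mendelian_violations()` score call sets against truth. See the methods
vignette (`vignettes/alu-genotyping-methods.Rmd`) for the full model.

## Worked example

Simulate a small cohort carrying recurring Alu deletions, genotype every
annotated locus, and score against the simulated truth:

```r
library(aluscan)

cfg <- sim_config(mode = "SimDel", ref_length = 3e5, n_loci = 6,
                  n_decoys = 12, n_haplotypes = 8, coverage = 25,
                  seed = 11)
ds <- simulate_dataset(cfg, "alu_demo")
print(ds$truth)

calls <- cmd_del(ds$fasta, ds$bams, ds$alu_bed, "alu_demo/calls.vcf")
print(calls)

ev <- cmd_eval(ds$truth_vcf, "alu_demo/calls.vcf")
print(ev$confusion)
```

which prints:

```
Simulated truth (SimDel): 6 loci x 4 individuals
  heterozygotes per individual: mean 1.25 (min 0, max 2)
  homozygotes per individual:   mean 2.25 (min 2, max 3)
[ind001] library ind001.lib1: E[Y] = 399.6, sd(Y) = 39.9
[ind002] library ind002.lib1: E[Y] = 400.2, sd(Y) = 39.7
[ind003] library ind003.lib1: E[Y] = 399.7, sd(Y) = 39.7
[ind004] library ind004.lib1: E[Y] = 399.9, sd(Y) = 39.7
processed 6 loci; 0 no-calls
Alu deletion calls: 6 loci x 4 samples
  genotypes called: 24 / 24 (100.0%)
  carrier genotypes: 14
sensitivity = 100.0%, FDR = 0.0%
Genotype confusion matrix (rows = truth, cols = predicted)
    predicted
true G0 G1 G2
  G0 10  0  0
  G1  0  5  0
  G2  0  0  9
TPN = 14, sensitivity = 100.0%, FDR = 0.0%
```

The truth summary lists the simulated event dosage per individual (a
carrier of one deleted haplotype is a heterozygote). Each library's
E[Y]/σ(Y) line is the insert-length model behind every likelihood; the
confusion matrix counts genotype predictions against truth (rows truth,
columns predictions), from which sensitivity
TPN/(TPN + C10 + C20) with TPN = C11 + C22 + C12 + C21, and FDR
(C01 + C02)/(TPN + C01 + C02) follow. Here every carrier is recovered
with the correct dosage and there are no false discoveries.

The insertion path runs the same way from a shell:

```sh
inst/scripts/aluscan ins --ref ref.fa --bams s1.bam,s2.bam \
    --alu-bed known_alus.bed --out insertions.vcf
```

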