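---
title: "Detecting and genotyping polymorphic Alu elements: methods"
author: "aluscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and genotyping polymorphic Alu elements: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Alu elements are ~300 bp primate retrotransposons that make up more than a
tenth of the human genome. Recently inserted copies are *polymorphic*:
present in some individuals, absent in others. With short-read paired-end
data, a polymorphic Alu shows itself in two ways: through read pairs whose
mapped insert length is shifted by the element length, and through reads
that cross an element boundary and align only partially. `aluscan` turns
both signals into diploid genotype calls, across many individuals at once,
for two complementary problems:

* the **deletion problem** — an Alu is annotated in the reference but
  missing from some haplotypes; every annotated locus is genotyped;
* the **insertion problem** — an Alu is present in some haplotypes but not
  in the reference; sites must first be discovered, then located
  base-precisely, then genotyped.

This vignette describes the models, the tunable parameters, the numerical
choices, and what the bundled simulator does and does not establish.

## The insert-length model

For a concordantly mapped pair r with left read r^L and right read r^R, the
insert length measured on the reference is

    Y(r) = end(r^R) - begin(r^L).

All likelihoods rest on the empirical distribution of Y, estimated per
sequencing library (read-group `LB`, falling back to the sample name) from
proper pairs in a single streaming pass capped at 10^6 pairs per library
(`estimate_insert_model()`). We record the sample mean E[Y] and standard
deviation sd(Y) and a smoothed empirical probability mass f_Y: a 1-bp
histogram over [max(0, E[Y] - 5 sd), E[Y] + 5 sd] with add-one smoothing
inside the support and a fixed floor of 1e-6 outside it. The floor keeps
outlying inserts from zeroing out a whole likelihood product; the add-one
smoothing keeps unobserved cells inside the support comparable to the
floor. A degenerate library with sd(Y) = 0 has its sd replaced by 1 bp so
that windows and supports stay non-empty. The quantity

    w = round(E[Y] + 3 sd(Y))

is the single source of truth for every window in the caller: the flank
width of deletion windows, the admissible anchor window of the insertion
scan, and the concordance cutoff. The choice of 3 standard deviations for
"concordant within a close distance" is ours; it keeps ~99.9% of proper
pairs concordant under an approximately normal insert distribution.

## Genotyping Alu deletions

Each annotated element [AL, AR) is examined inside the window
[FL, FR) = [AL - w, AR + w), clipped at chromosome bounds. Read pairs with
at least one read overlapping the window are classified:

* **I (internal)** — one mate in a flank, the other inside the element.
  Such fragments require the element to be present (allele H0).
* **S (split)** — a soft-clipped read whose aligned part ends at one
  breakpoint and whose clipped part realigns on the far side of the
  element (Smith–Waterman, match +1, mismatch -2, gap open -3, gap extend
  -1; at least 20 aligned bp on each side; clipped-part score >= 25). Such
  reads require the element to be absent (allele H1).
* **A (across)** — mates in the two flanks. The insert discriminates: it
  follows Y under H0 and Y + l_Alu under H1, so the H1 likelihood is
  f_Y(Y(r) - l_Alu), evaluated with the pair's own library density.

Pairs matching none of the classes are dropped; a confirmed split
outranks I/A (it is the strongest signal, and prevents double counting a
pair that satisfies two definitions). Per-pair allele likelihoods are
relative: junction classes get likelihood 1 for the allele they support
and PE = 0.001 (the misclassification/sequencing-error allowance) for the
other.

The joint likelihood of the read set R given genotype G_g (G0 = homozygote
Alu, G1 = heterozygote, G2 = homozygote non-Alu) assumes pairs are
independent:

    L(R | G_g) = prod_r [ L(r|H0) P(H0|G_g) + L(r|H1) (1 - P(H0|G_g)) ]

with P(H0|G0) = 1, P(H0|G2) = 0 and, for the heterozygote under uniform
coverage,

    P(H0|G1) = (2 r + l_Alu) / (4 r + l_Alu),

the fraction of informative fragment placements that fall on the longer
(Alu-carrying) haplotype; r is the per-sample modal read length. The call
is the maximum-likelihood genotype; quality is the phred-scaled
complement of the normalized posterior under a uniform prior, capped at
99. Loci with fewer than `min_evidence = 2` classified pairs, or exactly
tied likelihoods, are no-calls; exact ties break toward G0, the
reference-supporting state. One deliberate departure from a
flag-trusting implementation: spanning pairs of a deleted haplotype have
inserts near E[Y] + l_Alu and are flagged discordant by aligners, so the
deletion window admits pairs in +/- orientation regardless of the
proper-pair flag.

## Discovering and genotyping Alu insertions

Insertion sites are unknown a priori, so discovery precedes genotyping.

**Informative reads.** A **D** pair is discordant with exactly one read
overlapping an annotated Alu; the other read (the *anchor*) is kept if it
lies outside annotated elements, classed `la` when forward-mapped (the
insertion lies to its right) and `ra` when reverse-mapped. A **C** read
is soft-clipped by >= 10 bp with mean clipped-segment base quality >= 20
and anchor MAPQ >= 20 — the "good C read" thresholds are ours, as is the
optional `--unmapped-mates` rescue that aligns unmapped mates against the
consensus panel (score >= 25) for aligners that fail to place pure-Alu
mates.

**Support scan.** A position p covers an la anchor if
p in [end(r), begin(r) + w] and an ra anchor if
p in [end(r) - w, begin(r)]. Only candidate positions p = end(la) or
end(ra) are evaluated (sorted sweep, O(m log m + g)); positions with
support(p) > n (default n = 4) seed candidate regions built greedily with
span < 200 bp, so each region holds at most one insertion. Regions from
all individuals are pooled, traversed by begin position, and merged while
b_l < e_k and e_l - b_k < 200.

**Pooling.** Joint calling should find sites that no single individual
supports strongly. Requiring support > n per individual before merging
would make the merged set no more sensitive than its inputs, so the
multi-sample path prescans each individual at a permissive threshold
(`n_pre = 1`, i.e. two supporting reads) and applies the full threshold n
to the *pooled* support of the merged region. A site with three
supporting reads in each of two samples is thus recovered (pooled support
6 > 4) while remaining invisible to single-sample runs — the intended
pooling gain. Single-sample runs scan directly at n.

**Breakpoints.** Within each region, clipped segments of C reads from all
individuals are split-mapped: the anchored part keeps its reference
alignment, the clipped part is aligned to the consensus panel on both
strands. To bound the alignment work, the panel family is elected from
the up-to-24 longest clips against the full panel, and remaining reads
are confirmed against that family only (accepted at >= 60% of the
maximal score with >= 20 bp on each side). A read clipped on its right
side votes for a left breakpoint AL at its clip position; a left-side
clip votes for AR. Voting has two levels, AL and AR handled
independently: per individual the modal position (ties to the smaller
position), then across individuals the modal level-1 position (ties to
the larger total read support, then the smaller position). Regions where
neither side receives a vote are excluded. AL and AR may legitimately
differ — a target-site duplication puts AL to the right of AR by the
duplication length (reported as TSD), a target-site deletion does the
reverse — but sides more than 50 bp apart cannot belong to one clean
event, so only the better-voted side is kept. Compound events
(novel sequence co-inserted with the Alu) surface as one-sided calls by
construction. Adjacent regions occasionally elect the same breakpoint;
calls within 50 bp collapse to the best-supported one.

**Genotyping by in-silico insertion.** With a breakpoint P fixed, imagine
the element inserted at P: in that coordinate frame the Alu is present,
and the deletion engine applies with the allele H0 = "element present" =
the carrier allele. Both D pairs (mate inside the inserted element) and
split-confirmed C reads (contiguous across the junction in the inserted
frame) are junction evidence *for* H0 and enter the engine as type I;
fragments counted in both sets are counted once. Concordant pairs
spanning P enter as type A with their observed insert shifted by
delta = 300 bp (a carrier fragment spans delta unrepresented bases, so
its reference insert is compressed by delta): the engine sees Y + delta,
giving likelihood f_Y(Y + delta) for the carrier allele and f_Y(Y) for
the reference allele. The heterozygote balance uses l_Alu := delta. The
fixed delta stands in for the unknown inserted length, which cannot be
measured without assembly. Engine genotypes map to insertion dosage
(engine G0, homozygote for the element, is the homozygous carrier) for
VCF output, where the ALT allele is the insertion.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `pe` | 0.001 | likelihood of a junction read under the wrong allele |
| flank/window `w` | E[Y] + 3 sd(Y) | window half-width, concordance cutoff, anchor window |
| `n` | 4 | support threshold (exceeded strictly) |
| `n_pre` | 1 | per-sample prescan threshold, multi-sample mode |
| `region_len` | 200 bp | maximum candidate-region span |
| `delta` | 300 bp | assumed inserted Alu length for genotyping |
| `bp_tol` | 50 bp | maximum distance between AL and AR |
| `min_flank` | 20 bp | aligned bases required on each side of a split |
| `min_score` | 25 | split realignment score (match +1, mismatch -2, gap -3/-1) |
| `min_clip` | 10 bp | minimum soft clip for a C read / split attempt |
| `min_clip_qual` | 20 | mean base quality of the clipped segment |
| `min_anchor_mapq` | 20 | anchor mapping quality |
| `min_evidence` | 2 | classified fragments required for a genotype call |
| `min_pairs` | 1000 | concordant pairs required per library |

## The simulator and what it establishes

`simulate_dataset()` builds truth-known benchmark populations in the
recurring-Alu design: a seeded random background sequence in place of a
human chromosome (removing any download), `n_decoys` fixed Alu copies
diverged 5–15% from the consensus panel (the mapping targets for reads
inside inserted elements, and the "known Alu" annotation of the insertion
path), and `n_loci` polymorphic target Alus diverged 2%, all separated by
at least 600 bp. Locus frequencies are uniform on (0, 1); each of
`n_haplotypes` (default 200) haplotypes carries each event independently
at its frequency, consecutive haplotypes pair into diploids — with 100
loci this gives about 33 heterozygous and 33 homozygous events per
individual in expectation. SNPs (1e-3/bp) and geometric-length indels
(1e-4/bp, length ~ 1 + Geom(0.7)) are injected per haplotype; these
noise rates are our own choices, as the originals behind the published
benchmark are not printed.

Read pairs are drawn uniformly along each haplotype with insert lengths
Normal(400, 40) truncated above twice the read length (100 bp), and
written directly as coordinate-sorted BAM in working-reference
coordinates by an internal aligner-emulator: small indels become I/D
CIGAR operations, reads crossing an Alu junction are soft-clipped on the
shorter side (one primary record, the representation the split
realigner consumes), pairs spanning a deleted element carry the shifted
insert and lose the proper flag, and reads fully inside an inserted
element map to a random decoy of the same family (or stay unmapped under
`map_alu_mates = "unmapped"`). Base call errors are uniform
substitutions at 1e-3 with constant quality Q35.

The simulator reproduces the geometric and distributional signals the
caller uses; it does **not** model sequencing error profiles, quality
decay, PCR duplicates, GC bias, alignment ambiguity beyond the decoy
mechanism, reference gaps, or the true Alu subfamily phylogeny (the
shipped panel is synthetic, eight Alu-like consensus families sharing an
alignable ~300 bp body and poly-A tail). Recovery results on simulated
data therefore demonstrate the correctness of the algorithms under their
own model assumptions, not performance on real libraries, where mapping
artifacts near repeats are the dominant error source.

Validation in the test suite runs at a reduced scale chosen to exercise
every code path with comfortable margins: a 1 Mb reference, 20 loci, 40
decoys, 20 diploid individuals, at 25x and 10x coverage. At that scale
the deletion path recovers >= 95% of truth genotypes with zero false
discoveries and the insertion path reaches sensitivity >= 0.85 with FDR
<= 0.02 and breakpoints within 5 bp at >= 90% of detected sites;
`scripts/acceptance.R` recomputes these quantities from scratch.

## Numerical and degenerate-input choices

* Histogram density: 1-bp bins, add-one smoothing, floor 1e-6 outside
  [E - 5 sd, E + 5 sd]; sums to 1 over its support.
* sd(Y) = 0 is replaced by 1 bp; insert models refuse libraries with
  fewer than `min_pairs` concordant pairs, naming the library.
* Empty read sets give log-likelihoods (0, 0, 0) and a no-call; the
  empty annotation gives a header-only VCF.
* Voting ties: level 1 to the smaller position; level 2 to the larger
  supporting read count, then the smaller position — so permuting
  samples or reads never changes a call.
* Genotype ties break toward G0; phred qualities are capped at 99;
  PL values are scaled so the best genotype is 0.
* Coordinates are 0-based half-open internally, converted to 1-based
  only in VCF output.

## Known limitations

The deletion path only genotypes annotated loci; it discovers nothing.
The insertion path reports at most one event per 200 bp region, assumes
a fixed inserted length delta, and does not assemble the inserted
sequence or characterize compound insertions beyond the determinable
side. Only Alu-sized elements are considered; LINE elements, somatic
events, and duplicate marking are out of scope. Input alignments are
trusted as given.
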