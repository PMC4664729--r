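---
title: "Methods: parent-specific expression analysis in reciprocal hybrid crosses"
author: "crossbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parent-specific expression analysis in reciprocal hybrid crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbias)
```

## The design and the question

A reciprocal cross produces two F1 hybrid families from the same pair of
lineages: in one family (here called EA) the European lineage is the mother
and the Africanized lineage the father; in the other (AE) the roles are
reversed. Because every diagnostic SNP is heterozygous in all F1 offspring,
with the parental origin of each allele known, allele-specific read counts
separate two confounded phenomena:

* **parent-of-origin effects** — the maternal (or paternal) allele is
  preferred regardless of lineage, so the *same parental role* is favoured
  in both families; and
* **allele (lineage) effects** — one lineage's allele is preferred
  regardless of parent, so the bias appears *maternal in one family and
  paternal in the other*.

The package tests each gene for allelic bias within each family and sample
type, combines the two per-family states into a nine-way category system,
tests for differential total expression between the families, asks whether
bias categories are over-represented in QTL intervals or gene sets, and
scans for chromosomal clusters of extreme maternal bias. A synthetic data
generator with a complete truth table makes every stage testable end to end
without access to sequencing data.

## Per-gene allelic bias: a beta-binomial likelihood-ratio test

For one gene, family and sample type, let $m_i$ of $n_i$ informative reads
in replicate library $i$ support the maternal allele (counts are summed
over the gene's diagnostic SNPs within a library; the F1 design puts all of
a gene's SNPs in phase). The maternal fraction is
$b = \sum_i m_i / \sum_i n_i$: in the EA family the European-lineage reads
are maternal, in AE the Africanized-lineage reads are.

Replicate libraries are more variable than binomial sampling allows
(library construction, pooling of individuals), so the within-library
counts are modelled as beta-binomial with mean $\mu$ and intra-class
correlation $\rho \in [0, 1)$:
$m_i \sim \mathrm{BB}(n_i, \mu, \rho)$, which reduces to
$\mathrm{Binomial}(n_i, \mu)$ at $\rho = 0$. The test of allelic bias is a
likelihood-ratio test of

$$H_0:\ \mu = \tfrac12,\ \rho\ \text{free} \qquad \text{vs.} \qquad
  H_1:\ \mu,\ \rho\ \text{free},$$

with $\Lambda = 2(\hat\ell_1 - \hat\ell_0) \ge 0$ referred to
$\chi^2_1$. Keeping $\rho$ free under the null is deliberate: a gene whose
libraries disagree wildly should not be declared biased merely because its
pooled fraction drifts from one half.

Numerical choices:

* $\rho$ is profiled out by a coarse grid on $[0, 0.95]$ followed by local
  refinement; likelihood ties are broken toward the smaller $\rho$, so
  equidispersed data land exactly on the binomial boundary.
* For fixed $\rho$, the profile over $\mu$ is a bounded one-dimensional
  optimisation, with the pooled fraction checked as a boundary candidate.
* **Boundary rule.** When both fits sit at $\rho = 0$ (or the caller fixes
  $\rho = 0$) the model is a pooled binomial, and the reported p-value is
  the *exact* two-sided binomial test (probability-mass ordering) rather
  than the $\chi^2$ approximation. The approximation is inaccurate for the
  small and moderate totals common near the testability threshold (for
  example, 6 of 20 maternal reads: $\chi^2$ p = 0.070 against the exact
  0.115), while the exact tail is correct at every total and keeps null
  p-values conservative. With overdispersion present ($\hat\rho > 0$) no
  exact conditional test is available and the $\chi^2_1$ tail is used.
* With a single library the parent effect is confounded with
  overdispersion — the free-$\rho$ null can absorb any imbalance — so the
  estimated test is deliberately near-powerless at $L = 1$; fixing
  $\rho = 0$ recovers the classical binomial test when replicates are
  unavailable.

A combination is **testable** when its summed depth reaches
`min_total_reads` (default 20; below this the 60 % cutoff has essentially
no power, and the threshold also mimics the "insufficient read counts"
exclusions that motivate it). Benjamini–Hochberg FDR is applied within
each family × sample-type stratum, because each family's bias is assessed
on its own.

## Nine bias categories and consolidation

Within one sample type a family's state is **M** (maternal) when
$q \le 0.05$ *and* $b \ge \tau$, **P** when $q \le 0.05$ and
$b \le 1 - \tau$, and **N** otherwise; the default cutoff $\tau = 0.6$
("at least 60 % of reads from one parent") is inclusive. The pair
(state in EA, state in AE) maps bijectively to nine categories:

| state pair (EA, AE) | category | interpretation |
|---|---|---|
| M, M | `maternal_both` | parent-of-origin, maternal |
| P, P | `paternal_both` | parent-of-origin, paternal |
| M, N | `ea_maternal_only` | asymmetric maternal (EA family only) |
| N, M | `ae_maternal_only` | asymmetric maternal (AE family only) |
| P, N / N, P | `ea_paternal_only` / `ae_paternal_only` | asymmetric paternal |
| M, P | `european_allele` | lineage effect, European allele |
| P, M | `africanized_allele` | lineage effect, Africanized allele |
| N, N | `unbiased` | — |

A gene testable in only one family is *not* classified for that sample
type: the categories are defined on both families, and defaulting the
missing family to N would fabricate asymmetry. Across sample types a
single confident category dominates unbiased calls (a cluster member biased
in larvae but shallowly covered in brains is still that category), while
two *distinct* non-unbiased categories make the gene `MULTI`; MULTI genes
are excluded from enrichment cohorts. `cutoff_robustness()` re-runs the
whole classification over a cutoff grid; because the per-family gate is
monotone in $\tau$, biased cohorts can only shrink or migrate out of MULTI
as the cutoff rises.

## Differential expression between families

Family-level expression differences use a conditional exact test for
negative-binomial counts, fully specified at desk scale:

1. **Effective library sizes.** Each library's median-of-ratios factor is
   computed on depth-normalised counts (so it captures composition only),
   scaled to geometric mean one, and multiplied by the raw total.
2. **Common dispersion.** A method-of-moments estimate pools, over genes
   and replicated families, the residual variance in excess of the scaled
   Poisson component against squared means, floored at zero. There is no
   gene-wise shrinkage; the test family is small enough that a single
   common $\phi$ per sample type is the stable choice.
3. **Exact test.** Counts are quantile-mapped (mid-probability) to the
   geometric-mean library size, summed within families, and the two-sided
   p-value is the sum of conditional probabilities of all splits of the
   total that are as or less likely than the observed one. At $\phi = 0$
   with equal sizes this reduces exactly to binomial enumeration; the
   implementation agrees with an independent reference implementation of
   the same conditional test to $10^{-10}$.

Sample types are tested independently and BH-adjusted within sample type;
a gene is significant at $q \le 0.05$.

## Enrichment and clustering

Gene and QTL intervals are 0-based half-open; "in a QTL" means an overlap
of at least one basepair. Enrichment of a cohort (a bias category, or the
biased set as a whole) in a target (QTL trait class, gene set, or the
DE-gene set) is a $\chi^2$ goodness-of-fit test with one degree of
freedom, expecting $E = n \cdot m / N$ members from the universe
proportion. Both forms are always reported: the two-cell statistic
$(O-E)^2/E + (O-E)^2/(n-E)$ (the default), and the one-cell
$(O-E)^2/E$ used when only a direct expectation is available. Bonferroni
correction runs over the tests actually emitted.

The batch QTL scan additionally applies **Cochran's validity rule**: a
category × trait-class combination is tabulated but not tested when its
expected count is below `min_expected` (default 5, settable to 0). The
$\chi^2_1$ tail is anti-conservative for tiny expectations, and without
the floor the label-permutation family-wise error of the scan measurably
exceeds its nominal level (about 7 % at $\alpha = 5\%$ in 1000
permutations, 3.5 % with the floor). `enrichment_permutation_null()`
exposes that calibration check directly.

Cluster detection is an explicit scan rather than a model: on each
chromosome, maximal runs of consecutive *tested* genes whose maternal
fraction in the chosen family reaches `fraction_threshold` (default 0.9)
in at least one sample type, with inter-gene gaps of at most `max_gap_bp`
(default 250 kb), are reported when they contain at least
`min_cluster_size` genes (default 8). The defaults are set so that runs of
the size and span reported for the motivating system (about a dozen genes
across ~0.4–0.6 Mb, all >90 % maternal) are called as single clusters;
untested genes are ignored, so adding genes without usable counts cannot
break a run.

## The synthetic reciprocal cross

`sim_config()` describes a complete study and `simulate_cross_dataset()`
realises it: 2663 testable genes on 16 chromosomes of 12 Mb; per family
two larval pools, two guard (adult) pools and three individual brains;
per-SNP depth $\sim \mathrm{NB}(100, 0.3)$; allelic counts beta-binomial
with $\rho = 0.02$; biased genes at fraction $\mu_1 = 0.9$. Planted
category counts follow the motivating study where printed
(223 `ea_maternal_only`, 24 `ae_maternal_only`, 46 symmetric split
23/23); the remaining classes are free defaults chosen once so the biased
total lands near five hundred (120 `european_allele`,
30 `africanized_allele`, 20/16 paternal-only). Two clusters are planted
(13 genes / 410 kb and 29 genes / 600 kb) at fraction 0.95, matching the
report of >90 % maternal bias for essentially all tested cluster members.
QTL intervals cover roughly 16 %, 11 % and 6 % of the genome for defense,
reproduction and foraging, with planted assignment odds of 2 for
`ea_maternal_only` in defense QTL and 3 for `european_allele` in foraging
QTL — the same direction and magnitude as the observed/expected ratios in
the study. Differential expression plants 160 genes, 101 of them beyond
twofold (|log2 fc| drawn in [1.1, 2], the rest in [0.4, 0.9]), each acting
in one sample type.

The generator emulates *count structure*, not sequences: no reads, no
alignment artifacts, no allelic mapping bias, no correlated dispersion
across genes, and a single genome-wide $\rho$. Recovery results on
synthetic data therefore demonstrate that the pipeline's inference is
correct under its own model assumptions and calibrated under the null —
not that real libraries satisfy those assumptions. Two known behavioural
differences from the motivating data: per-library depth and
overdispersion defaults are free choices (the study does not print them),
and the generator's MULTI genes arise from significance dropout in the AE
family (so they persist when the cutoff rises), whereas the study's MULTI
genes sat near the 60 % cutoff and mostly vanished at 70 %.

Determinism: every stage derives its RNG stream from the configuration
seed, so identical configurations yield byte-identical datasets and
artifacts.

## Problem sizes and runtime choices

The test suite exercises the full study scale where the claim depends on
it (category recovery, null false-positive control, cluster recovery and
permutation calibration all run at 2663 genes with the default library
design; permutation calibration uses 1000 shuffles; oracle equivalence
sweeps every total up to 200 for the allelic test and every split of
totals up to 40 for the expression test) and small configurations of
40–800 genes elsewhere. The power property asserted for differential
expression reflects the Monte-Carlo power of the default design — with
common dispersion 0.1 and two to three replicates per family,
more-than-twofold effects are recovered at roughly 40 % and sub-twofold
effects rarely — rather than a nominal figure.

## Limitations

* The beta-binomial LRT stands in for the original study's proprietary
  mixed-model analysis; both target a parent effect on allele usage gated
  at FDR 0.05, but numerical equality with the original is not claimed,
  and the exact structure of that model is not public.
* The common-dispersion exact test likewise approximates a commercial
  implementation whose normalisation defaults are undocumented.
* A gene testable in only one family cannot be classified; cohorts
  therefore depend on coverage in *both* families.
* The $\chi^2$ enrichment framework assumes genes are exchangeable units;
  physically clustered genes violate independence, which is precisely why
  cluster membership is reported alongside enrichment rather than folded
  into it.
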