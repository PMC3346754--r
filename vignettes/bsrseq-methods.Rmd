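---
title: "Mapping causal mutations with pooled RNA-Seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping causal mutations with pooled RNA-Seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsrseq)
```

## The problem

Bulked segregant analysis (BSA) maps a recessive mutation by comparing two
pools of siblings from a segregating F2 family: one pool of individuals
expressing the mutant phenotype (all homozygous for the causal allele) and
one pool of their non-mutant siblings. Markers tightly linked to the causal
locus are fixed in the mutant pool and segregate 1:2 in the non-mutant pool;
unlinked markers segregate 1:1 in both. Doing BSA on RNA-Seq reads (BSR-Seq)
yields SNP genotypes, pool allele counts, and expression levels from a
single experiment — but RNA-level allele frequencies are distorted by
allele-specific expression (ASE) and sampling noise, so naive frequency
cutoffs misbehave. The package implements an empirical-Bayes treatment of
exactly this problem, plus the surrounding pipeline: SNP discovery from
pileups, a sliding-window genome scan, Fisher-exact differential expression
between pools, and a full simulator of the experiment.

## SNP discovery filters

Calls from both pools are merged per site. A base is a candidate allele iff
it has at least 3 calls of base quality ≥ 15 and those calls are ≥ 20% of
the quality-passing calls at the site; a site is a SNP iff exactly two
candidates exist and together they carry ≥ 90% of the quality-passing
calls. Design choices:

* a low-fraction third base (sequencing error) does not veto a site — it
  only counts against the 90% off-type budget; the per-allele thresholds
  define candidacy, the 90% rule guards total off-type mass;
* all fraction thresholds are inclusive (≥), and calls below quality 15 are
  excluded from numerators *and* denominators — the simplest single
  convention covering all four rules;
* alleles are stored in lexicographic order; reference/alternate labels are
  never needed.

After allele-specific quantification per pool, a SNP enters the linkage
computation only if both pools have ≥ 5 reads over the two alleles and both
alleles appear at least once in the non-mutant pool (`bsr_eligible()`);
fixation in the *non-mutant* pool carries no linkage information and breaks
the 1:2 expectation the second stage uses.

Aligned-read filtering keeps uniquely mapped reads with at most 2
mismatches per 36 aligned bases (indels count as mismatches); for a read of
length L the allowance is prorated as floor(2L/36).

## The two-stage linkage statistic

For each eligible SNP, with $x_1 \ge x_2$ the two allele counts in the
mutant pool and $n = x_1 + x_2$:

**Stage 1 — no recombination in the mutant pool.** The mutant pool carries
$2N$ gametes ($N$ plants). Under complete linkage every gamete carries the
coupled allele, so $P(x \mid \text{noR}) = 1$ iff $x_2 = 0$ and $0$
otherwise. Under recombination, $x_1 \sim \mathrm{Binomial}(n, p)$ with the
success probability $p$ unknown and SNP-specific. We give $p$ a discrete
empirical prior built from the non-mutant pool: every SNP with non-mutant
depth ≥ 5 contributes its two observed non-zero allele relative frequencies
as equally weighted atoms. Then

$$P(\text{noR} \mid x) = \frac{\pi_{\text{noR}}}
 {\pi_{\text{noR}} + (1-\pi_{\text{noR}}) \sum_j w_j p_j^{\,n}}$$

for monoallelic sites, and exactly 0 otherwise. The prior
$\pi_{\text{noR}}$ integrates the Haldane no-recombination probability
$(1-r(d))^{2N}$, $r(d) = (1-e^{-2d})/2$, against a uniform density for the
SNP–locus distance $d$ on $(0, d_{\max}]$ with $d_{\max} = 0.2$ Morgans by
default: the integrand is negligible beyond a few cM for realistic $N$, so
the result is insensitive to $d_{\max}$. The integral is a composite
trapezoid over 10,001 nodes, accurate to well below $10^{-6}$ for this
smooth integrand (verified against a $10^6$-node Riemann oracle in the
tests).

**Stage 2 — the mutant allele is the rarer one where it should be.** Near
the causal locus the non-mutant pool is 1/3 mutant-coupled alleles at the
DNA level, so the mutant allele's *expression* share $p$ should satisfy
$p \le 1/2$ even under moderate ASE. With $y_1$ reads of the mutant allele
(the major mutant-pool allele) among $m$ non-mutant-pool reads,

$$P(p \le 1/2 \mid y_1, m) =
 \frac{\sum_{j:\,p_j \le 1/2} w_j \binom{m}{y_1} p_j^{y_1}(1-p_j)^{m-y_1}}
      {\sum_j w_j \binom{m}{y_1} p_j^{y_1}(1-p_j)^{m-y_1}},$$

with the same empirical prior and atoms at exactly 0.5 counted in the
numerator. The final linkage probability is the product of the two
posteriors. The empirical prior is what makes the statistic robust to ASE:
a monoallelic unlinked site is explained by the prior's atoms at 1.0 (such
sites exist genome-wide), so stage 1 does not over-reward it, and a site
whose mutant allele is *over*-expressed in the non-mutant pool is penalized
by stage 2.

Numerical notes: all binomial pmfs are evaluated in log space and
mixed with a log-sum-exp; atoms with identical frequency are merged with
summed weight (pure computational compression, the distribution is
unchanged). The prior defaults to *all* discovered SNPs with non-mutant
depth ≥ 5 — before the both-alleles eligibility rule — precisely so that
monoallelic-expression atoms at 1.0 are retained; `prior_source =
"eligible"` selects the restricted variant. We reuse the non-zero-frequency
atom rule for both stages: atoms at 0 would contribute zero likelihood for
any $y_1 > 0$ and a degenerate spike otherwise.

Tie-breaks: the mutant allele is the major mutant-pool allele; on a tie,
the allele rarer in the non-mutant pool, then `allele_a`. Ties imply
$x_2 > 0$, hence a zero stage-1 posterior, so the choice never affects
results.

## Genome scan

Final probabilities are summarized in sliding windows of 50 SNPs with a
step of 5, per chromosome (a window spanning chromosomes would be
meaningless); the window statistic is the median, its position the mean of
the first and last SNP positions. The even-size median is the mean of the
two central order statistics. The reported locus interval is the union span
of the top 10 windows by median (ties broken toward smaller positions);
when the top windows split across chromosomes the interval is restricted to
the best window's chromosome, with a warning. The median over 50 SNPs is
what buys robustness: isolated ASE-driven monoallelic sites cannot lift a
window unless more than half its SNPs are affected.

## The simulator

`simulate_bsrseq()` generates the full experiment the analysis assumes: two
parental haplotypes, F2 individuals as pairs of independent gametes
generated marker-to-marker with switch probability equal to the Haldane
recombination fraction of the inter-marker distance (a first-order Markov
chain, exact under no interference — no explicit crossover process is
needed), a recessive phenotype (homozygous carriers of the coupled
haplotype at the causal position), pools of 32 mutants and 31 non-mutants
sampled from 200 F2 progeny, optional misclassification of mutant-pool
slots, and read counts that are binomial draws from the pool haplotype
frequency at negative-binomial depth (mean 20, dispersion 5 by default;
dispersion `Inf` gives Poisson for clean unit-test arithmetic). ASE is a
cis effect: a fraction of SNPs (default 0.1) gets a per-SNP favored allele
whose haplotypes emit reads with weight $s/(1-s)$, $s = 0.8$ by default
(0.9 in the stress tests), shared between pools.

**Genome scale.** The default map is a density-preserving scale-down. The
window statistic's behavior is governed by marker density per centimorgan:
deep RNA-Seq of a maize-sized genome yields roughly 40 usable SNPs per cM
(tens of thousands of SNPs over a ~1,500 cM map), so a 50-SNP window spans
about 1 cM — comparable to the ~1–2 cM over which a 32-plant mutant pool
stays fixed. The simulator keeps that density and shrinks the genome about
30-fold: ten chromosomes of 5 cM / 6 Mb, 200 markers each (2,000
genome-wide), causal locus mid-chromosome 4. Pool sizes, depth, and the
recombination process are at full scale. A "full-length" map with only
2,000 SNPs would put ~0.5 cM between markers and make every 50-SNP window
span ~25 cM, destroying the median signal — a property of marker density,
not of the method. Consequences for interpretation: passing tests show the
statistic recovers a locus under the stated density, depth and pool sizes;
they do not exercise reference-genome artifacts, paramorphic paralogs
(handled in practice via the blacklist), uneven marker spacing, or
base-level sequencing error (subsumed by the skew/depth model).

## Differential expression between pools

Reads are counted per gene by any-overlap of the aligned span with the gene
model. Genes with fewer than 40 combined reads are excluded from testing
entirely (no p, no q — they cannot dilute the Benjamini–Hochberg
adjustment, which runs over tested genes only). Each tested gene gets a
two-sided Fisher exact p-value on (gene reads vs remaining reads) × (pool),
using the probability-mass definition of extremeness. A gene is significant
iff q ≤ 0.001 and |log2 fold change| > 0.8, where the fold change is
computed on counts scaled to the smaller library's total, plus 1: the
pseudocount scale matters near zero counts, and the smaller-library scale
keeps the pseudocount's weight comparable across pools (`ref_total` is
exposed for other conventions). RPKM (reads per kb exon per million mapped)
is reported when exon lengths are known.

Because the design is unreplicated, the test measures *reproducibility of
proportions*, not biological variability; with strong DE a second
composition effect appears (DE genes inflate one library's total and shift
every other gene's proportion), which is a property of the method, not a
bug. The chromosome-level down/up bias check (`region_bias_test`) is the
Pearson chi-square with 1 df and no continuity correction on the in/out
region 2×2 table of significantly down- vs up-regulated genes.

## Problem sizes and determinism

Test and example problem sizes were chosen to exercise the estimators at
realistic pool sizes and depths while completing quickly: 10,000 F2
individuals for segregation checks, 50 simulation replicates for locus
recovery (each well under a second), 20 for the ASE stress test, 5,000
genes for DE calibration, and exhaustive Fisher-oracle verification over
all 2×2 tables with total ≤ 60. All randomness flows through a single seed
per simulated experiment; the same configuration and seed reproduce every
output table bit for bit.

## Known limitations

* Dominant traits, QTL, backcross/RIL designs and mutant-pool
  misclassification corrections are out of scope (the misclassification
  *simulator* knob exists to study robustness, but the statistic itself
  assumes a fixed mutant pool).
* No formal credible interval for the locus — the top-window span is an
  operational interval, not a posterior region.
* Indels and multi-allelic sites are not called.
* The DE stage inherits every caveat of unreplicated count comparisons.
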