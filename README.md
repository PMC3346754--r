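# bsrseq

Maps recessive causal mutations from pooled RNA-Seq of a segregating F2
population — bulked segregant analysis on RNA-Seq reads (BSR-Seq). One
sequencing experiment on two pools (phenotypically mutant F2 individuals
vs their non-mutant siblings) yields SNP genotypes, pool allele counts and
expression levels; this package turns those into a genome location for the
mutation and a differential-expression profile. It is aimed at geneticists
mapping EMS/transposon-induced recessive mutants in crops or other crossing
species, and at methodologists who want a fully simulated test bed for
pooled-sequencing linkage statistics.

## The statistic

For each biallelic SNP with mutant-pool allele counts `x1 >= x2`
(`n = x1 + x2`) and non-mutant-pool counts `y1` (mutant allele) of `m`, the
linkage score is the product of two posteriors:

1. **No recombination in the mutant pool.** With N plants in the mutant
   pool (2N gametes), complete linkage forces `x2 = 0`, so

   `P(noR | x) = pi / (pi + (1 - pi) * sum_j w_j p_j^n)` if `x2 = 0`, else 0,

   where `pi` integrates the Haldane no-recombination probability
   `(1 - r(d))^(2N)`, `r(d) = (1 - exp(-2d))/2`, over a uniform prior for
   the SNP–locus distance `d` in (0, 0.2] Morgans, and `{p_j, w_j}` is an
   empirical prior over allele expression proportions: the observed
   non-zero allele relative frequencies at every SNP in the non-mutant
   pool. The empirical prior absorbs allele-specific expression — a
   monoallelic unlinked SNP is not surprising under recombination, because
   atoms at 1.0 exist genome-wide.

2. **Mutant allele under-expressed in the non-mutant pool.** Near the locus
   the non-mutant pool is 1:2 mutant:wildtype at the DNA level, so
   `P(p <= 1/2 | y1, m)` is computed under the same empirical prior.

A sliding window of 50 SNPs (step 5) per chromosome summarizes the final
probabilities by their median; the span of the top 10 windows is the
reported interval. A Fisher-exact stage tests per-gene read proportions
between pools (tested genes: ≥ 40 combined reads; significant: BH q ≤ 0.001
and |log2FC| > 0.8).

A full F2 simulator (Haldane-model meiosis, pool construction, ASE-skewed
binomial read sampling) generates every input, so the whole pipeline is
testable without sequencing data.

## Worked example

```r
library(bsrseq)

cfg  <- sim_config(seed = 42)           # 10 chr x 200 SNPs, causal on chr4 at 3 Mb
expt <- simulate_bsrseq(cfg)            # F2 of 200, pools of 32 + 31, depth ~20x
lk   <- linkage_probabilities(expt$snps, n_plants = 32)
head(lk[order(-lk$final), c("chrom", "pos", "n", "m", "x2",
                            "post_no_recomb", "post_p_le_half", "final")], 5)
#>     chrom     pos  n  m x2 post_no_recomb post_p_le_half final
#> 647  chr4 2170855 49 18  0          0.933          0.998 0.932
#> 717  chr4 4371860 40 30  0          0.931          0.997 0.928
#> 718  chr4 4402010 31 32  0          0.925          1.000 0.925
#> 666  chr4 2773870 30 34  0          0.924          0.998 0.922
#> 767  chr4 6000000 28 26  0          0.922          1.000 0.921

peak_interval(sliding_windows(lk, 50, 5), top_k = 10)
#> peak interval: chr4:150,755-5,909,548 (10 top windows)
```

Every top SNP sits on chromosome 4 with a monoallelic mutant pool
(`x2 = 0`); `post_no_recomb` is bounded near 0.93 here because the
no-recombination prior for a 32-plant pool is `prior_no_recomb(32) ≈
0.0794` and ~20–50 reads of evidence can only push it so far — ranking, not
calibration, is what the scan uses. The reported interval contains the true
simulated locus (chr4:3,000,000). SNPs with both alleles in the mutant pool
get a final probability of exactly 0.

The same stages are scriptable from a shell via the thin CLI in
`inst/cli/bsrseq.R` (subcommands `simulate`, `call-snps`, `map`, `scan`,
`dge`, `run-all`), or in one call with `run_bsrseq(config, out_dir)`.

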