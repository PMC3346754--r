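test_that("alignment filter applies the prorated per-36bp mismatch allowance", {
  reads <- data.frame(
    read_id = paste0("r", 1:4), chrom = "chr1", start = 1L,
    aligned_length = c(36L, 36L, 75L, 75L),
    mismatches = c(2L, 3L, 5L, 0L),
    unique = c(TRUE, TRUE, TRUE, FALSE))
  # 36 bp allows 2; 75 bp allows floor(2*75/36) = 4; non-unique always drops
  expect_equal(filter_alignments(reads), c(TRUE, FALSE, FALSE, FALSE))
  expect_true(filter_alignments(transform(reads[3, ], mismatches = 4L)))
  expect_error(filter_alignments(transform(reads, aligned_length = 0L)),
               "positive")
})

test_that("single-site SNP calling applies all four thresholds inclusively", {
  q <- function(n) rep(30, n)
  # third base below per-allele thresholds does not veto; 15/16 >= 90%
  expect_equal(call_snp_site(rep(c("A", "C", "G"), c(10, 5, 1)), q(16)),
               c("A", "C"))
  # an allele with < 3 reads is not a candidate
  expect_null(call_snp_site(rep(c("A", "C"), c(10, 2)), q(12)))
  # three passing candidates violate the two-allele rule
  expect_null(call_snp_site(rep(c("A", "C", "G"), c(5, 4, 3)), q(12)))
  # 18/20 = 90% exactly: boundary is inclusive
  expect_equal(call_snp_site(rep(c("A", "C", "G"), c(9, 9, 2)), q(20)),
               c("A", "C"))
  expect_null(call_snp_site(character(), numeric()))
})

test_that("low-quality calls are excluded from numerators and denominators", {
  base <- rep(c("A", "C", "G"), c(6, 4, 30))
  qual <- c(rep(30, 10), rep(10, 30))  # all G calls fail q >= 15
  expect_equal(call_snp_site(base, qual), c("A", "C"))
  expect_null(call_snp_site(base, rep(30, 40)))
})

test_that("site calling is invariant to call order and matches brute force", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(0:25, 1)
    base <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                   prob = c(0.45, 0.35, 0.15, 0.05))
    qual <- sample(c(5, 20, 40), n, replace = TRUE)
    got <- call_snp_site(base, qual)
    want <- brute_call(base, qual)
    expect_identical(got, want)
    perm <- sample(n)
    expect_identical(call_snp_site(base[perm], qual[perm]), got)
  }
})

test_that("adding a read of the minor allele never un-calls a SNP", {
  # the minor candidate gains fraction, the major stays above 20% because a
  # called site has top-two fraction >= 90%, and off-type mass shrinks
  set.seed(7)
  for (i in 1:200) {
    counts <- c(A = sample(3:15, 1), C = sample(3:15, 1),
                G = sample(0:1, 1))
    base <- rep(names(counts), counts)
    qual <- rep(30, length(base))
    alleles <- call_snp_site(base, qual)
    if (is.null(alleles)) next
    minor <- alleles[which.min(counts[alleles])]
    expect_equal(call_snp_site(c(base, minor), c(qual, 30)), alleles)
  }
})

test_that("two clean alleles with enough reads and fraction always call", {
  set.seed(11)
  for (i in 1:100) {
    a <- sample(3:30, 1)
    b <- sample(3:30, 1)
    if (min(a, b) / (a + b) < 0.20) next
    base <- rep(c("G", "T"), c(a, b))
    expect_equal(call_snp_site(base, rep(30, a + b)), c("G", "T"))
  }
})

test_that("pileup discovery quantifies alleles per pool and ignores off-types", {
  pu <- rbind(
    pileup_site(c(A = 12), pool = "mut", pos = 100),
    pileup_site(c(A = 6, C = 6), pool = "wt", pos = 100),
    pileup_site(c(A = 5, C = 5), pool = "mut", pos = 200),
    pileup_site(c(A = 4, C = 4, T = 2), pool = "wt", pos = 200))
  snps <- discover_snps(pu)
  expect_equal(nrow(snps), 2)
  s1 <- snps[snps$pos == 100, ]
  expect_equal(c(s1$mut_a, s1$mut_b, s1$wt_a, s1$wt_b), c(12, 0, 6, 6))
  # T calls at pos 200 fail the per-allele rules and are not quantified
  s2 <- snps[snps$pos == 200, ]
  expect_equal(c(s2$allele_a, s2$allele_b), c("A", "C"))
  expect_equal(c(s2$mut_a, s2$mut_b, s2$wt_a, s2$wt_b), c(5, 5, 4, 4))
})

test_that("blacklisting removes exact sites and preserves order", {
  snps <- snp_table(c(5, 6, 7), c(0, 1, 2), c(3, 3, 3), c(3, 3, 3),
                    chrom = "chr1", pos = c(10, 20, 30))
  bl <- data.frame(chrom = "chr1", pos = 20)
  expect_equal(apply_blacklist(snps, bl)$pos, c(10, 30))
  expect_equal(apply_blacklist(snps, bl[0, ]), snps)
  expect_equal(nrow(apply_blacklist(snps, snps[c("chrom", "pos")])), 0)
  # same position on another chromosome is untouched
  bl2 <- data.frame(chrom = "chr2", pos = 20)
  expect_equal(apply_blacklist(snps, bl2), snps)
})

test_that("linkage eligibility needs depth 5 in both pools and both wt alleles", {
  snps <- snp_table(mut_a = c(12, 3, 12, 12),
                    mut_b = c(0, 1, 0, 0),
                    wt_a = c(6, 6, 10, 4),
                    wt_b = c(4, 4, 0, 0))
  expect_equal(bsr_eligible(snps), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("eligible SNPs have non-mutant allele frequencies strictly inside (0,1)", {
  set.seed(5)
  snps <- snp_table(mut_a = sample(0:20, 200, TRUE),
                    mut_b = sample(0:20, 200, TRUE),
                    wt_a = sample(0:20, 200, TRUE),
                    wt_b = sample(0:20, 200, TRUE),
                    chrom = "chr1", pos = 1:200)
  el <- snps[bsr_eligible(snps), ]
  f <- el$wt_a / (el$wt_a + el$wt_b)
  expect_true(all(f > 0 & f < 1))
})
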