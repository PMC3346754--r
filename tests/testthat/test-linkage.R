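test_that("Haldane map function has the right limits and closed form", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(10), 0.5, tolerance = 1e-8)
  expect_equal(haldane(0.2), (1 - exp(-0.4)) / 2)
  expect_error(haldane(-0.1), "non-negative")
})

test_that("no-recombination probability is monotone in distance and pool size", {
  d <- seq(0, 0.5, by = 0.01)
  p <- prob_no_recomb_given_d(d, 32)
  expect_equal(p[1], 1)
  expect_true(all(diff(p) < 0))
  expect_true(all(prob_no_recomb_given_d(0.1, c(1, 8, 32)) ==
                    sort(prob_no_recomb_given_d(0.1, c(1, 8, 32)),
                         decreasing = TRUE)))
  # 2 gametes at the r = 0.5 asymptote: (1 - 0.5)^2
  expect_equal(prob_no_recomb_given_d(50, 1), 0.25, tolerance = 1e-8)
})

test_that("trapezoid prior integral matches a fine midpoint Riemann sum", {
  riemann <- function(N, d_max, nodes = 2e5) {
    h <- d_max / nodes
    mid <- (seq_len(nodes) - 0.5) * h
    sum((1 - haldane(mid))^(2 * N)) * h / d_max
  }
  for (N in c(1, 32)) {
    expect_lt(abs(prior_no_recomb(N) - riemann(N, 0.2)), 1e-6)
  }
  # shrinking the neighborhood toward zero drives the prior to 1
  expect_gt(prior_no_recomb(32, d_max = 1e-6), 0.9999)
  expect_lt(prior_no_recomb(64, 0.2), prior_no_recomb(8, 0.2))
})

test_that("empirical prior collects non-zero non-mutant allele frequencies", {
  snps <- snp_table(mut_a = c(10, 10), mut_b = c(0, 0),
                    wt_a = c(6, 10), wt_b = c(4, 0))
  pr <- empirical_prior(snps, min_depth = 5)
  expect_equal(pr$p, c(0.4, 0.6, 1.0))
  expect_equal(pr$w, rep(1 / 3, 3))

  # both alleles at 0.5 merge into one atom of full weight
  pr2 <- empirical_prior(snp_table(10, 0, 5, 5), min_depth = 5)
  expect_equal(pr2$p, 0.5)
  expect_equal(pr2$w, 1)

  # zero frequencies are discarded entirely
  pr3 <- empirical_prior(snp_table(10, 0, 0, 8), min_depth = 5)
  expect_equal(pr3$p, 1.0)

  expect_error(empirical_prior(snp_table(10, 0, 2, 1), min_depth = 5),
               "no SNPs")
})

test_that("mixture likelihood matches hand binomials and normalizes", {
  expect_equal(lik_counts_given_recomb(2, 4, make_prior(0.5)),
               choose(4, 2) * 0.5^4)
  expect_equal(lik_counts_given_recomb(7, 7, make_prior(1.0)), 1)
  pr <- make_prior(c(0.1, 0.45, 0.8), c(2, 1, 3))
  expect_equal(sum(lik_counts_given_recomb(0:9, 9, pr)), 1)
})

test_that("stage-1 posterior follows the Bayes formula and its structural zero", {
  # both alleles in the mutant pool: posterior exactly 0
  expect_identical(posterior_no_recomb(7, 3, 0.3, make_prior(0.5)), 0)
  # monoallelic: pi / (pi + (1 - pi) * p^n) for a one-atom prior
  expect_equal(posterior_no_recomb(10, 0, 0.5, make_prior(0.5)),
               0.5 / (0.5 + 0.5 * 0.5^10))
  # a prior concentrated at 1 makes the likelihoods equal: posterior = pi
  expect_equal(posterior_no_recomb(10, 0, 0.37, make_prior(1.0)), 0.37)
  expect_error(posterior_no_recomb(0, 0, 0.5, make_prior(0.5)), "no mutant")
})

test_that("stage-1 posterior grows with monoallelic depth", {
  pr <- make_prior(c(0.2, 0.5, 0.8))
  post <- posterior_no_recomb(1:30, rep(0, 30), 0.2, pr)
  expect_true(all(diff(post) > 0))
  expect_true(all(post > 0 & post < 1))
})

test_that("mutant allele is the major mutant-pool allele with tie-breaks", {
  snps <- snp_table(mut_a = c(12, 5, 5), mut_b = c(0, 5, 5),
                    wt_a = c(5, 8, 4), wt_b = c(5, 2, 4))
  expect_equal(identify_mutant_allele(snps), c("a", "b", "a"))
})

test_that("stage-2 posterior handles pure, mixed and boundary priors", {
  expect_equal(posterior_p_le_half(3, 10, make_prior(c(0.2, 0.4))), 1)
  expect_equal(posterior_p_le_half(3, 10, make_prior(0.75)), 0)
  pr <- make_prior(c(0.25, 0.75))
  want <- dbinom(2, 10, 0.25) / (dbinom(2, 10, 0.25) + dbinom(2, 10, 0.75))
  expect_equal(posterior_p_le_half(2, 10, pr), want)
  # an atom exactly at 0.5 counts toward p <= 1/2
  expect_equal(posterior_p_le_half(5, 10, make_prior(0.5)), 1)
  expect_error(posterior_p_le_half(3, 10, make_prior(1.0)), "degenerate")
})

test_that("posteriors match exhaustive summation oracles on small problems", {
  set.seed(13)
  for (i in 1:25) {
    k <- sample(1:5, 1)
    pr <- make_prior(runif(k), runif(k) + 0.1)
    n <- sample(1:12, 1)
    pi0 <- runif(1, 0.05, 0.95)
    # oracle: plain loops over atoms, no shared code with the implementation
    lik_r <- 0
    for (j in seq_len(k)) lik_r <- lik_r + pr$w[j] * pr$p[j]^n
    expect_equal(posterior_no_recomb(n, 0, pi0, pr),
                 pi0 / (pi0 + (1 - pi0) * lik_r), tolerance = 1e-12)
    y1 <- sample(0:n, 1)
    num <- den <- 0
    for (j in seq_len(k)) {
      pmf <- choose(n, y1) * pr$p[j]^y1 * (1 - pr$p[j])^(n - y1)
      den <- den + pr$w[j] * pmf
      if (pr$p[j] <= 0.5) num <- num + pr$w[j] * pmf
    }
    expect_equal(posterior_p_le_half(y1, n, pr), num / den,
                 tolerance = 1e-12)
  }
})

test_that("linkage table computes the product and zeroes biallelic mutant sites", {
  snps <- snp_table(mut_a = c(12, 8, 9), mut_b = c(0, 3, 0),
                    wt_a = c(4, 6, 3), wt_b = c(6, 5, 7),
                    chrom = "chr1", pos = c(10, 20, 30))
  lk <- linkage_probabilities(snps, n_plants = 32)
  expect_equal(nrow(lk), 3)
  expect_equal(lk$final, lk$post_no_recomb * lk$post_p_le_half)
  expect_equal(lk$final[lk$x2 > 0], 0)
  expect_true(all(lk$final >= 0 & lk$final <= 1))
  # mutant allele of the fixed sites is the fixed one; y1 uses its wt count
  expect_equal(lk$mutant_allele, c("A", "A", "A"))
})

test_that("SNPs tightly linked to the causal locus outscore unlinked ones", {
  deltas <- numeric()
  for (s in 1:3) {
    truth <- simulate_bsrseq(sim_config(seed = 100 + s))
    lk <- linkage_probabilities(truth$snps, n_plants = 32)
    cm_per_bp <- truth$cfg$genetic_length / truth$cfg$physical_length * 100
    near <- lk$chrom == truth$cfg$causal_chrom &
      abs(lk$pos - truth$cfg$causal_pos) * cm_per_bp <= 1
    far <- lk$chrom != truth$cfg$causal_chrom
    deltas <- c(deltas, mean(lk$final[near]) - mean(lk$final[far]))
  }
  expect_true(all(deltas > 0.3))
})
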