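#' Haldane map function
#'
#' Converts genetic distance in Morgans to a recombination fraction under the
#' assumption of no crossover interference: r = (1 - exp(-2d)) / 2.
#'
#' @param d genetic distance in Morgans (vectorized, must be >= 0).
#' @return recombination fraction in [0, 0.5).
#' @export
haldane <- function(d) {
  if (any(d < 0)) stop("genetic distance must be non-negative")
  (1 - exp(-2 * d)) / 2
}

#' Probability of no recombination at distance d in the mutant pool
#'
#' The mutant pool holds 2N independently sampled gametes (N plants, two
#' chromosomes each), so the probability that none recombined between a SNP
#' at distance d Morgans and the causal locus is (1 - r(d))^(2N), with r
#' the Haldane recombination fraction.
#'
#' @param d genetic distance in Morgans.
#' @param n_plants number of plants in the mutant pool (N).
#' @export
prob_no_recomb_given_d <- function(d, n_plants) {
  stopifnot(n_plants >= 1)
  (1 - haldane(d))^(2 * n_plants)
}

#' Prior probability of no recombination between a random SNP and the locus
#'
#' Integrates (1 - r(d))^(2N) against a uniform density for d over
#' (0, d_max], by composite trapezoid quadrature. d_max defaults to 0.20
#' Morgans (20 cM): the integrand decays to near zero well inside that
#' neighborhood for realistic pool sizes, so the result is insensitive to
#' d_max beyond it.
#'
#' @param n_plants number of plants in the mutant pool (N >= 1).
#' @param d_max upper limit of the neighborhood, Morgans.
#' @param quadrature_points number of trapezoid nodes (>= 3).
#' @return scalar prior probability in (0, 1].
#' @export
prior_no_recomb <- function(n_plants, d_max = 0.20, quadrature_points = 10001) {
  stopifnot(n_plants >= 1, d_max > 0, d_max <= 0.5, quadrature_points >= 3)
  d <- seq(0, d_max, length.out = quadrature_points)
  f <- prob_no_recomb_given_d(d, n_plants)
  h <- d[2] - d[1]
  (h * (sum(f) - (f[1] + f[length(f)]) / 2)) / d_max
}

#' Build the empirical prior over allele expression proportions
#'
#' For every contributing SNP the two observed relative allele frequencies in
#' the non-mutant pool, `wt_a / m` and `wt_b / m`, are added as prior atoms;
#' zero frequencies are discarded, every contributed atom carries equal
#' weight, and the weights are normalized to sum to one. Atoms with the same
#' frequency are merged with summed weight. Because monoallelic sites
#' contribute atoms at 1.0, the prior absorbs allele-specific expression and
#' sampling artifacts: under recombination, seeing only one allele is not
#' surprising, which is what keeps such sites from masquerading as linked.
#'
#' @param snps SNP table with columns `wt_a`, `wt_b` (and the mutant
#'   counterparts for the `"eligible"` source).
#' @param source `"all"` (default) uses every SNP with non-mutant depth
#'   >= `min_depth`; `"eligible"` restricts to [bsr_eligible()] SNPs.
#' @param min_depth minimum non-mutant pool depth for a SNP to contribute.
#' @return object of class `empirical_prior`: list with numeric vectors `p`
#'   (atom locations, sorted) and `w` (weights summing to 1).
#' @export
empirical_prior <- function(snps, source = c("all", "eligible"), min_depth = 5) {
  source <- match.arg(source)
  m <- snps$wt_a + snps$wt_b
  keep <- m >= min_depth
  if (source == "eligible") keep <- keep & bsr_eligible(snps, min_depth)
  if (!any(keep)) stop("no SNPs contribute to the empirical prior")
  freq <- c(snps$wt_a[keep] / m[keep], snps$wt_b[keep] / m[keep])
  freq <- freq[freq > 0]
  if (length(freq) == 0) stop("no non-zero allele frequencies for the prior")
  p <- sort(unique(freq))
  w <- tabulate(match(freq, p), nbins = length(p)) / length(freq)
  structure(list(p = p, w = w), class = "empirical_prior")
}

#' @export
print.empirical_prior <- function(x, ...) {
  cat("empirical prior:", length(x$p), "atoms, mean",
      format(sum(x$p * x$w), digits = 4), "\n")
  invisible(x)
}

#' Marginal likelihood of mutant-pool allele counts under recombination
#'
#' With some recombination the count x1 of an allele among the n mutant-pool
#' reads is modeled binomial(n, p) with p drawn from the empirical prior;
#' the marginal likelihood is the prior-weighted mixture of binomial pmfs.
#' Computed in log space.
#'
#' @param x1 observed allele count (vectorized).
#' @param n total mutant-pool reads at the SNP (vectorized).
#' @param prior an [empirical_prior()].
#' @return numeric vector of probabilities.
#' @export
lik_counts_given_recomb <- function(x1, n, prior) {
  stopifnot(inherits(prior, "empirical_prior"), all(x1 >= 0), all(x1 <= n),
            all(n >= 1))
  k <- length(prior$p)
  nx <- max(length(x1), length(n))
  x1 <- rep_len(x1, nx); n <- rep_len(n, nx)
  # nx x k matrix of log pmfs
  lp <- dbinom(rep(x1, times = k), rep(n, times = k),
               rep(prior$p, each = nx), log = TRUE)
  dim(lp) <- c(nx, k)
  lw <- matrix(log(prior$w), nx, k, byrow = TRUE)
  apply(lp + lw, 1, logsumexp_exp)
}

logsumexp_exp <- function(v) {
  mx <- max(v)
  if (mx == -Inf) return(0)
  exp(mx) * sum(exp(v - mx))
}

#' Stage-1 posterior probability of no recombination in the mutant pool
#'
#' If both alleles are observed in the mutant pool the posterior is exactly 0
#' (no recombination would imply a fixed allele). For a monoallelic site the
#' no-recombination likelihood is 1 and the posterior is
#' pi / (pi + (1 - pi) * P(x | R)) with P(x | R) the mixture likelihood of
#' [lik_counts_given_recomb()] evaluated at x1 = n.
#'
#' @param mut_a,mut_b per-allele mutant-pool read counts (vectorized).
#' @param pi_no_recomb prior probability of no recombination, from
#'   [prior_no_recomb()].
#' @param prior an [empirical_prior()].
#' @return posterior probabilities in [0, 1].
#' @export
posterior_no_recomb <- function(mut_a, mut_b, pi_no_recomb, prior) {
  n <- mut_a + mut_b
  if (any(n < 1)) stop("SNP with no mutant-pool reads; filter first")
  stopifnot(pi_no_recomb > 0, pi_no_recomb < 1)
  out <- numeric(length(n))
  mono <- pmin(mut_a, mut_b) == 0
  if (any(mono)) {
    lik_r <- lik_counts_given_recomb(n[mono], n[mono], prior)
    out[mono] <- pi_no_recomb / (pi_no_recomb + (1 - pi_no_recomb) * lik_r)
  }
  out
}

#' Identify the mutant-coupled allele of each SNP
#'
#' The mutant-coupled allele is the more frequent allele in the mutant pool.
#' On a tie the allele rarer in the non-mutant pool is chosen (near the
#' causal locus the mutant allele is the less expressed one there); a double
#' tie falls back to `allele_a`. Ties only arise at SNPs whose stage-1
#' posterior is zero, so the tie-breaks never affect the final ranking.
#'
#' @param snps SNP table with count columns.
#' @return character vector, `"a"` or `"b"` per SNP.
#' @export
identify_mutant_allele <- function(snps) {
  if (any(snps$mut_a + snps$mut_b < 1)) stop("SNP with no mutant-pool reads")
  ifelse(snps$mut_a > snps$mut_b, "a",
    ifelse(snps$mut_a < snps$mut_b, "b",
      ifelse(snps$wt_a <= snps$wt_b, "a", "b")))
}

#' Stage-2 posterior that the mutant allele's expression share is <= 1/2
#'
#' In the non-mutant pool of an F2 the mutant allele is expected at a 1:2
#' disadvantage at the DNA level near the causal locus, so its RNA expression
#' proportion p should satisfy p <= 1/2. Given y1 mutant-allele reads out of
#' m in the non-mutant pool and the empirical prior over p, the posterior is
#' the prior-weighted binomial mass on atoms with p <= 1/2 divided by the
#' total. Atoms exactly at 0.5 count toward the numerator.
#'
#' @param y1 mutant-allele read count in the non-mutant pool (vectorized).
#' @param m total non-mutant pool reads at the SNP (vectorized).
#' @param prior an [empirical_prior()].
#' @return posterior probabilities in [0, 1].
#' @export
posterior_p_le_half <- function(y1, m, prior) {
  stopifnot(inherits(prior, "empirical_prior"),
            all(y1 >= 0), all(y1 <= m), all(m >= 1))
  k <- length(prior$p)
  nx <- max(length(y1), length(m))
  y1 <- rep_len(y1, nx); m <- rep_len(m, nx)
  pm <- dbinom(rep(y1, times = k), rep(m, times = k),
               rep(prior$p, each = nx))
  dim(pm) <- c(nx, k)
  wpm <- pm * matrix(prior$w, nx, k, byrow = TRUE)
  denom <- rowSums(wpm)
  if (any(denom == 0))
    stop("degenerate empirical prior: zero likelihood at some SNP")
  rowSums(wpm[, prior$p <= 0.5, drop = FALSE]) / denom
}

#' Per-SNP linkage probabilities
#'
#' Runs the full two-stage computation over a SNP table: restricts to
#' [bsr_eligible()] SNPs, builds the empirical prior (by default from all
#' SNPs with adequate non-mutant depth, before the both-alleles eligibility
#' rule, so monoallelic-expression atoms are retained), computes the stage-1
#' posterior of no recombination in the mutant pool, the stage-2 posterior
#' that the mutant allele's expression share in the non-mutant pool is
#' <= 1/2, and their product — the final linkage probability.
#'
#' @param snps SNP table from [discover_snps()] or [read_snp_table()].
#' @param n_plants number of plants in the mutant pool.
#' @param d_max neighborhood for the no-recombination prior, Morgans.
#' @param prior_source `"all"` or `"eligible"`, see [empirical_prior()].
#' @param min_pool_depth eligibility depth threshold per pool.
#' @return data.frame with one row per eligible SNP: `chrom`, `pos`, `n`,
#'   `m`, `x2` (minor mutant-pool count), `mutant_allele`, `pi_no_recomb`,
#'   `post_no_recomb`, `post_p_le_half`, `final`, sorted by (chrom, pos).
#' @export
linkage_probabilities <- function(snps, n_plants = 32, d_max = 0.20,
                                  prior_source = c("all", "eligible"),
                                  min_pool_depth = 5) {
  prior_source <- match.arg(prior_source)
  prior <- empirical_prior(snps, prior_source, min_depth = min_pool_depth)
  elig <- snps[bsr_eligible(snps, min_pool_depth), , drop = FALSE]
  if (nrow(elig) == 0) stop("no eligible SNPs")
  elig <- sort_snp_table(elig)
  pi0 <- prior_no_recomb(n_plants, d_max)
  mut_allele <- identify_mutant_allele(elig)
  y1 <- ifelse(mut_allele == "a", elig$wt_a, elig$wt_b)
  n <- elig$mut_a + elig$mut_b
  m <- elig$wt_a + elig$wt_b
  p1 <- posterior_no_recomb(elig$mut_a, elig$mut_b, pi0, prior)
  p2 <- posterior_p_le_half(y1, m, prior)
  data.frame(chrom = elig$chrom, pos = elig$pos, n = n, m = m,
             x2 = pmin(elig$mut_a, elig$mut_b),
             mutant_allele = ifelse(mut_allele == "a",
                                    elig$allele_a, elig$allele_b),
             pi_no_recomb = pi0,
             post_no_recomb = p1, post_p_le_half = p2,
             final = p1 * p2)
}
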