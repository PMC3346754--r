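#' Configuration of a simulated BSR-Seq experiment
#'
#' Describes the cross, genetic map, pools and sequencing model of a
#' simulated F2 bulked-segregant experiment. The default genome is a
#' density-preserving scale-down of a maize-sized transcriptome map: the
#' sliding-window statistic depends on marker density per centimorgan
#' (roughly 40 expressed SNPs per cM in a deep RNA-Seq experiment), so the
#' defaults keep that density and shrink the genome about 30-fold — ten
#' chromosomes of 6 Mb / 5 cM each with 200 uniformly spaced SNP markers
#' (2,000 genome-wide), a recessive causal mutation mid-chromosome 4, pools
#' of 32 mutants and 31 non-mutant siblings drawn from an F2 of 200 selfed
#' progeny, and negative-binomial sequencing depth of mean 20 per SNP per
#' pool. Pool sizes, depth and the recombination process are at full scale;
#' only the genome is shrunk.
#'
#' @param seed integer RNG seed.
#' @param n_chrom number of chromosomes.
#' @param physical_length physical length per chromosome, bp.
#' @param genetic_length genetic length per chromosome, Morgans. Physical
#'   and genetic coordinates are linked linearly per chromosome.
#' @param markers_per_chrom SNP markers per chromosome, uniformly spaced.
#' @param causal_chrom,causal_pos chromosome name and physical position of
#'   the causal mutation.
#' @param n_f2 F2 population size to simulate.
#' @param n_mutant_pool,n_wt_pool pool sizes.
#' @param mean_depth mean sequencing depth per SNP per pool.
#' @param depth_dispersion negative-binomial size parameter for depth
#'   (`Inf` gives Poisson depth).
#' @param ase_fraction fraction of SNPs with allele-specific expression skew.
#' @param ase_skew expression proportion of the favored allele at ASE SNPs,
#'   in (0, 1).
#' @param misclassification_rate probability that a mutant-pool slot is
#'   filled by a non-mutant instead.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 10,
                       physical_length = 6e6,
                       genetic_length = 0.05,
                       markers_per_chrom = 200,
                       causal_chrom = "chr4",
                       causal_pos = 3e6,
                       n_f2 = 200,
                       n_mutant_pool = 32,
                       n_wt_pool = 31,
                       mean_depth = 20,
                       depth_dispersion = 5,
                       ase_fraction = 0.1,
                       ase_skew = 0.8,
                       misclassification_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_chrom = n_chrom,
              physical_length = physical_length,
              genetic_length = genetic_length,
              markers_per_chrom = markers_per_chrom,
              causal_chrom = causal_chrom, causal_pos = causal_pos,
              n_f2 = n_f2, n_mutant_pool = n_mutant_pool,
              n_wt_pool = n_wt_pool, mean_depth = mean_depth,
              depth_dispersion = depth_dispersion,
              ase_fraction = ase_fraction, ase_skew = ase_skew,
              misclassification_rate = misclassification_rate)
  stopifnot(cfg$n_chrom >= 1, cfg$markers_per_chrom >= 1,
            cfg$n_mutant_pool >= 1, cfg$n_wt_pool >= 1,
            cfg$mean_depth > 0, cfg$ase_skew > 0, cfg$ase_skew < 1,
            cfg$ase_fraction >= 0, cfg$ase_fraction <= 1,
            cfg$misclassification_rate >= 0, cfg$misclassification_rate <= 1)
  if (!cfg$causal_chrom %in% paste0("chr", seq_len(cfg$n_chrom)) ||
      cfg$causal_pos < 1 || cfg$causal_pos > cfg$physical_length)
    stop("causal position lies outside the simulated genome")
  class(cfg) <- "sim_config"
  cfg
}

# marker map: uniformly spaced markers plus the causal locus as an extra
# locus on its chromosome. Genetic position is linear in physical position.
marker_map <- function(cfg) {
  maps <- lapply(seq_len(cfg$n_chrom), function(i) {
    chrom <- paste0("chr", i)
    pos <- round(seq(1, cfg$physical_length,
                     length.out = cfg$markers_per_chrom))
    causal <- logical(length(pos))
    if (chrom == cfg$causal_chrom && !cfg$causal_pos %in% pos) {
      pos <- c(pos, cfg$causal_pos)
      causal <- c(causal, TRUE)
      o <- order(pos)
      pos <- pos[o]; causal <- causal[o]
    } else if (chrom == cfg$causal_chrom) {
      causal[pos == cfg$causal_pos] <- TRUE
    }
    data.frame(chrom = chrom, pos = pos,
               gpos = pos / cfg$physical_length * cfg$genetic_length,
               causal = causal)
  })
  do.call(rbind, maps)
}

# n gametes over one chromosome's ordered genetic positions: first-order
# Markov chain with switch probability = Haldane r of the interval (exact
# under no interference). Returns an n x M matrix of 0/1 parental origins.
sim_gametes <- function(n, gpos) {
  M <- length(gpos)
  first <- rbinom(n, 1, 0.5)
  if (M == 1) return(matrix(first, ncol = 1))
  r <- haldane(diff(gpos))
  switches <- matrix(rbinom(n * (M - 1), 1, rep(r, each = n)), nrow = n)
  t(apply(cbind(first, switches), 1, cumsum)) %% 2
}

#' Simulate an F2 population segregating a recessive mutation
#'
#' Self-pollinates a plant heterozygous for the causal mutation: each F2
#' individual receives two independent gametes, each generated
#' marker-to-marker along the genetic map with switch probability equal to
#' the Haldane recombination fraction of the inter-marker distance (no
#' interference). The two parental haplotypes carry allele 0 and allele 1 at
#' every marker; the causal mutation is coupled with the allele-1 haplotype,
#' and an individual expresses the mutant phenotype iff it is homozygous
#' allele 1 at the causal locus.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_truth`: `map` (marker data.frame with a
#'   `causal` flag), `gam1`, `gam2` (individuals x markers 0/1 matrices),
#'   `mutant` (logical per individual), and `cfg`.
#' @export
simulate_f2 <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  map <- marker_map(cfg)
  gam1 <- matrix(0L, cfg$n_f2, nrow(map))
  gam2 <- matrix(0L, cfg$n_f2, nrow(map))
  for (chrom in unique(map$chrom)) {
    idx <- which(map$chrom == chrom)
    gam1[, idx] <- sim_gametes(cfg$n_f2, map$gpos[idx])
    gam2[, idx] <- sim_gametes(cfg$n_f2, map$gpos[idx])
  }
  ci <- which(map$causal)
  mutant <- gam1[, ci] == 1L & gam2[, ci] == 1L
  structure(list(map = map, gam1 = gam1, gam2 = gam2,
                 mutant = mutant, cfg = cfg),
            class = "sim_truth")
}

#' Assign simulated individuals to the mutant and non-mutant pools
#'
#' Samples `n_mutant_pool` phenotypically mutant and `n_wt_pool` non-mutant
#' individuals without replacement. With probability `misclassification_rate`
#' each mutant-pool slot is filled by a (distinct, unpooled) non-mutant
#' instead, emulating phenotyping errors.
#'
#' @param truth a `sim_truth` from [simulate_f2()].
#' @return `truth` with added integer index vectors `mut_pool`, `wt_pool`.
#' @export
build_pools <- function(truth) {
  cfg <- truth$cfg
  mutants <- which(truth$mutant)
  nonmut <- which(!truth$mutant)
  if (length(mutants) < cfg$n_mutant_pool)
    stop("not enough mutant individuals (", length(mutants), ") for the pool")
  n_wrong <- rbinom(1, cfg$n_mutant_pool, cfg$misclassification_rate)
  if (length(nonmut) < cfg$n_wt_pool + n_wrong)
    stop("not enough non-mutant individuals for the pools")
  nm_sample <- sample(nonmut, cfg$n_wt_pool + n_wrong)
  truth$mut_pool <- c(sample(mutants, cfg$n_mutant_pool - n_wrong),
                      nm_sample[seq_len(n_wrong)])
  truth$wt_pool <- nm_sample[n_wrong + seq_len(cfg$n_wt_pool)]
  truth
}

#' Simulate per-SNP, per-pool allele read counts
#'
#' For each SNP and pool, sequencing depth is drawn negative-binomial (mean
#' `mean_depth`, size `depth_dispersion`; Poisson when the dispersion is
#' infinite) and the allele-1 read count is binomial(depth, f'), where f is
#' the pool's allele-1 haplotype frequency. At ASE SNPs (a fraction
#' `ase_fraction`, shared between pools as a cis effect) one allele, chosen
#' at random, is favored: haplotypes of the favored allele emit reads with
#' weight s/(1-s) relative to the other allele, s = `ase_skew`, so
#' f' = w f / (w f + 1 - f) when allele 1 is favored and symmetrically
#' otherwise. Each SNP is assigned two distinct bases; `allele_a` is the
#' lexicographically smaller and carries parental allele 0 or 1 at random.
#'
#' @param truth a pooled `sim_truth` from [build_pools()].
#' @return `truth` with `snps` (the standard SNP table: `chrom`, `pos`,
#'   `allele_a`, `allele_b`, `mut_a`, `mut_b`, `wt_a`, `wt_b`) and
#'   `snp_truth` (per-SNP true pool frequencies and ASE status). The causal
#'   locus itself is not emitted as a SNP.
#' @export
simulate_allele_counts <- function(truth) {
  cfg <- truth$cfg
  if (is.null(truth$mut_pool)) stop("call build_pools() first")
  map <- truth$map
  midx <- which(!map$causal)
  M <- length(midx)

  hap_mut <- rbind(truth$gam1[truth$mut_pool, midx, drop = FALSE],
                   truth$gam2[truth$mut_pool, midx, drop = FALSE])
  hap_wt <- rbind(truth$gam1[truth$wt_pool, midx, drop = FALSE],
                  truth$gam2[truth$wt_pool, midx, drop = FALSE])
  c1_mut <- colSums(hap_mut); c0_mut <- nrow(hap_mut) - c1_mut
  c1_wt <- colSums(hap_wt); c0_wt <- nrow(hap_wt) - c1_wt

  is_ase <- runif(M) < cfg$ase_fraction
  favored1 <- runif(M) < 0.5        # which allele the ASE skew favors
  w <- cfg$ase_skew / (1 - cfg$ase_skew)
  w1 <- ifelse(is_ase & favored1, w, 1)
  w0 <- ifelse(is_ase & !favored1, w, 1)
  f_mut <- w1 * c1_mut / (w1 * c1_mut + w0 * c0_mut)
  f_wt <- w1 * c1_wt / (w1 * c1_wt + w0 * c0_wt)

  draw_depth <- function(n) {
    if (is.infinite(cfg$depth_dispersion)) rpois(n, cfg$mean_depth)
    else rnbinom(n, size = cfg$depth_dispersion, mu = cfg$mean_depth)
  }
  dep_mut <- draw_depth(M)
  dep_wt <- draw_depth(M)
  x1_mut <- rbinom(M, dep_mut, f_mut)
  x1_wt <- rbinom(M, dep_wt, f_wt)

  # two distinct bases per SNP; allele_a is the lexicographically smaller
  # and carries parental allele 1 with probability 1/2
  bases <- c("A", "C", "G", "T")
  b1 <- sample(bases, M, replace = TRUE)
  b2i <- (match(b1, bases) - 1 + sample(3, M, replace = TRUE)) %% 4 + 1
  pair <- cbind(b1, bases[b2i])
  a_is_1 <- runif(M) < 0.5
  allele_a <- pmin(pair[, 1], pair[, 2])
  allele_b <- pmax(pair[, 1], pair[, 2])
  snps <- data.frame(
    chrom = map$chrom[midx], pos = map$pos[midx],
    allele_a = allele_a, allele_b = allele_b,
    mut_a = as.integer(ifelse(a_is_1, x1_mut, dep_mut - x1_mut)),
    mut_b = as.integer(ifelse(a_is_1, dep_mut - x1_mut, x1_mut)),
    wt_a = as.integer(ifelse(a_is_1, x1_wt, dep_wt - x1_wt)),
    wt_b = as.integer(ifelse(a_is_1, dep_wt - x1_wt, x1_wt)))
  truth$snps <- sort_snp_table(snps)
  truth$snp_truth <- data.frame(
    chrom = map$chrom[midx], pos = map$pos[midx],
    f1_mut_pool = c1_mut / nrow(hap_mut),
    f1_wt_pool = c1_wt / nrow(hap_wt),
    f1_mut_reads = f_mut, f1_wt_reads = f_wt,
    ase = is_ase, allele1_base = ifelse(a_is_1, allele_a, allele_b))
  truth
}

#' Simulate a whole BSR-Seq experiment
#'
#' Convenience wrapper: [simulate_f2()], [build_pools()],
#' [simulate_allele_counts()].
#'
#' @param cfg a [sim_config()].
#' @return a `sim_truth` with pools, SNP table and truth tables attached.
#' @export
simulate_bsrseq <- function(cfg) {
  simulate_allele_counts(build_pools(simulate_f2(cfg)))
}

#' Simulate a per-gene read-count table for the DE stage
#'
#' Baseline expression per gene is log-normal; counts per pool are Poisson
#' around the baseline, with the mutant-pool mean multiplied by
#' `fold_change` for `n_de` randomly chosen genes. The log-normal spread
#' (sdlog 1) reproduces the several-orders-of-magnitude expression range of
#' a typical transcriptome.
#'
#' @param n_genes number of genes.
#' @param n_de number of truly differentially expressed genes.
#' @param fold_change multiplicative effect on the mutant-pool mean for DE
#'   genes.
#' @param mean_depth mean reads per gene per pool.
#' @param seed integer RNG seed.
#' @return list with `counts` (data.frame `gene_id`, `mut_reads`,
#'   `wt_reads`, `exon_length`), `de_genes` (character vector of true DE
#'   gene ids), `mut_total`, `wt_total`.
#' @export
simulate_gene_counts <- function(n_genes, n_de = 0, fold_change = 1,
                                 mean_depth = 200, seed = 1L) {
  stopifnot(n_de <= n_genes, fold_change > 0)
  set.seed(seed)
  base <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
  base <- base / mean(base) * mean_depth
  de <- sample(n_genes, n_de)
  mu_mut <- base
  mu_mut[de] <- mu_mut[de] * fold_change
  counts <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(n_genes)),
    mut_reads = rpois(n_genes, mu_mut),
    wt_reads = rpois(n_genes, base),
    exon_length = pmax(200L, as.integer(round(rlnorm(n_genes, 7.3, 0.6)))))
  list(counts = counts, de_genes = counts$gene_id[sort(de)],
       mut_total = sum(counts$mut_reads), wt_total = sum(counts$wt_reads))
}
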