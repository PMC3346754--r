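#' Count reads overlapping each gene model
#'
#' A read is counted for every gene whose span it overlaps by at least one
#' base ("any portion" overlap); a read overlapping two genes increments
#' both, and intergenic reads are not counted.
#'
#' @param reads data.frame with `chrom`, `start`, `aligned_length` (1-based
#'   inclusive spans), typically pre-filtered with [filter_alignments()].
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @return integer vector of raw counts, one per row of `genes`.
#' @export
count_reads_per_gene <- function(reads, genes) {
  stopifnot(all(c("chrom", "start", "aligned_length") %in% names(reads)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (nrow(reads) == 0) return(integer(nrow(genes)))
  r <- GenomicRanges::GRanges(
    reads$chrom,
    IRanges::IRanges(reads$start, width = reads$aligned_length))
  g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  GenomicRanges::countOverlaps(g, r, minoverlap = 1L)
}

#' Reads per kilobase of exon per million mapped reads
#'
#' @param raw raw read count for the gene.
#' @param exon_length total exonic length of the gene, bases (>= 1).
#' @param library_total total uniquely mapped reads in the library (>= 1).
#' @export
rpkm <- function(raw, exon_length, library_total) {
  if (any(exon_length < 1) || any(library_total < 1))
    stop("exon_length and library_total must be >= 1")
  raw / (exon_length / 1e3) / (library_total / 1e6)
}

#' Log2 fold change between pools with a +1 pseudocount
#'
#' Counts are first scaled to a common library size — the smaller of the two
#' totals, so that the pseudocount is added on the scale of the shallower
#' library — then 1 is added to each and the ratio non-mutant over mutant is
#' taken on the log2 scale. Positive values mean higher expression in the
#' non-mutant pool.
#'
#' @param mut_reads,wt_reads raw gene counts per pool (vectorized).
#' @param mut_total,wt_total library totals of uniquely mapped reads.
#' @param ref_total normalization scale; defaults to `min(mut_total,
#'   wt_total)`.
#' @export
log2_fold_change <- function(mut_reads, wt_reads, mut_total, wt_total,
                             ref_total = min(mut_total, wt_total)) {
  stopifnot(mut_total >= 1, wt_total >= 1)
  log2((as.numeric(wt_reads) * ref_total / wt_total + 1) /
       (as.numeric(mut_reads) * ref_total / mut_total + 1))
}

#' Two-sided Fisher exact test for one gene's read proportions
#'
#' Tests whether a gene's share of the uniquely mapped reads differs between
#' pools, on the 2x2 table (gene reads vs remaining reads, by pool). The
#' two-sided p-value sums hypergeometric probabilities of all tables with
#' the same margins whose probability does not exceed that of the observed
#' table (probability-mass definition of extremeness, with the customary
#' 1e-7 relative tolerance for ties). Degenerate margins give p = 1.
#'
#' @param mut_reads,wt_reads gene read counts per pool (vectorized).
#' @param mut_total,wt_total library totals (>= corresponding counts).
#' @return two-sided p-values.
#' @export
fisher_de_test <- function(mut_reads, wt_reads, mut_total, wt_total) {
  nx <- max(length(mut_reads), length(wt_reads))
  a <- rep_len(mut_reads, nx); c_ <- rep_len(wt_reads, nx)
  m1 <- rep_len(mut_total, nx); m2 <- rep_len(wt_total, nx)
  if (any(a > m1) || any(c_ > m2) || any(c(a, c_) < 0))
    stop("counts must satisfy 0 <= reads <= total")
  vapply(seq_len(nx), function(i)
    fisher_2x2(a[i], m1[i] - a[i], c_[i], m2[i] - c_[i]), numeric(1))
}

fisher_2x2 <- function(a, b, c, d) {
  k <- a + c                       # gene-read column margin
  m1 <- a + b; m2 <- c + d
  if (k == 0 || k == m1 + m2 || m1 == 0 || m2 == 0) return(1)
  support <- max(0, k - m2):min(k, m1)
  pmf <- dhyper(support, m1, m2, k)
  p_obs <- pmf[support == a]
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param p vector of p-values in [0, 1] (NA allowed, propagated).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes between pools
#'
#' Genes with fewer than `min_total_reads` combined reads are excluded from
#' testing (they receive no p- or q-value and cannot dilute the FDR
#' adjustment). Tested genes get a Fisher exact p-value, BH q-value over
#' tested genes only, and are flagged significant iff q <= `fdr` and
#' |log2 fold change| > `min_abs_log2fc`.
#'
#' @param counts data.frame with `gene_id`, `mut_reads`, `wt_reads`, and
#'   optionally `exon_length` (enables RPKM columns).
#' @param mut_total,wt_total library totals; default to the column sums.
#' @param min_total_reads minimum combined reads for a gene to be tested.
#' @param fdr q-value threshold.
#' @param min_abs_log2fc minimum absolute log2 fold change (exclusive).
#' @return the input with added columns `log2fc`, `p_value`, `q_value`,
#'   `tested`, `significant` (and `rpkm_mut`, `rpkm_wt` when exon lengths
#'   are available).
#' @export
call_de <- function(counts, mut_total = sum(counts$mut_reads),
                    wt_total = sum(counts$wt_reads),
                    min_total_reads = 40, fdr = 0.001,
                    min_abs_log2fc = 0.8) {
  stopifnot(all(c("gene_id", "mut_reads", "wt_reads") %in% names(counts)))
  out <- counts
  if (!is.null(counts$exon_length)) {
    out$rpkm_mut <- rpkm(counts$mut_reads, counts$exon_length, mut_total)
    out$rpkm_wt <- rpkm(counts$wt_reads, counts$exon_length, wt_total)
  }
  out$log2fc <- log2_fold_change(counts$mut_reads, counts$wt_reads,
                                 mut_total, wt_total)
  out$tested <- counts$mut_reads + counts$wt_reads >= min_total_reads
  out$p_value <- NA_real_
  out$q_value <- NA_real_
  if (any(out$tested)) {
    out$p_value[out$tested] <- fisher_de_test(
      counts$mut_reads[out$tested], counts$wt_reads[out$tested],
      mut_total, wt_total)
    out$q_value[out$tested] <- bh_fdr(out$p_value[out$tested])
  }
  out$significant <- !is.na(out$q_value) & out$q_value <= fdr &
    abs(out$log2fc) > min_abs_log2fc
  out
}

#' Ratio of down- to up-regulated significant genes
#'
#' Down-regulated means significantly lower in the mutant pool, i.e. a
#' positive non-mutant-over-mutant log2 fold change. An optional region
#' restricts the tally to genes inside a (chrom, start, end) interval; this
#' needs `chrom` and `start` columns on the table.
#'
#' @param de flagged table from [call_de()].
#' @param region optional `list(chrom =, start =, end =)`.
#' @return list with `down`, `up`, `ratio` (Inf when nothing is
#'   up-regulated in scope).
#' @export
down_up_ratio <- function(de, region = NULL) {
  sig <- de[de$significant, , drop = FALSE]
  if (!is.null(region)) {
    stopifnot(all(c("chrom", "start") %in% names(sig)))
    sig <- sig[sig$chrom == region$chrom & sig$start >= region$start &
               sig$start <= region$end, , drop = FALSE]
  }
  down <- sum(sig$log2fc > 0)
  up <- sum(sig$log2fc < 0)
  list(down = down, up = up,
       ratio = if (up == 0) Inf else down / up)
}

#' Chi-square test for regional bias in the down/up ratio
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' down- vs up-regulated significant genes inside vs outside a genomic
#' region, testing whether the down:up ratio differs between them.
#'
#' @param down_in,up_in counts of down-/up-regulated genes in the region.
#' @param down_out,up_out counts outside the region.
#' @return list with `statistic`, `df` (always 1), `p_value`.
#' @export
region_bias_test <- function(down_in, up_in, down_out, up_out) {
  tab <- matrix(c(down_in, up_in, down_out, up_out), nrow = 2)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins of the 2x2 table must be positive")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1,
       p_value = unname(ct$p.value))
}
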