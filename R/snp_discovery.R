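#' Filter aligned reads by uniqueness and mismatch rate
#'
#' Keeps reads that mapped uniquely and carry at most a fixed number of
#' mismatches per 36 aligned bases (insertions and deletions each count as
#' one mismatch). For a read of aligned length L the allowance is
#' `floor(allowance_per_36bp * L / 36)`, i.e. the 36-bp rate is prorated for
#' reads trimmed to other lengths.
#'
#' @param reads data.frame with columns `read_id`, `chrom`, `start`,
#'   `aligned_length`, `mismatches`, `unique` (logical).
#' @param allowance_per_36bp mismatches allowed per 36 aligned bases.
#' @return logical vector, `TRUE` for reads to keep.
#' @examples
#' reads <- data.frame(read_id = c("r1", "r2"), chrom = "chr1", start = 1L,
#'                     aligned_length = c(36L, 36L), mismatches = c(2L, 3L),
#'                     unique = TRUE)
#' filter_alignments(reads)  # TRUE FALSE
#' @export
filter_alignments <- function(reads, allowance_per_36bp = 2) {
  stopifnot(is.data.frame(reads))
  need <- c("aligned_length", "mismatches", "unique")
  if (!all(need %in% names(reads)))
    stop("reads must have columns: ", paste(need, collapse = ", "))
  if (any(reads$aligned_length <= 0))
    stop("aligned_length must be positive")
  if (any(reads$mismatches < 0))
    stop("mismatches must be non-negative")
  allowed <- floor(allowance_per_36bp * reads$aligned_length / 36)
  reads$unique & reads$mismatches <= allowed
}

#' Call a biallelic SNP from one merged pileup column
#'
#' Applies the four-site filters to the base calls of both pools merged at a
#' single position: a base is a candidate allele iff it has at least
#' `min_allele_reads` calls with base quality >= `min_base_quality` and those
#' calls make up at least `min_allele_frac` of all quality-passing calls; a
#' SNP is returned iff exactly two candidate alleles exist and together they
#' account for at least `min_top2_frac` of the quality-passing calls. A
#' low-fraction third base that fails the per-allele thresholds does not by
#' itself disqualify the site; the top-two-fraction rule guards total
#' off-type mass. Calls below `min_base_quality` are excluded from both the
#' numerators and denominators of the fraction rules.
#'
#' @param base character vector of base calls (`A`,`C`,`G`,`T`).
#' @param qual numeric vector of phred base qualities, same length.
#' @param min_allele_reads minimum quality-passing reads per allele.
#' @param min_base_quality minimum phred quality for a call to count.
#' @param min_allele_frac minimum per-allele fraction of quality-passing calls.
#' @param min_top2_frac minimum combined fraction of the two alleles.
#' @return character vector of the two alleles (lexicographic order), or
#'   `NULL` if the site is not a valid biallelic SNP. All thresholds are
#'   inclusive (>=).
#' @examples
#' call_snp_site(rep(c("A", "C", "G"), c(10, 5, 1)), rep(30, 16))  # c("A","C")
#' call_snp_site(rep(c("A", "C"), c(10, 2)), rep(30, 12))          # NULL
#' @export
call_snp_site <- function(base, qual,
                          min_allele_reads = 3, min_base_quality = 15,
                          min_allele_frac = 0.20, min_top2_frac = 0.90) {
  stopifnot(length(base) == length(qual))
  if (length(base) == 0) return(NULL)
  keep <- qual >= min_base_quality
  if (!any(keep)) return(NULL)
  counts <- table(factor(base[keep], levels = c("A", "C", "G", "T")))
  total <- sum(counts)
  cand <- counts >= min_allele_reads & counts / total >= min_allele_frac
  if (sum(cand) != 2L) return(NULL)
  if (sum(counts[cand]) / total < min_top2_frac) return(NULL)
  sort(names(counts)[cand])
}

#' Discover biallelic SNPs from a two-pool pileup table
#'
#' Merges the calls of both pools at each position for SNP discovery, applies
#' [call_snp_site()] filters, then quantifies the two alleles separately in
#' each pool among quality-passing calls (calls matching neither allele are
#' ignored). Alleles are stored with `allele_a` < `allele_b` lexicographically.
#'
#' @param pileup data.frame with columns `chrom`, `pos`, `pool`
#'   (`"mut"`/`"wt"`), `base`, `qual`, `count` (number of identical calls;
#'   defaults to 1 if missing).
#' @param blacklist optional data.frame of known bad sites (`chrom`, `pos`)
#'   to drop after discovery.
#' @inheritParams call_snp_site
#' @return data.frame with columns `chrom`, `pos`, `allele_a`, `allele_b`,
#'   `mut_a`, `mut_b`, `wt_a`, `wt_b`, sorted by (chrom, pos) with natural
#'   chromosome order.
#' @export
discover_snps <- function(pileup, blacklist = NULL,
                          min_allele_reads = 3, min_base_quality = 15,
                          min_allele_frac = 0.20, min_top2_frac = 0.90) {
  stopifnot(is.data.frame(pileup))
  need <- c("chrom", "pos", "pool", "base", "qual")
  if (!all(need %in% names(pileup)))
    stop("pileup must have columns: ", paste(need, collapse = ", "))
  if (!all(pileup$pool %in% c("mut", "wt")))
    stop("pool must be 'mut' or 'wt'")
  if (is.null(pileup$count)) pileup$count <- 1L

  dt <- data.table::as.data.table(pileup)
  dt <- dt[qual >= min_base_quality & count > 0]
  if (nrow(dt) == 0) return(empty_snp_table())
  # per (site, base): quality-passing calls, merged and per pool
  agg <- dt[, .(n_mut = sum(count[pool == "mut"]),
                n_wt  = sum(count[pool == "wt"])),
            by = .(chrom, pos, base)]
  agg[, n_all := n_mut + n_wt]
  agg[, total := sum(n_all), by = .(chrom, pos)]
  agg[, cand := n_all >= min_allele_reads & n_all / total >= min_allele_frac]
  sites <- agg[, {
    cc <- cand
    if (sum(cc) == 2L && sum(n_all[cc]) / total[1] >= min_top2_frac) {
      o <- order(base[cc])
      i <- which(cc)[o]
      .(allele_a = base[i[1]], allele_b = base[i[2]],
        mut_a = n_mut[i[1]], mut_b = n_mut[i[2]],
        wt_a = n_wt[i[1]], wt_b = n_wt[i[2]])
    }
  }, by = .(chrom, pos)]
  snps <- as.data.frame(sites)
  if (nrow(snps) == 0) return(empty_snp_table())
  for (col in c("mut_a", "mut_b", "wt_a", "wt_b"))
    snps[[col]] <- as.integer(snps[[col]])
  snps <- sort_snp_table(snps)
  if (!is.null(blacklist)) snps <- apply_blacklist(snps, blacklist)
  snps
}

empty_snp_table <- function() {
  data.frame(chrom = character(), pos = integer(),
             allele_a = character(), allele_b = character(),
             mut_a = integer(), mut_b = integer(),
             wt_a = integer(), wt_b = integer())
}

#' Remove blacklisted sites from a SNP table
#'
#' Drops every SNP whose (chrom, pos) appears in the blacklist of known bad
#' sites (reference sequencing errors or paramorphisms); input order is
#' preserved.
#'
#' @param snps SNP table as produced by [discover_snps()].
#' @param blacklist data.frame with columns `chrom`, `pos`.
#' @return the filtered SNP table.
#' @export
apply_blacklist <- function(snps, blacklist) {
  stopifnot(is.data.frame(snps), is.data.frame(blacklist))
  if (nrow(blacklist) == 0 || nrow(snps) == 0) return(snps)
  bad <- paste(blacklist$chrom, blacklist$pos)
  snps[!(paste(snps$chrom, snps$pos) %in% bad), , drop = FALSE]
}

#' Flag SNPs eligible for the linkage analysis
#'
#' A SNP enters the Bayesian linkage computation only if both pools have at
#' least `min_pool_depth` reads over the two alleles and both alleles are
#' seen at least once in the non-mutant pool.
#'
#' @param snps SNP table (columns `mut_a`, `mut_b`, `wt_a`, `wt_b`).
#' @param min_pool_depth minimum two-allele read total per pool.
#' @return logical vector.
#' @export
bsr_eligible <- function(snps, min_pool_depth = 5) {
  n <- snps$mut_a + snps$mut_b
  m <- snps$wt_a + snps$wt_b
  n >= min_pool_depth & m >= min_pool_depth & snps$wt_a >= 1 & snps$wt_b >= 1
}

# natural chromosome order: chr2 < chr10
natural_chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", chrom)))
  order(is.na(num), num, chrom)
}

sort_snp_table <- function(snps) {
  lev <- unique(snps$chrom)[natural_chrom_order(unique(snps$chrom))]
  snps <- snps[order(match(snps$chrom, lev), snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  snps
}
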