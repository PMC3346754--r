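# quick SNP-table constructor for tests
snp_table <- function(mut_a, mut_b, wt_a, wt_b,
                      chrom = paste0("chr", seq_along(mut_a)),
                      pos = seq_along(mut_a)) {
  data.frame(chrom = chrom, pos = as.integer(pos),
             allele_a = "A", allele_b = "C",
             mut_a = as.integer(mut_a), mut_b = as.integer(mut_b),
             wt_a = as.integer(wt_a), wt_b = as.integer(wt_b))
}

# pileup rows for one site: counts named by base, e.g. c(A = 10, C = 5)
pileup_site <- function(counts, pool = "mut", chrom = "chr1", pos = 100,
                        qual = 30) {
  data.frame(chrom = chrom, pos = as.integer(pos), pool = pool,
             base = names(counts), qual = qual,
             count = as.integer(counts))
}

# discrete prior with given atoms and weights (normalized)
make_prior <- function(p, w = rep(1, length(p))) {
  o <- order(p)
  structure(list(p = p[o], w = (w / sum(w))[o]), class = "empirical_prior")
}

# independent brute-force re-evaluation of the four SNP-calling rules,
# working directly from the call-level definition
brute_call <- function(base, qual, min_reads = 3, min_q = 15,
                       min_frac = 0.20, min_top2 = 0.90) {
  base <- base[qual >= min_q]
  if (length(base) == 0) return(NULL)
  cand <- character()
  for (b in unique(base)) {
    cnt <- sum(base == b)
    if (cnt >= min_reads && cnt / length(base) >= min_frac)
      cand <- c(cand, b)
  }
  if (length(cand) != 2) return(NULL)
  if (sum(base %in% cand) / length(base) < min_top2) return(NULL)
  sort(cand)
}
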