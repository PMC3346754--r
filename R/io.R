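# TSV conventions: UTF-8, tab-delimited, mandatory header, '#' comments
read_tsv_checked <- function(path, required, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " ", path, " is missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Read a per-pool pileup table
#'
#' @param path TSV with columns `chrom`, `pos`, `pool`, `base`, `qual` and
#'   optionally `count`.
#' @return validated data.frame for [discover_snps()].
#' @export
read_pileup <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos", "pool", "base", "qual"),
                         "pileup")
  if (!all(df$pool %in% c("mut", "wt")))
    stop("pileup pool column must be 'mut' or 'wt'")
  df
}

#' Read a blacklist of known bad sites
#'
#' @param path 2-column TSV (`chrom`, `pos`).
#' @export
read_blacklist <- function(path) {
  read_tsv_checked(path, c("chrom", "pos"), "blacklist")
}

#' Read a SNP allele-count table
#'
#' Validates the standard SNP schema, rejects malformed rows with their line
#' numbers, rejects duplicated positions, and returns the table sorted by
#' (chrom, pos) in natural chromosome order.
#'
#' @param path TSV with columns `chrom`, `pos`, `allele_a`, `allele_b`,
#'   `mut_a`, `mut_b`, `wt_a`, `wt_b`.
#' @export
read_snp_table <- function(path) {
  cols <- c("chrom", "pos", "allele_a", "allele_b",
            "mut_a", "mut_b", "wt_a", "wt_b")
  df <- read_tsv_checked(path, cols, "SNP table")
  counts <- as.matrix(df[c("mut_a", "mut_b", "wt_a", "wt_b")])
  bad <- which(!stats::complete.cases(df[cols]) | rowSums(counts < 0) > 0 |
                 df$pos < 1 | df$allele_a == df$allele_b)
  if (length(bad))
    stop("malformed SNP table rows (after header): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (anyDuplicated(df[c("chrom", "pos")]))
    stop("duplicate (chrom, pos) in SNP table")
  for (col in c("mut_a", "mut_b", "wt_a", "wt_b"))
    df[[col]] <- as.integer(df[[col]])
  sort_snp_table(df[cols])
}

#' Write a SNP table as TSV
#'
#' @param snps SNP table.
#' @param path output path.
#' @export
write_snp_table <- function(snps, path) {
  write_tsv(snps, path)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write biallelic SNPs as VCF
#'
#' Minimal VCF 4.2 with one record per SNP: `allele_a` as REF, `allele_b`
#' as ALT, and per-pool allelic depths in the AD field of two samples, MUT
#' and WT. [read_vcf_snps()] round-trips the counts exactly.
#'
#' @param snps SNP table.
#' @param path output path.
#' @export
write_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bsrseq",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths (allele_a,allele_b)\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "MUT", "WT"), collapse = "\t"))
  lines <- hdr
  if (nrow(snps) > 0) {
    lines <- c(lines, paste(
      snps$chrom, snps$pos, ".", snps$allele_a, snps$allele_b, ".", "PASS",
      ".", "AD",
      paste0(snps$mut_a, ",", snps$mut_b),
      paste0(snps$wt_a, ",", snps$wt_b), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read SNPs back from a VCF written by [write_vcf()]
#'
#' @param path VCF path.
#' @return SNP table in the standard schema.
#' @export
read_vcf_snps <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) return(empty_snp_table())
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != 11)) stop("unexpected VCF record layout")
  f <- do.call(rbind, f)
  ad_mut <- do.call(rbind, strsplit(f[, 10], ",", fixed = TRUE))
  ad_wt <- do.call(rbind, strsplit(f[, 11], ",", fixed = TRUE))
  sort_snp_table(data.frame(
    chrom = f[, 1], pos = as.integer(f[, 2]),
    allele_a = f[, 4], allele_b = f[, 5],
    mut_a = as.integer(ad_mut[, 1]), mut_b = as.integer(ad_mut[, 2]),
    wt_a = as.integer(ad_wt[, 1]), wt_b = as.integer(ad_wt[, 2])))
}

#' Read gene models from GFF3 or BED
#'
#' GFF3 files (via rtracklayer) use `gene` features for the span and sum
#' `exon` widths per gene for the exonic length; if a gene has no exon
#' features its span length is used. BED input (6 columns, 0-based
#' half-open, converted to 1-based inclusive) takes the `name` column as
#' gene id and the span as exonic length unless `exon_lengths` supplies a
#' `gene_id`/`exon_length` TSV.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED (`.bed`) path.
#' @param exon_lengths optional TSV path with columns `gene_id`,
#'   `exon_length` (BED input only).
#' @return data.frame: `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `exon_length`.
#' @export
read_gene_models <- function(path, exon_lengths = NULL) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("rtracklayer is required to read GFF3")
    gr <- rtracklayer::import(path)
    genes <- gr[gr$type == "gene"]
    if (length(genes) == 0) stop("no gene features in ", path)
    gid <- as.character(genes$ID)
    exons <- gr[gr$type == "exon"]
    elen <- tapply(GenomicRanges::width(exons),
                   sub("\\..*$", "", as.character(exons$Parent)), sum)
    out <- data.frame(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(genes)),
      strand = as.character(GenomicRanges::strand(genes)),
      start = GenomicRanges::start(genes),
      end = GenomicRanges::end(genes),
      exon_length = GenomicRanges::width(genes))
    hit <- match(gid, names(elen))
    out$exon_length[!is.na(hit)] <- as.integer(elen[hit[!is.na(hit)]])
    return(out)
  }
  bed <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("BED input needs 6 columns")
  out <- data.frame(gene_id = bed[[4]], chrom = bed[[1]],
                    strand = bed[[6]],
                    start = bed[[2]] + 1L, end = bed[[3]],
                    exon_length = bed[[3]] - bed[[2]])
  if (!is.null(exon_lengths)) {
    el <- read_tsv_checked(exon_lengths, c("gene_id", "exon_length"))
    hit <- match(out$gene_id, el$gene_id)
    out$exon_length[!is.na(hit)] <- el$exon_length[hit[!is.na(hit)]]
  }
  out
}

#' Write a differential-expression table
#'
#' Serializes a [call_de()] result with self-describing column names
#' (`GeneID`, `mut`, `wt`, RPKM, log2FC, p/q-values, significance flag).
#'
#' @param de flagged table from [call_de()].
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  out <- data.frame(GeneID = de$gene_id, mut = de$mut_reads,
                    wt = de$wt_reads)
  if (!is.null(de$rpkm_mut)) {
    out$mut.RPKM <- de$rpkm_mut
    out$wt.RPKM <- de$rpkm_wt
  }
  out$wt.mut_log2FC <- de$log2fc
  out$wt.mut_pvalue <- de$p_value
  out$wt.mut_qvalue <- de$q_value
  out$wt.mut_sig <- de$significant
  write_tsv(out, path)
}

#' Run the whole BSR-Seq pipeline
#'
#' Either simulates an experiment (when `config$simulate` is given) or
#' ingests a pileup/SNP table, then runs SNP discovery (if starting from a
#' pileup), the linkage computation, the sliding-window scan and peak call,
#' and (when gene counts are provided or simulated) the DE stage. Every
#' intermediate table is written to `out_dir` along with the resolved
#' configuration and a plain-text run log.
#'
#' @param config list; recognised entries: `simulate` (list of
#'   [sim_config()] arguments), `pileup`, `snps`, `blacklist`, `gene_counts`
#'   (file paths), `n_mutant_plants`, `d_max`, `prior_source`,
#'   `min_pool_depth`, `window_size`, `step`, `top_k`, `min_total_reads`,
#'   `fdr`, `min_abs_log2fc`, `plot` (logical). Unknown entries are an
#'   error.
#' @param out_dir output directory, created if missing.
#' @return list with the main results (`snps`, `linkage`, `windows`,
#'   `peak`, and `de` when computed), invisibly.
#' @export
run_bsrseq <- function(config, out_dir) {
  known <- c("simulate", "pileup", "snps", "blacklist", "gene_counts",
             "n_mutant_plants", "d_max", "prior_source", "min_pool_depth",
             "window_size", "step", "top_k", "min_total_reads", "fdr",
             "min_abs_log2fc", "plot")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  get <- function(key, default) if (is.null(config[[key]])) default
    else config[[key]]
  for (key in c("pileup", "snps", "blacklist", "gene_counts"))
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("input file not found: ", config[[key]])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run_log.txt")
  log_line <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                                ..., "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  log_line("bsrseq ", as.character(utils::packageVersion("bsrseq")))
  yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))
  res <- list()
  n_plants <- get("n_mutant_plants", 32)

  stage <- function(name, expr) {
    log_line("stage ", name, " start")
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    log_line("stage ", name, " done")
    out
  }

  gene_counts <- NULL
  if (!is.null(config$simulate)) {
    truth <- stage("simulate", {
      cfg <- do.call(sim_config, config$simulate)
      simulate_bsrseq(cfg)
    })
    n_plants <- truth$cfg$n_mutant_pool
    res$snps <- truth$snps
    write_snp_table(truth$snps, file.path(out_dir, "snps.tsv"))
    write_tsv(truth$snp_truth, file.path(out_dir, "snp_truth.tsv"))
  } else if (!is.null(config$pileup)) {
    res$snps <- stage("call-snps", {
      bl <- if (is.null(config$blacklist)) NULL
        else read_blacklist(config$blacklist)
      discover_snps(read_pileup(config$pileup), blacklist = bl)
    })
    write_snp_table(res$snps, file.path(out_dir, "snps.tsv"))
    write_vcf(res$snps, file.path(out_dir, "snps.vcf"))
  } else if (!is.null(config$snps)) {
    res$snps <- stage("read-snps", {
      snps <- read_snp_table(config$snps)
      if (is.null(config$blacklist)) snps
      else apply_blacklist(snps, read_blacklist(config$blacklist))
    })
  } else stop("config must provide 'simulate', 'pileup' or 'snps'")

  res$linkage <- stage("map", linkage_probabilities(
    res$snps, n_plants = n_plants, d_max = get("d_max", 0.20),
    prior_source = get("prior_source", "all"),
    min_pool_depth = get("min_pool_depth", 5)))
  write_tsv(res$linkage, file.path(out_dir, "linkage.tsv"))

  res$windows <- stage("scan", sliding_windows(
    res$linkage, window_size = get("window_size", 50),
    step = get("step", 5)))
  write_tsv(res$windows, file.path(out_dir, "windows.tsv"))
  res$peak <- stage("peak", peak_interval(res$windows,
                                          top_k = get("top_k", 10)))
  writeLines(sprintf("%s\t%d\t%d", res$peak$chrom,
                     as.integer(res$peak$start) - 1L,
                     as.integer(res$peak$end)),
             file.path(out_dir, "peak_interval.bed"))
  if (isTRUE(get("plot", TRUE)) && nrow(res$windows) > 0) {
    ggplot2::ggsave(file.path(out_dir, "scan.png"), plot_scan(res$windows),
                    width = 10, height = 4, dpi = 150)
  }

  if (!is.null(config$gene_counts)) {
    gene_counts <- read_tsv_checked(
      config$gene_counts, c("gene_id", "mut_reads", "wt_reads"),
      "gene counts")
    res$de <- stage("dge", call_de(
      gene_counts, min_total_reads = get("min_total_reads", 40),
      fdr = get("fdr", 0.001),
      min_abs_log2fc = get("min_abs_log2fc", 0.8)))
    write_de_table(res$de, file.path(out_dir, "de.tsv"))
  }
  log_line("pipeline complete")
  invisible(res)
}
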