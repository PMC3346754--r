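#' Sliding-window scan of final linkage probabilities
#'
#' Slides a fixed-SNP-count window along each chromosome (windows never span
#' chromosomes) and records the median final probability per window. Window
#' start indices are 1, 1 + step, 1 + 2*step, ... for as long as a full
#' window fits; chromosomes with fewer SNPs than `window_size` yield no
#' windows. The window midpoint is the arithmetic mean of its first and last
#' SNP positions; the median of an even-sized window is the mean of the two
#' central order statistics.
#'
#' @param linkage data.frame from [linkage_probabilities()] (needs `chrom`,
#'   `pos`, `final`), sorted by position within chromosome.
#' @param window_size number of SNPs per window.
#' @param step number of SNPs between successive window starts.
#' @return data.frame: `chrom`, `first_pos`, `last_pos`, `midpoint`,
#'   `median_prob`.
#' @export
sliding_windows <- function(linkage, window_size = 50, step = 5) {
  if (window_size < 1 || step < 1) stop("window_size and step must be >= 1")
  stopifnot(all(c("chrom", "pos", "final") %in% names(linkage)))
  lev <- unique(linkage$chrom)[natural_chrom_order(unique(linkage$chrom))]
  out <- lapply(lev, function(cc) {
    sub <- linkage[linkage$chrom == cc, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    s <- nrow(sub)
    if (s < window_size) return(NULL)
    starts <- seq(1L, s - window_size + 1L, by = step)
    data.frame(
      chrom = cc,
      first_pos = sub$pos[starts],
      last_pos = sub$pos[starts + window_size - 1L],
      midpoint = (sub$pos[starts] + sub$pos[starts + window_size - 1L]) / 2,
      median_prob = vapply(starts, function(i)
        median(sub$final[i:(i + window_size - 1L)]), numeric(1)))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), first_pos = numeric(),
                      last_pos = numeric(), midpoint = numeric(),
                      median_prob = numeric())
  rownames(out) <- NULL
  out
}

#' Peak interval from the top-scoring windows
#'
#' Ranks windows by median linkage probability (ties broken by smaller first
#' position, then chromosome order) and returns the physical interval spanned
#' by the top `top_k`. If the top windows fall on several chromosomes, the
#' interval is restricted to the chromosome holding the single best window
#' and a warning is emitted.
#'
#' @param windows data.frame from [sliding_windows()].
#' @param top_k number of top windows to span.
#' @return list with `chrom`, `start`, `end`, `n_windows` (top windows on
#'   the reported chromosome), of class `peak_interval`.
#' @export
peak_interval <- function(windows, top_k = 10) {
  if (nrow(windows) < top_k)
    stop("fewer than top_k windows available")
  lev <- unique(windows$chrom)[natural_chrom_order(unique(windows$chrom))]
  o <- order(-windows$median_prob, windows$first_pos,
             match(windows$chrom, lev))
  top <- windows[o[seq_len(top_k)], , drop = FALSE]
  if (length(unique(top$chrom)) > 1L) {
    warning("top windows span multiple chromosomes; reporting the ",
            "chromosome of the best window")
    top <- top[top$chrom == top$chrom[1], , drop = FALSE]
  }
  structure(list(chrom = top$chrom[1],
                 start = min(top$first_pos), end = max(top$last_pos),
                 n_windows = nrow(top)),
            class = "peak_interval")
}

#' @export
print.peak_interval <- function(x, ...) {
  cat(sprintf("peak interval: %s:%s-%s (%d top windows)\n",
              x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","), x$n_windows))
  invisible(x)
}

#' Genome-scan plot of window linkage probabilities
#'
#' @param windows data.frame from [sliding_windows()].
#' @return a ggplot object (midpoint vs median probability, one panel per
#'   chromosome).
#' @export
plot_scan <- function(windows) {
  lev <- unique(windows$chrom)[natural_chrom_order(unique(windows$chrom))]
  windows$chrom <- factor(windows$chrom, levels = lev)
  ggplot2::ggplot(windows,
                  ggplot2::aes(x = .data$midpoint / 1e6,
                               y = .data$median_prob)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~chrom, nrow = 2, scales = "free_x") +
    ggplot2::labs(x = "physical position (Mb)",
                  y = "window median linkage probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}
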