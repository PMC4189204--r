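#' Poisson peak calling on fixed windows
#'
#' Global-background Poisson model: the genome is tiled in fixed windows,
#' the background rate is `lambda = URC * window / effective genome length`,
#' and a window is significant when the upper-tail Poisson probability
#' `P(X >= RC | lambda)` falls below `p_threshold`. Adjacent or overlapping
#' significant windows are merged; a merged peak keeps the total read count
#' and the minimum member p-value.
#'
#' @param read_set an `aligned_reads` object with `unique_mapped > 0`.
#' @param genome genome [Biostrings::DNAStringSet].
#' @param window window width in bp (default 100).
#' @param p_threshold per-window significance threshold (default 0.05).
#' @param effective_length optional effective genome length used for the
#'   background rate (default: total chromosome length).
#' @return object of class `peak_set`: list with `peaks` (GRanges with `rc`
#'   and `p`), `lambda`, `window`, `p_threshold`, `n_windows`,
#'   `n_significant_windows`.
#' @export
call_peaks <- function(read_set, genome, window = 100L, p_threshold = 0.05,
                       effective_length = NULL) {
  stopifnot(inherits(read_set, "aligned_reads"))
  if (read_set$unique_mapped <= 0) stopf("URC must be positive")
  sl <- genome_seqlengths(genome)
  if (is.null(effective_length)) effective_length <- sum(as.numeric(sl))
  lambda <- read_set$unique_mapped * window / effective_length
  tiles <- unlist(GenomicRanges::tileGenome(sl, tilewidth = window))
  starts <- read_starts(read_set$reads)
  rc <- GenomicRanges::countOverlaps(tiles, starts, ignore.strand = TRUE)
  pval <- stats::ppois(rc - 1, lambda, lower.tail = FALSE)
  sig <- pval < p_threshold
  merged <- GenomicRanges::reduce(tiles[sig])
  if (length(merged)) {
    ov <- GenomicRanges::findOverlaps(merged, tiles[sig])
    grp <- factor(S4Vectors::queryHits(ov), levels = seq_along(merged))
    merged$rc <- as.integer(tapply(rc[sig][S4Vectors::subjectHits(ov)],
                                   grp, sum))
    merged$p <- as.numeric(tapply(pval[sig][S4Vectors::subjectHits(ov)],
                                  grp, min))
  } else {
    merged$rc <- integer(); merged$p <- numeric()
  }
  structure(list(peaks = merged, lambda = lambda, window = window,
                 p_threshold = p_threshold, n_windows = length(tiles),
                 n_significant_windows = sum(sig)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set: %d peaks (lambda=%.4g, window=%d bp, p<%g)\n",
              length(x$peaks), x$lambda, x$window, x$p_threshold))
  invisible(x)
}

#' Fraction of the genome covered by peaks
#'
#' @param peaks a `peak_set` or GRanges.
#' @param genome genome [Biostrings::DNAStringSet].
#' @return total merged peak length divided by total chromosome length.
#' @export
peak_genome_coverage <- function(peaks, genome) {
  gr <- if (inherits(peaks, "peak_set")) peaks$peaks else peaks
  glen <- sum(as.numeric(genome_seqlengths(genome)))
  if (length(gr) == 0) return(0)
  sum(as.numeric(BiocGenerics::width(GenomicRanges::reduce(gr)))) / glen
}

#' Union of peak regions across two groups
#'
#' Assembles the candidate regions for differential methylation testing:
#' the interval union of both groups' peaks, with overlapping or abutting
#' intervals merged into maximal regions.
#'
#' @param peaks_a,peaks_b `peak_set` objects or GRanges.
#' @return GRanges of merged union regions.
#' @export
union_peak_regions <- function(peaks_a, peaks_b) {
  a <- if (inherits(peaks_a, "peak_set")) peaks_a$peaks else peaks_a
  b <- if (inherits(peaks_b, "peak_set")) peaks_b$peaks else peaks_b
  GenomicRanges::reduce(c(GenomicRanges::granges(a), GenomicRanges::granges(b)))
}
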