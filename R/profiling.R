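#' Window-normalised read-depth profile
#'
#' Tiles the genome in fixed-width windows (last window of each chromosome
#' may be shorter), assigns each read to the window containing its start
#' position, and normalises the raw count `RC` per window to
#' `RC * 1e6 / URC` (reads per window per million unique reads), so windows
#' are comparable between libraries of different depth.
#'
#' @param read_set an `aligned_reads` object with `unique_mapped > 0`.
#' @param genome genome [Biostrings::DNAStringSet] defining chromosome
#'   lengths.
#' @param window window width in bp (default 10000).
#' @return object of class `window_profile`: list with `windows` (GRanges
#'   with `rc` and `norm` columns), `window` and `urc`.
#' @export
normalize_windows <- function(read_set, genome, window = 10000L) {
  stopifnot(inherits(read_set, "aligned_reads"))
  if (read_set$unique_mapped <= 0) stopf("URC must be positive")
  sl <- genome_seqlengths(genome)
  tiles <- unlist(GenomicRanges::tileGenome(sl, tilewidth = window))
  starts <- read_starts(read_set$reads)
  rc <- GenomicRanges::countOverlaps(tiles, starts, ignore.strand = TRUE)
  tiles$rc <- rc
  tiles$norm <- rc * 1e6 / read_set$unique_mapped
  structure(list(windows = tiles, window = window,
                 urc = read_set$unique_mapped),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("window_profile: %d windows of %d bp, %d reads assigned\n",
              length(x$windows), x$window, sum(x$windows$rc)))
  invisible(x)
}

#' Per-element read proportions
#'
#' Fraction of the unique reads overlapping (by at least one base) each
#' element class of an `element_map`. A read counts toward every class it
#' overlaps, so fractions need not sum to one.
#'
#' @param read_set an `aligned_reads` object.
#' @param element_map an `element_map` from [partition_gene_elements()].
#' @return data.frame with element, reads and fraction columns.
#' @export
element_read_proportions <- function(read_set, element_map) {
  stopifnot(inherits(read_set, "aligned_reads"),
            inherits(element_map, "element_map"))
  urc <- read_set$unique_mapped
  if (urc <= 0) stopf("URC must be positive")
  reads <- read_set$reads
  n <- vapply(element_map, function(gr) {
    if (length(gr) == 0) return(0L)
    sum(GenomicRanges::countOverlaps(reads, gr, ignore.strand = TRUE) > 0)
  }, 0L)
  data.frame(element = names(element_map), reads = as.integer(n),
             fraction = as.numeric(n) / urc, row.names = NULL,
             stringsAsFactors = FALSE)
}

# per-region bin boundaries for a metagene profile, as plain vectors; bins
# ordered so that bin 1 is always biological upstream (minus-strand regions
# are reversed)
region_bins <- function(region, n_body, n_flank, flank, chrom_len) {
  a <- BiocGenerics::start(region); b <- BiocGenerics::end(region)
  minus <- as.character(GenomicRanges::strand(region)) == "-"
  fw <- flank / n_flank
  # genomic left flank bins, body bins, right flank bins
  lf <- cbind(floor(a - flank + fw * (seq_len(n_flank) - 1)),
              floor(a - flank + fw * seq_len(n_flank)) - 1)
  body_bk <- round(seq(a, b + 1, length.out = n_body + 1))
  bd <- cbind(body_bk[-(n_body + 1)], body_bk[-1] - 1)
  rf <- cbind(floor(b + 1 + fw * (seq_len(n_flank) - 1)),
              floor(b + 1 + fw * seq_len(n_flank)) - 1)
  m <- rbind(lf, bd, rf)
  idx <- seq_len(nrow(m))
  if (minus) idx <- rev(idx)
  keep <- m[, 1] >= 1 & m[, 2] <= chrom_len & m[, 2] >= m[, 1]
  list(start = m[keep, 1], end = m[keep, 2], bin = idx[keep])
}

#' Metagene / meta-island methylation profile
#'
#' Averaged normalised read depth over a fixed binning of a region class:
#' 20 fixed-width bins across each 2-kb flank, and the region body rescaled
#' to 40 bins for genes or 20 bins for CpG islands. Minus-strand regions are
#' reversed so that bin 1 is always biological upstream. The value of a bin
#' is the number of reads overlapping it (summed over regions), scaled by
#' `1e6 / URC` and divided by the number of contributing regions.
#'
#' @param read_set an `aligned_reads` object.
#' @param regions GRanges of gene spans or islands (strand respected).
#' @param kind `"gene"` (40 body bins) or `"island"` (20 body bins).
#' @param flank flank width in bp (default 2000, i.e. 100-bp flank bins).
#' @param genome optional genome for chromosome bounds; bins extending
#'   beyond a chromosome are dropped from the count (their share of the
#'   average is zero).
#' @return object of class `profile_curve`: data.frame with `bin`, `zone`
#'   (upstream/body/downstream) and `value` columns; attributes `kind`,
#'   `n_regions`, `group`.
#' @export
metagene_profile <- function(read_set, regions, kind = c("gene", "island"),
                             flank = 2000L, genome = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(read_set, "aligned_reads"))
  if (length(regions) == 0) stopf("regions must be non-empty")
  if (read_set$unique_mapped <= 0) stopf("URC must be positive")
  n_body <- if (kind == "gene") 40L else 20L
  n_flank <- 20L
  sl <- if (is.null(genome)) {
    stats::setNames(rep(Inf, length(unique(as.character(GenomeInfoDb::seqnames(regions))))),
                    unique(as.character(GenomeInfoDb::seqnames(regions))))
  } else genome_seqlengths(genome)

  wide_enough <- BiocGenerics::width(regions) >= n_body
  if (any(!wide_enough)) {
    warning(sprintf("%d region(s) shorter than %d bp skipped",
                    sum(!wide_enough), n_body))
  }
  regions <- regions[wide_enough]
  if (length(regions) == 0) stopf("no region is wide enough to profile")

  chroms <- as.character(GenomeInfoDb::seqnames(regions))
  bins <- lapply(seq_along(regions), function(i) {
    region_bins(regions[i], n_body, n_flank, flank, sl[[chroms[i]]])
  })
  all_bins <- GenomicRanges::GRanges(
    rep(chroms, vapply(bins, function(b) length(b$bin), 0L)),
    IRanges::IRanges(unlist(lapply(bins, `[[`, "start")),
                     unlist(lapply(bins, `[[`, "end"))))
  all_bins$bin <- unlist(lapply(bins, `[[`, "bin"))
  hits <- GenomicRanges::countOverlaps(all_bins, read_set$reads,
                                       ignore.strand = TRUE)
  total_bins <- n_body + 2L * n_flank
  acc <- rep(0, total_bins)
  agg <- tapply(hits, all_bins$bin, sum)
  acc[as.integer(names(agg))] <- agg
  value <- acc * 1e6 / read_set$unique_mapped / length(regions)
  zone <- c(rep("upstream", n_flank), rep("body", n_body),
            rep("downstream", n_flank))
  out <- data.frame(bin = seq_len(total_bins), zone = zone, value = value,
                    stringsAsFactors = FALSE)
  attr(out, "kind") <- kind
  attr(out, "n_regions") <- length(regions)
  attr(out, "group") <- read_set$group
  class(out) <- c("profile_curve", "data.frame")
  out
}
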