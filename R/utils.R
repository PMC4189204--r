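#' Round half away from zero
#'
#' Report-table rounding convention: ties are rounded away from zero
#' (so 0.125 -> 0.13 and -0.125 -> -0.13 at two decimals), unlike base
#' [round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_away(49.9358, 2)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# seqlengths vector from a DNAStringSet genome
genome_seqlengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

# attach seqlengths (and ordered seqlevels) from a genome to a GRanges
with_genome_seqinfo <- function(gr, genome) {
  sl <- genome_seqlengths(genome)
  GenomeInfoDb::seqlevels(gr) <- names(sl)
  GenomeInfoDb::seqlengths(gr) <- sl
  gr
}

# GRanges of 1-bp read start anchors (5' end in genomic coordinates is not
# needed here: assignment contracts use the leftmost base of the alignment)
read_starts <- function(reads) {
  GenomicRanges::resize(reads, width = 1L, fix = "start", ignore.strand = TRUE)
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}
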