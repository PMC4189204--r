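#' Count reads per repeat category
#'
#' Number of unique reads overlapping (by at least one base) each repeat
#' category; a read overlapping repeats of two categories counts in both.
#'
#' @param read_set an `aligned_reads` object.
#' @param repeats GRanges with a `category` metadata column.
#' @return named integer vector of read counts per category.
#' @export
count_repeat_reads <- function(read_set, repeats) {
  stopifnot(inherits(read_set, "aligned_reads"))
  cats <- sort(unique(repeats$category))
  vapply(cats, function(cc) {
    sum(GenomicRanges::countOverlaps(read_set$reads,
                                     repeats[repeats$category == cc],
                                     ignore.strand = TRUE) > 0)
  }, 0L)
}

#' Two-proportion u-test for repeat-category read fractions
#'
#' Compares, per repeat category, the fraction of each library's reads
#' falling in the category, with the pooled two-proportion z statistic
#' `u = (p_A - p_B) / sqrt(p(1-p)(1/n_A + 1/n_B))` where
#' `p = (x_A + x_B) / (n_A + n_B)`. A category differs between groups when
#' `|u| > 1.96` (two-sided 5% level); the sign of `u` follows the sign of
#' `p_A - p_B` (group A in excess when positive). When the pooled
#' proportion is 0 or 1 the statistic is defined as 0.
#'
#' @param reads_a,reads_b per-category read counts (named numeric vectors
#'   with the same names, or unnamed of equal length).
#' @param totals_a,totals_b the per-library denominators; by convention the
#'   unique mapped read counts.
#' @return data.frame with category, reads_a, reads_b, prop_a, prop_b, u
#'   and significant columns.
#' @export
repeat_category_test <- function(reads_a, totals_a, reads_b, totals_b) {
  if (!is.null(names(reads_a)) && !is.null(names(reads_b))) {
    if (!identical(names(reads_a), names(reads_b))) {
      reads_b <- reads_b[names(reads_a)]
    }
  }
  if (length(reads_a) != length(reads_b)) {
    stopf("reads_a and reads_b must cover the same categories")
  }
  if (any(totals_a <= 0) || any(totals_b <= 0)) stopf("totals must be positive")
  if (any(reads_a > totals_a) || any(reads_b > totals_b)) {
    stopf("category counts cannot exceed library totals")
  }
  p1 <- reads_a / totals_a
  p2 <- reads_b / totals_b
  pp <- (reads_a + reads_b) / (totals_a + totals_b)
  se <- sqrt(pp * (1 - pp) * (1 / totals_a + 1 / totals_b))
  u <- ifelse(pp <= 0 | pp >= 1, 0, (p1 - p2) / se)
  data.frame(
    category = if (is.null(names(reads_a))) seq_along(reads_a) else names(reads_a),
    reads_a = as.numeric(reads_a), reads_b = as.numeric(reads_b),
    prop_a = p1, prop_b = p2, u = u, significant = abs(u) > 1.96,
    row.names = NULL, stringsAsFactors = FALSE)
}
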