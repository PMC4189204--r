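#' Expression-tier-stratified metagene methylation profiles
#'
#' Splits genes into the four expression tiers (high, medium, low, silent)
#' using the given group's own RPKM — a gene may sit in different tiers in
#' the two groups, matching per-group profile panels — after dropping genes
#' flagged `excluded_from_profiles`, and computes a gene-body metagene
#' profile per tier from that group's MeDIP reads.
#'
#' @param read_set the group's `aligned_reads`.
#' @param records `expression_records` with tiers assigned.
#' @param models a `gene_models` object.
#' @param group which group's tiers and reads: `"abnormal"` or `"normal"`
#'   (defaults to the read set's label).
#' @param flank flank width in bp (default 2000).
#' @param genome optional genome for chromosome bounds.
#' @return object of class `tier_profiles`: named list of `profile_curve`s
#'   (`high`, `medium`, `low`, `silent`); empty tiers hold all-zero curves.
#' @export
expression_stratified_profiles <- function(read_set, records, models,
                                           group = read_set$group,
                                           flank = 2000L, genome = NULL) {
  stopifnot(inherits(read_set, "aligned_reads"),
            inherits(records, "expression_records"))
  tier_col <- if (identical(group, "normal")) "tier_normal" else "tier_abnormal"
  usable <- records[!records$excluded_from_profiles &
                      records[[tier_col]] != "excluded", ]
  spans <- gene_spans(models)
  tiers <- c("high", "medium", "low", "silent")
  out <- lapply(tiers, function(tt) {
    ids <- usable$gene_id[usable[[tier_col]] == tt]
    gs <- spans[spans$gene_id %in% ids]
    if (length(gs) == 0) {
      warning(sprintf("expression tier '%s' is empty; returning a zero curve", tt))
      zero <- data.frame(bin = seq_len(80L),
                         zone = c(rep("upstream", 20), rep("body", 40),
                                  rep("downstream", 20)),
                         value = 0, stringsAsFactors = FALSE)
      attr(zero, "kind") <- "gene"; attr(zero, "n_regions") <- 0L
      attr(zero, "group") <- group
      class(zero) <- c("profile_curve", "data.frame")
      return(zero)
    }
    metagene_profile(read_set, gs, kind = "gene", flank = flank,
                     genome = genome)
  })
  names(out) <- tiers
  structure(out, class = "tier_profiles", group = group)
}

#' Overlap between differentially methylated and expressed gene sets
#'
#' Set intersection with percentages of each set, to one decimal, rounded
#' half away from zero. Percentages are reported as `NA` with a message
#' when a set is empty.
#'
#' @param dmgs character vector of differentially methylated gene ids.
#' @param degs character vector of differentially expressed gene ids.
#' @return list with `dmgs`, `degs`, `intersection`, `pct_of_dmgs`,
#'   `pct_of_degs`.
#' @export
overlap_dmg_deg <- function(dmgs, degs) {
  dmgs <- unique(as.character(dmgs))
  degs <- unique(as.character(degs))
  inter <- intersect(dmgs, degs)
  pct <- function(n_set) {
    if (n_set == 0) {
      message("empty gene set: overlap percentage not applicable")
      return(NA_real_)
    }
    round_half_away(100 * length(inter) / n_set, 1)
  }
  list(dmgs = dmgs, degs = degs, intersection = inter,
       pct_of_dmgs = pct(length(dmgs)), pct_of_degs = pct(length(degs)))
}

#' qPCR relative quantification (2^-ddCt, Livak)
#'
#' `dCt = Cq_target - Cq_reference` per condition (replicate Cq values are
#' averaged first), `ddCt = dCt_treated - dCt_control`, fold change
#' `2^-ddCt` of the treated condition relative to the control.
#'
#' @param cq_target_treated,cq_ref_treated target and housekeeping Cq
#'   values in the treated condition (vectors of replicates allowed).
#' @param cq_target_control,cq_ref_control same for the control condition.
#' @return fold change (treated relative to control).
#' @export
#' @examples
#' ddct_fold_change(20, 15, 18, 15)  # 0.25
ddct_fold_change <- function(cq_target_treated, cq_ref_treated,
                             cq_target_control, cq_ref_control) {
  vals <- list(cq_target_treated, cq_ref_treated,
               cq_target_control, cq_ref_control)
  if (any(vapply(vals, function(v) length(v) == 0 || any(is.na(v)) ||
                   any(v <= 0), TRUE))) {
    stopf("all Cq values must be present and positive")
  }
  dct_t <- mean(cq_target_treated) - mean(cq_ref_treated)
  dct_c <- mean(cq_target_control) - mean(cq_ref_control)
  2^(-(dct_t - dct_c))
}

#' Chi-square test on bisulfite clone methylation calls
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' methylated/unmethylated CpG calls by group from sequenced bisulfite
#' clones. Fewer than 15 calls in a group triggers a soft warning (the
#' protocol sequences more than 15 clones per fragment). A zero margin
#' yields chi-square 0 and p = 1 with a warning.
#'
#' @param meth_a,unmeth_a methylated / unmethylated call counts, group A.
#' @param meth_b,unmeth_b same for group B.
#' @return list with `chi_square` and `p` (upper tail, df = 1).
#' @export
#' @examples
#' bisulfite_group_test(40, 10, 10, 40)  # chi-square 36
bisulfite_group_test <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  counts <- c(meth_a, unmeth_a, meth_b, unmeth_b)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (meth_a + unmeth_a < 15 || meth_b + unmeth_b < 15) {
    warning("fewer than 15 clone calls in a group; estimates will be unstable")
  }
  margins <- c(meth_a + unmeth_a, meth_b + unmeth_b,
               meth_a + meth_b, unmeth_a + unmeth_b)
  if (any(margins == 0)) {
    warning("zero margin in the 2x2 table; returning p = 1")
    return(list(chi_square = 0, p = 1))
  }
  stat <- pearson_chisq_2x2(meth_a, meth_a + unmeth_a,
                            meth_b, meth_b + unmeth_b)
  list(chi_square = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
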