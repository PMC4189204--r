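#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment
#' `q_(i) = min_(j >= i) (p_(j) * m / j)` capped at 1 and mapped back to
#' input order (delegates to [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order; empty input gives empty output.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must lie in [0, 1] with no NA")
  }
  stats::p.adjust(p, method = "BH")
}

# vectorised 2x2 Pearson chi-square (no continuity correction) for
# [x1, n1 - x1; x2, n2 - x2]; identical to the squared pooled two-proportion
# z statistic
pearson_chisq_2x2 <- function(x1, n1, x2, n2) {
  a <- x1; b <- n1 - x1; c_ <- x2; d <- n2 - x2
  N <- n1 + n2
  denom <- as.numeric(n1) * n2 * (a + c_) * (b + d)
  stat <- ifelse(denom > 0, N * (a * d - b * c_)^2 / denom, 0)
  stat
}

#' Differential methylation test over candidate regions
#'
#' For each candidate region, counts the reads of both groups (a read is
#' assigned to a region when its start lies inside), normalises counts to
#' per-million (`rc * 1e6 / URC`) and applies a 2x2 Pearson chi-square test
#' (no continuity correction) of region reads versus the rest of each
#' library, with Benjamini-Hochberg correction across all regions. A region
#' is called hypermethylated in group A when `p < p_max`, `q < q_max`, both
#' groups have at least one read in the region, and the normalised count of
#' A strictly exceeds `fold_min` times that of B; hypomethylated
#' symmetrically. Group A is the "abnormal" group by convention, so
#' hyper/hypo describe the abnormal methylome relative to the normal one.
#'
#' @param regions GRanges of candidate regions (typically
#'   [union_peak_regions()] output).
#' @param read_set_a,read_set_b `aligned_reads` for groups A (abnormal) and
#'   B (normal); both URCs must be positive.
#' @param fold_min minimum normalised fold change, strict (default 2).
#' @param p_max chi-square p-value threshold (default 0.05).
#' @param q_max BH q-value threshold (default 0.05).
#' @return GRanges of class input with metadata columns rc_a, rc_b, norm_a,
#'   norm_b, fold (>= 1, direction in `call`), p, q and call
#'   (hyper/hypo/none).
#' @export
differential_methylation_test <- function(regions, read_set_a, read_set_b,
                                          fold_min = 2, p_max = 0.05,
                                          q_max = 0.05) {
  stopifnot(inherits(read_set_a, "aligned_reads"),
            inherits(read_set_b, "aligned_reads"))
  n1 <- read_set_a$unique_mapped
  n2 <- read_set_b$unique_mapped
  if (n1 <= 0 || n2 <= 0) stopf("both URCs must be positive")
  regions <- GenomicRanges::granges(regions)
  rc_a <- GenomicRanges::countOverlaps(regions, read_starts(read_set_a$reads),
                                       ignore.strand = TRUE)
  rc_b <- GenomicRanges::countOverlaps(regions, read_starts(read_set_b$reads),
                                       ignore.strand = TRUE)
  norm_a <- rc_a * 1e6 / n1
  norm_b <- rc_b * 1e6 / n2
  stat <- pearson_chisq_2x2(rc_a, n1, rc_b, n2)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[rc_a == 0 & rc_b == 0] <- 1
  q <- bh_fdr(p)
  covered <- rc_a > 0 & rc_b > 0
  sig <- p < p_max & q < q_max & covered
  call <- rep("none", length(regions))
  call[sig & norm_a > fold_min * norm_b] <- "hyper"
  call[sig & norm_b > fold_min * norm_a] <- "hypo"
  fold <- ifelse(pmin(norm_a, norm_b) > 0,
                 pmax(norm_a, norm_b) / pmin(norm_a, norm_b),
                 ifelse(pmax(norm_a, norm_b) > 0, Inf, NA_real_))
  regions$rc_a <- rc_a; regions$rc_b <- rc_b
  regions$norm_a <- norm_a; regions$norm_b <- norm_b
  regions$fold <- fold
  regions$p <- p; regions$q <- q
  regions$call <- call
  regions
}

#' Annotate called regions to gene elements
#'
#' Tallies the called (hyper/hypo) regions per element class — a region
#' contributes to every class it overlaps — per chromosome, and collects
#' the differentially methylated genes (DMGs): genes whose span extended by
#' the element-map flank overlaps at least one called region.
#'
#' @param methyl_regions output of [differential_methylation_test()].
#' @param element_map an `element_map`.
#' @param models a `gene_models` object.
#' @return object of class `dmr_summary`: list with `summary` (element x
#'   hyper/hypo counts plus a Total row), `by_chromosome`, and `dmgs`
#'   (data.frame of gene_id and direction hyper/hypo/both).
#' @export
annotate_dmrs <- function(methyl_regions, element_map, models) {
  stopifnot(inherits(element_map, "element_map"))
  called <- methyl_regions[methyl_regions$call != "none"]
  classes <- names(element_map)
  tab <- t(vapply(classes, function(cl) {
    gr <- element_map[[cl]]
    if (length(gr) == 0 || length(called) == 0) return(c(hyper = 0L, hypo = 0L))
    hit <- GenomicRanges::countOverlaps(called, gr, ignore.strand = TRUE) > 0
    c(hyper = sum(hit & called$call == "hyper"),
      hypo = sum(hit & called$call == "hypo"))
  }, c(hyper = 0L, hypo = 0L)))
  summary <- data.frame(element = classes, hyper = tab[, "hyper"],
                        hypo = tab[, "hypo"], row.names = NULL,
                        stringsAsFactors = FALSE)
  summary <- rbind(summary,
                   data.frame(element = "Total", hyper = sum(summary$hyper),
                              hypo = sum(summary$hypo),
                              stringsAsFactors = FALSE))

  chroms <- sort(unique(as.character(GenomeInfoDb::seqnames(called))))
  by_chrom <- data.frame(
    chrom = chroms,
    hyper = vapply(chroms, function(ch) sum(
      as.character(GenomeInfoDb::seqnames(called)) == ch & called$call == "hyper"), 0L),
    hypo = vapply(chroms, function(ch) sum(
      as.character(GenomeInfoDb::seqnames(called)) == ch & called$call == "hypo"), 0L),
    row.names = NULL, stringsAsFactors = FALSE)

  flank <- attr(element_map, "flank")
  spans <- gene_spans(models)
  ext <- GenomicRanges::resize(spans, BiocGenerics::width(spans) + 2 * flank,
                               fix = "center")
  dmg_rows <- list()
  if (length(called) > 0 && length(ext) > 0) {
    ov <- GenomicRanges::findOverlaps(ext, called, ignore.strand = TRUE)
    if (length(ov)) {
      gid <- spans$gene_id[S4Vectors::queryHits(ov)]
      dir <- called$call[S4Vectors::subjectHits(ov)]
      agg <- tapply(dir, gid, function(d) {
        d <- unique(d)
        if (length(d) == 2) "both" else d
      })
      dmg_rows <- data.frame(gene_id = names(agg),
                             direction = as.character(agg),
                             row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  if (!is.data.frame(dmg_rows)) {
    dmg_rows <- data.frame(gene_id = character(), direction = character(),
                           stringsAsFactors = FALSE)
  }
  structure(list(summary = summary, by_chromosome = by_chrom,
                 dmgs = dmg_rows),
            class = "dmr_summary")
}

#' @export
print.dmr_summary <- function(x, ...) {
  cat("dmr_summary:\n")
  print(x$summary)
  cat(sprintf("%d differentially methylated genes\n", nrow(x$dmgs)))
  invisible(x)
}
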