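#' Filter raw RNA-seq reads
#'
#' Applies the standard pre-alignment filters, in order, to a Phred+33
#' FASTQ: (1) adaptor trimming — the longest read suffix exactly matching a
#' prefix of `adaptor` of at least `min_adaptor_match` bases is removed, and
#' the read is dropped when fewer than `min_len` bases remain; (2) reads
#' with more than 10% unknown (`N`) bases are dropped; (3) reads in which
#' more than 50% of bases have quality <= 5 are dropped. Each read is
#' removed at most once, by the first matching rule.
#'
#' @param fastq path to a FASTQ file (Phred+33).
#' @param adaptor adaptor sequence, or `NULL` to skip trimming.
#' @param out optional path; when given, the clean reads are written there
#'   as FASTQ.
#' @param max_n_frac maximum tolerated N fraction (default 0.10, strict).
#' @param max_lowq_frac maximum tolerated fraction of bases with quality
#'   <= `lowq_max` (default 0.50, strict).
#' @param lowq_max quality value counted as low (default 5).
#' @param min_len minimum read length after adaptor trimming (default 20).
#' @param min_adaptor_match minimum adaptor overlap in bases (default 8).
#' @return list with `reads` (clean [Biostrings::DNAStringSet], qualities in
#'   `mcols(reads)$qualities`) and `report` (one-row data.frame: input,
#'   removed_adaptor, removed_ambiguous, removed_low_quality, clean).
#' @export
filter_reads <- function(fastq, adaptor = NULL, out = NULL,
                         max_n_frac = 0.10, max_lowq_frac = 0.50,
                         lowq_max = 5L, min_len = 20L,
                         min_adaptor_match = 8L) {
  if (!file.exists(fastq)) stopf("FASTQ file not found: %s", fastq)
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) stopf("malformed FASTQ %s: %s", fastq, conditionMessage(e)))
  quals <- S4Vectors::mcols(reads)$qualities
  seq_chr <- as.character(reads)
  qual_chr <- as.character(quals)
  n_in <- length(reads)
  removed <- rep("", n_in)

  # (1) adaptor trim: longest suffix of the read equal to a prefix of the
  # adaptor, checked from the longest feasible overlap down
  if (!is.null(adaptor) && nzchar(adaptor)) {
    lens <- nchar(seq_chr)
    for (i in seq_len(n_in)) {
      L <- lens[i]
      for (k in seq(min(L, nchar(adaptor)), min_adaptor_match)) {
        if (substr(seq_chr[i], L - k + 1, L) == substr(adaptor, 1, k)) {
          seq_chr[i] <- substr(seq_chr[i], 1, L - k)
          qual_chr[i] <- substr(qual_chr[i], 1, L - k)
          break
        }
      }
    }
    removed[nchar(seq_chr) < min_len] <- "adaptor"
  }

  # (2) ambiguous-base filter
  n_frac <- vapply(seq_len(n_in), function(i) {
    L <- nchar(seq_chr[i])
    if (L == 0) return(1)
    lengths(regmatches(seq_chr[i], gregexpr("N", seq_chr[i], fixed = TRUE))) / L
  }, 0)
  removed[removed == "" & n_frac > max_n_frac] <- "ambiguous"

  # (3) low-quality filter (Phred+33)
  lowq_frac <- vapply(seq_len(n_in), function(i) {
    if (nchar(qual_chr[i]) == 0) return(0)
    q <- utf8ToInt(qual_chr[i]) - 33L
    mean(q <= lowq_max)
  }, 0)
  removed[removed == "" & lowq_frac > max_lowq_frac] <- "low_quality"

  keep <- removed == ""
  clean <- Biostrings::DNAStringSet(seq_chr[keep])
  names(clean) <- names(reads)[keep]
  S4Vectors::mcols(clean)$qualities <- Biostrings::BStringSet(qual_chr[keep])
  report <- data.frame(
    input = n_in,
    removed_adaptor = sum(removed == "adaptor"),
    removed_ambiguous = sum(removed == "ambiguous"),
    removed_low_quality = sum(removed == "low_quality"),
    clean = sum(keep))
  if (!is.null(out)) {
    qs <- Biostrings::QualityScaledDNAStringSet(
      clean, Biostrings::PhredQuality(S4Vectors::mcols(clean)$qualities))
    Biostrings::writeQualityScaledXStringSet(qs, out)
  }
  list(reads = clean, report = report)
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count * 1e9 / (gene_length_bp * library_mapped_reads)`.
#'
#' @param count read (tag) count for the gene; vectorised.
#' @param gene_length_bp summed exon length of the gene in bp.
#' @param library_mapped_reads total mapped reads in the library.
#' @return RPKM values.
#' @export
compute_rpkm <- function(count, gene_length_bp, library_mapped_reads) {
  if (any(gene_length_bp <= 0)) stopf("gene_length_bp must be positive")
  if (any(library_mapped_reads <= 0)) stopf("library_mapped_reads must be positive")
  count * 1e9 / (as.numeric(gene_length_bp) * as.numeric(library_mapped_reads))
}

# log P(Y = k | x) under the Audic-Claverie conditional distribution with
# library-size ratio r = N2/N1:
#   P(Y = k | x) = C(x + k, k) r^k / (1 + r)^(x + k + 1)
ac_log_pmf <- function(k, x, r) {
  lchoose(x + k, k) + k * log(r) - (x + k + 1) * log1p(r)
}

#' Audic-Claverie test for two digital expression libraries
#'
#' Exact conditional test of equal expression for tag counts `x` (library
#' 1, size `n1`) and `y` (library 2, size `n2`) under Poisson sampling.
#' Conditional on `x`, the count in library 2 follows
#' `P(Y = y | x) = (n2/n1)^y (x+y)! / (x! y! (1 + n2/n1)^(x+y+1))`. The
#' two-sided p-value doubles the smaller tail (`P(Y <= y | x)` or
#' `P(Y >= y | x)`), capped at 1. Tail sums are accumulated in log space.
#'
#' @param x,y non-negative integer tag counts (vectorised).
#' @param n1,n2 library sizes (total tags), positive.
#' @return two-sided p-values.
#' @export
#' @examples
#' ac_test(5, 0, 1e6, 1e6)  # 0.03125
ac_test <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y))) {
    stopf("x and y must be non-negative integers")
  }
  if (any(n1 <= 0) || any(n2 <= 0)) stopf("library sizes must be positive")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  vapply(seq_len(n), function(i) {
    r <- n2[i] / n1[i]
    lp <- ac_log_pmf(0:y[i], x[i], r)
    lower <- exp(logsumexp(lp))
    if (lower <= 0.5) return(min(1, 2 * lower))
    # the upper tail is the smaller one: sum it forward from y in log space
    # (1 - lower would lose all precision for tails below ~1e-16)
    k <- y[i]
    lt <- lp[y[i] + 1]
    ls <- lt
    repeat {
      lt <- lt + log(x[i] + k + 1) - log(k + 1) + log(r) - log1p(r)
      k <- k + 1
      hi <- max(ls, lt)
      ls <- hi + log1p(exp(min(ls, lt) - hi))
      if (lt < ls - 40 || k - y[i] > 1e6) break
    }
    min(1, 2 * exp(ls))
  }, 0)
}

#' Call differentially expressed genes between two libraries
#'
#' Computes per-gene RPKM in each library, the log2 ratio
#' (abnormal/normal), the Audic-Claverie p-value and its BH-adjusted
#' q-value (FDR computed over genes with at least one tag in either
#' library), and calls a gene up- or down-regulated in the abnormal group
#' when `q <= fdr_max` and `|log2 ratio| >= lfc_min`. A gene expressed in
#' only one library has an infinite log2 ratio and is callable only when
#' the nonzero count reaches `min_count_one_sided` — a minimum-evidence
#' gate rather than a pseudocount.
#'
#' @param counts_normal,counts_abnormal named numeric vectors of tag counts
#'   over the same gene universe.
#' @param gene_lengths named vector of summed exon lengths (bp).
#' @param n_normal,n_abnormal library sizes; default the column sums.
#' @param fdr_max FDR threshold (default 0.001).
#' @param lfc_min minimum |log2 ratio| (default 1).
#' @param min_count_one_sided minimum count to call a gene whose other
#'   library has zero tags (default 5).
#' @return data.frame of class `expression_records`: gene_id,
#'   count_normal, count_abnormal, rpkm_normal, rpkm_abnormal, log2_ratio,
#'   p, q, call (up/down/none), tier_normal, tier_abnormal,
#'   excluded_from_profiles.
#' @export
call_degs <- function(counts_normal, counts_abnormal, gene_lengths,
                      n_normal = sum(counts_normal),
                      n_abnormal = sum(counts_abnormal),
                      fdr_max = 0.001, lfc_min = 1,
                      min_count_one_sided = 5) {
  genes <- names(counts_normal)
  if (is.null(genes) || !setequal(genes, names(counts_abnormal)) ||
      !all(genes %in% names(gene_lengths))) {
    stopf("counts and gene_lengths must be named over the same gene universe")
  }
  counts_abnormal <- counts_abnormal[genes]
  gene_lengths <- gene_lengths[genes]
  rpkm_n <- compute_rpkm(counts_normal, gene_lengths, n_normal)
  rpkm_a <- compute_rpkm(counts_abnormal, gene_lengths, n_abnormal)
  log2_ratio <- ifelse(rpkm_n == 0 & rpkm_a == 0, NA_real_,
                       log2(rpkm_a / rpkm_n))
  testable <- counts_normal + counts_abnormal > 0
  p <- rep(NA_real_, length(genes))
  q <- rep(NA_real_, length(genes))
  p[testable] <- ac_test(counts_normal[testable], counts_abnormal[testable],
                         n_normal, n_abnormal)
  q[testable] <- bh_fdr(p[testable])
  evid_up <- is.finite(log2_ratio) | (rpkm_n == 0 & counts_abnormal >= min_count_one_sided)
  evid_dn <- is.finite(log2_ratio) | (rpkm_a == 0 & counts_normal >= min_count_one_sided)
  call <- rep("none", length(genes))
  sig <- !is.na(q) & q <= fdr_max
  call[sig & log2_ratio >= lfc_min & evid_up] <- "up"
  call[sig & log2_ratio <= -lfc_min & evid_dn] <- "down"
  out <- data.frame(
    gene_id = genes,
    count_normal = as.numeric(counts_normal),
    count_abnormal = as.numeric(counts_abnormal),
    rpkm_normal = rpkm_n, rpkm_abnormal = rpkm_a,
    log2_ratio = log2_ratio, p = p, q = q, call = call,
    row.names = NULL, stringsAsFactors = FALSE)
  classify_expression_tiers(out)
}

rpkm_tier <- function(rpkm) {
  ifelse(rpkm == 0, "silent",
         ifelse(rpkm <= 1, "low",
                ifelse(rpkm <= 10, "medium",
                       ifelse(rpkm <= 1000, "high", "excluded"))))
}

#' Assign expression tiers
#'
#' Tier bounds on RPKM: silent = 0, low = (0, 1], medium = (1, 10],
#' high = (10, 1000]; RPKM above 1000 is excluded. Genes silent in both
#' groups, or excluded in both, are flagged `excluded_from_profiles` and
#' dropped from profile analyses.
#'
#' @param records data.frame with `rpkm_normal` and `rpkm_abnormal`.
#' @return the records with `tier_normal`, `tier_abnormal` and
#'   `excluded_from_profiles` columns, classed `expression_records`.
#' @export
classify_expression_tiers <- function(records) {
  records$tier_normal <- rpkm_tier(records$rpkm_normal)
  records$tier_abnormal <- rpkm_tier(records$rpkm_abnormal)
  records$excluded_from_profiles <-
    (records$tier_normal == "silent" & records$tier_abnormal == "silent") |
    (records$tier_normal == "excluded" & records$tier_abnormal == "excluded")
  class(records) <- c("expression_records", "data.frame")
  records
}
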