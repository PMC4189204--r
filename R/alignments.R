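#' Construct an aligned read set
#'
#' Container for one group's uniquely mapped MeDIP-seq reads plus library
#' counters. `unique_mapped` (URC) is always the number of read intervals
#' held; `total_reads` and `mapped_reads` carry the library totals used for
#' mapping-rate reporting and default to URC when unknown.
#'
#' @param reads GRanges of uniquely mapped read alignments.
#' @param group group label (for example `"abnormal"` or `"normal"`).
#' @param total_reads total reads sequenced in the library.
#' @param mapped_reads reads mapped (with up to the aligner's mismatch
#'   allowance).
#' @return object of class `aligned_reads`.
#' @export
aligned_reads <- function(reads, group = NA_character_,
                          total_reads = length(reads),
                          mapped_reads = length(reads)) {
  stopifnot(is(reads, "GRanges"))
  urc <- length(reads)
  if (total_reads < mapped_reads || mapped_reads < urc) {
    stopf("need unique (%d) <= mapped (%s) <= total (%s)",
          urc, format(mapped_reads), format(total_reads))
  }
  structure(list(
    group = group,
    reads = sort(reads, ignore.strand = TRUE),
    unique_mapped = urc,
    mapped_reads = as.numeric(mapped_reads),
    total_reads = as.numeric(total_reads)
  ), class = "aligned_reads")
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat(sprintf("aligned_reads [%s]: %d unique / %s mapped / %s total\n",
              x$group, x$unique_mapped, format(x$mapped_reads, big.mark = ","),
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Load aligned reads from BED or SAM
#'
#' BED input is taken as already filtered to uniquely mapped reads. SAM
#' input is filtered: unmapped, secondary and supplementary alignments and
#' alignments with mapping quality 0 (the aligner's multi-mapper marker) are
#' dropped. Reads are sorted by (chromosome, start).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bed"` or `"sam"`.
#' @param group group label stored in the result.
#' @param total_reads,mapped_reads optional library totals (defaults: the
#'   number of unique reads retained).
#' @return an `aligned_reads` object.
#' @export
load_alignments <- function(path, format = c("auto", "bed", "sam"),
                            group = NA_character_, total_reads = NULL,
                            mapped_reads = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("alignment file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", sam = "sam",
                     stopf("cannot infer alignment format from extension '%s'", ext))
  }
  if (format == "bed") {
    check_coord_fields(path, 2, 3, 3, paste0("BED ", path))
    n_data <- length(readLines(path))
    reads <- if (n_data == 0) GenomicRanges::GRanges() else
      rtracklayer::import(path, format = "bed")
    S4Vectors::mcols(reads) <- NULL
  } else {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    param <- Rsamtools::ScanBamParam(
      what = c("rname", "pos", "strand", "qwidth", "mapq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE))
    b <- Rsamtools::scanBam(bam, param = param)[[1]]
    keep <- !is.na(b$mapq) & b$mapq > 0
    reads <- GenomicRanges::GRanges(
      as.character(b$rname[keep]),
      IRanges::IRanges(b$pos[keep], width = b$qwidth[keep]),
      strand = b$strand[keep])
  }
  aligned_reads(reads, group = group,
                total_reads = if (is.null(total_reads)) length(reads) else total_reads,
                mapped_reads = if (is.null(mapped_reads)) length(reads) else mapped_reads)
}

#' Library-level alignment summary
#'
#' Reproduces the alignment summary table arithmetic: the unique mapping
#' rate is unique mapped reads / total reads, in percent, rounded half away
#' from zero to two decimals.
#'
#' @param read_set an `aligned_reads` object.
#' @return one-row data.frame with group, total_reads, mapped_reads,
#'   unique_mapped and unique_mapping_rate_pct.
#' @export
summarize_alignment <- function(read_set) {
  stopifnot(inherits(read_set, "aligned_reads"))
  data.frame(
    group = read_set$group,
    total_reads = read_set$total_reads,
    mapped_reads = read_set$mapped_reads,
    unique_mapped = read_set$unique_mapped,
    unique_mapping_rate_pct = unique_mapping_rate(read_set$unique_mapped,
                                                 read_set$total_reads),
    stringsAsFactors = FALSE
  )
}

#' Unique mapping rate in percent
#'
#' `unique / total * 100`, rounded half away from zero to two decimals —
#' the arithmetic behind the alignment summary table.
#'
#' @param unique_mapped unique mapped read count.
#' @param total_reads total read count.
#' @return percentage to two decimals.
#' @export
#' @examples
#' unique_mapping_rate(48916719, 97959184)
unique_mapping_rate <- function(unique_mapped, total_reads) {
  if (any(total_reads <= 0)) stopf("total_reads must be positive")
  round_half_away(unique_mapped / total_reads * 100, 2)
}
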