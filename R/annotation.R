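#' Read a genome FASTA file
#'
#' Loads a FASTA file into a named [Biostrings::DNAStringSet]. Record names
#' are the first whitespace-delimited token of each header and sequences are
#' uppercased, so downstream base counting never has to worry about
#' soft-masked (lowercase) regions.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet], one element per record, in file
#'   order.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stopf("FASTA file is empty: %s", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stopf("duplicate FASTA record name: %s", nm[duplicated(nm)][1])
  }
  out <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(out) <- nm
  out
}

# light line-level validation so malformed annotation lines fail with the
# offending line number (rtracklayer's errors do not carry one)
check_coord_fields <- function(path, start_col, end_col, min_fields, what) {
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(keep) == 0) return(invisible(NULL))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad)) {
    stopf("%s: malformed line %d (expected >= %d tab-separated fields): %s",
          what, keep[bad[1]], min_fields, lines[keep[bad[1]]])
  }
  s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", start_col)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[`, "", end_col)))
  bad <- which(is.na(s) | is.na(e) | e < s)
  if (length(bad)) {
    stopf("%s: malformed coordinates at line %d: %s",
          what, keep[bad[1]], lines[keep[bad[1]]])
  }
  invisible(NULL)
}

#' Read gene models from a GTF file
#'
#' Imports exon and CDS features and collapses them per `gene_id`: exons of
#' all transcripts are unioned, so every gene carries one set of
#' non-overlapping sorted exons, the introns are the gene span minus the
#' exons, and the UTRs are derived as the exonic bases strand-5' / strand-3'
#' of the CDS span (exonic bases inside the CDS span count as coding). The
#' transcription start site (TSS) is the strand-aware 5' end of the gene
#' span.
#'
#' @param path path to a GTF file (1-based inclusive coordinates).
#' @param genome optional [Biostrings::DNAStringSet]; when supplied, features
#'   extending beyond a chromosome end are rejected.
#' @return an object of class `gene_models`: a list with `genes` (data.frame
#'   of gene_id, chrom, start, end, strand, tss, tts, length_bp), and
#'   GRanges `exons`, `cds`, `utr5`, `utr3`, `introns`, each carrying a
#'   `gene_id` metadata column.
#' @export
read_gene_models <- function(path, genome = NULL) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  check_coord_fields(path, 4, 5, 9, paste0("GTF ", path))
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) > 0 && !"gene_id" %in% names(S4Vectors::mcols(gr))) {
    stopf("GTF %s has no gene_id attribute", path)
  }
  ex <- gr[gr$type == "exon"]
  cd <- gr[gr$type == "CDS"]
  if (length(ex) == 0) {
    return(empty_gene_models())
  }
  if (!is.null(genome)) {
    sl <- genome_seqlengths(genome)
    chr_of <- as.character(GenomeInfoDb::seqnames(ex))
    unknown <- setdiff(chr_of, names(sl))
    if (length(unknown)) {
      stopf("GTF %s references unknown chromosome %s", path, unknown[1])
    }
    over <- BiocGenerics::end(ex) > sl[chr_of]
    if (any(over)) {
      stopf("exon outside declared chromosome for gene %s",
            ex$gene_id[which(over)[1]])
    }
  }

  ids <- sort(unique(ex$gene_id))
  fid <- function(x) factor(x$gene_id, ids)
  exl <- GenomicRanges::reduce(GenomicRanges::split(ex, fid(ex)))
  cdl <- GenomicRanges::reduce(GenomicRanges::split(cd, fid(cd)))
  for (g in ids) {
    if (length(cdl[[g]]) &&
        sum(BiocGenerics::width(GenomicRanges::setdiff(
          cdl[[g]], exl[[g]], ignore.strand = TRUE))) > 0) {
      stopf("CDS without matching exon for gene %s", g)
    }
  }

  strands <- vapply(split(as.character(GenomicRanges::strand(ex)),
                          fid(ex)), `[`, "", 1)[ids]

  spans <- unlist(range(exl), use.names = FALSE)
  if (length(spans) != length(ids)) {
    stopf("GTF %s: a gene_id spans multiple chromosomes or strands", path)
  }
  tss <- ifelse(strands == "-", BiocGenerics::end(spans),
                BiocGenerics::start(spans))
  tts <- ifelse(strands == "-", BiocGenerics::start(spans),
                BiocGenerics::end(spans))
  genes <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomeInfoDb::seqnames(spans)),
    start = BiocGenerics::start(spans),
    end = BiocGenerics::end(spans),
    strand = strands,
    tss = tss, tts = tts,
    length_bp = as.integer(sum(BiocGenerics::width(exl))),
    stringsAsFactors = FALSE
  )
  rownames(genes) <- NULL

  flat <- function(grl) {
    g <- unlist(grl, use.names = FALSE)
    if (length(g)) g$gene_id <- rep(names(grl), lengths(grl))
    g
  }
  exons <- flat(exl)
  GenomicRanges::strand(exons) <- strands[exons$gene_id]

  # UTRs from CDS-span subtraction, per gene
  u5l <- list(); u3l <- list(); cel <- list()
  for (g in ids) {
    gex <- exl[[g]]
    gcd <- cdl[[g]]
    if (length(gcd) == 0) next
    cs <- min(BiocGenerics::start(gcd)); ce <- max(BiocGenerics::end(gcd))
    chr <- as.character(GenomeInfoDb::seqnames(gex))[1]
    clip <- function(a, b) {
      if (b < a) return(GenomicRanges::GRanges())
      GenomicRanges::intersect(
        gex, GenomicRanges::GRanges(chr, IRanges::IRanges(a, b)),
        ignore.strand = TRUE)
    }
    left <- clip(min(BiocGenerics::start(gex)), cs - 1)
    right <- clip(ce + 1, max(BiocGenerics::end(gex)))
    body <- clip(cs, ce)
    minus <- strands[[g]] == "-"
    u5 <- if (minus) right else left
    u3 <- if (minus) left else right
    add_id <- function(x) {
      if (length(x)) { x$gene_id <- g; GenomicRanges::strand(x) <- strands[[g]] }
      x
    }
    u5l[[g]] <- add_id(u5); u3l[[g]] <- add_id(u3); cel[[g]] <- add_id(body)
  }
  cat_grs <- function(lst) {
    lst <- Filter(length, lst)
    if (length(lst) == 0) {
      g <- GenomicRanges::GRanges(); g$gene_id <- character(); return(g)
    }
    do.call(c, unname(lst))
  }

  introns <- flat(GenomicRanges::psetdiff(
    unlist(range(exl), use.names = FALSE), exl))
  if (length(introns)) GenomicRanges::strand(introns) <- strands[introns$gene_id]

  structure(list(
    genes = genes,
    exons = exons,
    cds = cat_grs(cel),
    utr5 = cat_grs(u5l),
    utr3 = cat_grs(u3l),
    introns = introns
  ), class = "gene_models")
}

empty_gene_models <- function() {
  eg <- GenomicRanges::GRanges()
  eg$gene_id <- character()
  structure(list(
    genes = data.frame(gene_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       strand = character(), tss = integer(),
                       tts = integer(), length_bp = integer(),
                       stringsAsFactors = FALSE),
    exons = eg, cds = eg, utr5 = eg, utr3 = eg, introns = eg
  ), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons, %d CDS segments\n",
              nrow(x$genes), length(x$exons), length(x$cds)))
  invisible(x)
}

#' Gene spans as a GRanges
#'
#' @param models a `gene_models` object.
#' @return stranded GRanges of gene spans with a `gene_id` column.
#' @export
gene_spans <- function(models) {
  g <- models$genes
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                               strand = g$strand)
  gr$gene_id <- g$gene_id
  gr
}

# stats for one interval [a, b] (1-based inclusive) from cumulative counts
# (leading zero); dinucleotide i spans (i, i+1) so in-window CpGs are a..b-1
region_cpg_stats <- function(cums, a, b) {
  len <- b - a + 1
  nC <- cums$C[b + 1] - cums$C[a]
  nG <- cums$G[b + 1] - cums$G[a]
  nN <- cums$N[b + 1] - cums$N[a]
  nCpG <- cums$CG[b] - cums$CG[a]
  eff <- len - nN
  gc <- if (eff > 0) (nC + nG) / eff else 0
  oe <- if (nC > 0 && nG > 0) nCpG * eff / (nC * nG) else 0
  list(len = len, gc = gc, oe = oe)
}

#' Detect CpG islands
#'
#' Sliding-window CpG-island detection in the Takai-Jones style: a
#' `min_len`-bp window is slid at 1-bp resolution; windows whose GC fraction
#' exceeds `gc_min` and whose observed/expected CpG ratio exceeds `oe_min`
#' are merged when they overlap or abut; each merged region is anchored to
#' its first and last CpG dinucleotide and then trimmed symmetrically (one
#' base per side per step, re-anchoring) until it satisfies all three
#' criteria, including strict length > `min_len`. Anchoring stops a short
#' CpG-rich feature from being reported merely because windows padding it
#' with neutral flank still clear the thresholds; symmetric trimming keeps
#' the detector mirror-symmetric under reverse complementation (CpG counts
#' are strand-symmetric). `N` bases are excluded from all counts and from
#' the effective length; the observed/expected ratio is
#' `n_CpG * L / (n_C * n_G)` with `L` the effective (non-N) length.
#'
#' @param genome a named [Biostrings::DNAStringSet] (ACGTN alphabet).
#' @param min_len minimum island length in bp (strict: islands must be
#'   longer than this).
#' @param gc_min minimum GC fraction (strict).
#' @param oe_min minimum observed/expected CpG ratio (strict).
#' @return GRanges of islands with metadata columns `gc_fraction` and
#'   `obs_exp_cpg`.
#' @export
detect_cpg_islands <- function(genome, min_len = 200L, gc_min = 0.50,
                               oe_min = 0.60) {
  out <- list()
  for (chr in names(genome)) {
    s <- as.character(genome[[chr]])
    L <- nchar(s)
    if (L < min_len) next
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    if (any(!v %in% c("A", "C", "G", "T", "N"))) {
      stopf("chromosome %s contains letters outside ACGTN", chr)
    }
    isC <- v == "C"; isG <- v == "G"; isN <- v == "N"
    cpg <- isC & c(isG[-1L], FALSE)
    cums <- list(C = c(0, cumsum(isC)), G = c(0, cumsum(isG)),
                 N = c(0, cumsum(isN)), CG = c(0, cumsum(cpg)))
    starts <- seq_len(L - min_len + 1L)
    ends <- starts + min_len - 1L
    nC <- cums$C[ends + 1] - cums$C[starts]
    nG <- cums$G[ends + 1] - cums$G[starts]
    nN <- cums$N[ends + 1] - cums$N[starts]
    nCpG <- cums$CG[ends] - cums$CG[starts]
    eff <- min_len - nN
    gc <- ifelse(eff > 0, (nC + nG) / eff, 0)
    oe <- ifelse(nC > 0 & nG > 0, nCpG * eff / (nC * nG), 0)
    ok <- gc > gc_min & oe > oe_min
    if (!any(ok)) next
    cpg_pos <- which(cpg)  # dinucleotide start positions, sorted
    r <- rle(ok)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (k in which(r$values)) {
      a <- starts[run_start[k]]
      b <- ends[run_end[k]]
      repeat {
        # anchor both ends on a CpG
        lo_i <- findInterval(a - 1L, cpg_pos) + 1L
        hi_i <- findInterval(b - 1L, cpg_pos)
        if (lo_i > hi_i || lo_i > length(cpg_pos)) { a <- NA; break }
        a <- cpg_pos[lo_i]
        b <- cpg_pos[hi_i] + 1L
        st <- region_cpg_stats(cums, a, b)
        if (st$len <= min_len) { a <- NA; break }
        if (st$gc > gc_min && st$oe > oe_min) break
        a <- a + 1L; b <- b - 1L
      }
      if (is.na(a)) next
      st <- region_cpg_stats(cums, a, b)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = a, end = b,
        gc_fraction = st$gc, obs_exp_cpg = st$oe)
    }
  }
  if (length(out) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$gc_fraction <- numeric(); gr$obs_exp_cpg <- numeric()
    return(gr)
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  gr$gc_fraction <- df$gc_fraction
  gr$obs_exp_cpg <- df$obs_exp_cpg
  with_genome_seqinfo(gr, genome)
}

#' Read a repeat annotation BED file
#'
#' BED6+1: chrom, start, end, name, score, strand, category (for example
#' `"SINE/tRNA-Glu"` or `"Satellite/centr"`). Coordinates follow the BED
#' convention (0-based half-open) and are converted to 1-based GRanges.
#'
#' @param path path to the BED6+1 file.
#' @return GRanges with `name` and `category` metadata columns.
#' @export
read_repeat_annotation <- function(path) {
  if (!file.exists(path)) stopf("repeat BED file not found: %s", path)
  check_coord_fields(path, 2, 3, 7, paste0("repeat BED ", path))
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(keep) == 0) {
    gr <- GenomicRanges::GRanges()
    gr$name <- character(); gr$category <- character()
    return(gr)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  cat_col <- vapply(fields, `[`, "", 7)
  if (any(!nzchar(cat_col))) {
    stopf("repeat BED %s: empty category at line %d", path,
          keep[which(!nzchar(cat_col))[1]])
  }
  gr <- GenomicRanges::GRanges(
    vapply(fields, `[`, "", 1),
    IRanges::IRanges(as.integer(vapply(fields, `[`, "", 2)) + 1L,
                     as.integer(vapply(fields, `[`, "", 3))),
    strand = vapply(fields, `[`, "", 6))
  gr$name <- vapply(fields, `[`, "", 4)
  gr$category <- cat_col
  gr
}

#' Partition the genome into gene-element classes
#'
#' Builds the eight element classes used for read-proportion and
#' differential-methylation annotation: strand-aware upstream/downstream
#' flanks of each gene (clipped at chromosome ends), 5' UTR, CDS, intron and
#' 3' UTR, plus genome-wide CpG islands and repeats when supplied. Classes
#' are not mutually exclusive: a base may lie both in a repeat and in an
#' intron.
#'
#' @param models a `gene_models` object.
#' @param genome genome [Biostrings::DNAStringSet] (for chromosome bounds).
#' @param cpg_islands optional GRanges of CpG islands.
#' @param repeats optional GRanges with a `category` column.
#' @param flank flank width in bp (default 2000).
#' @return an object of class `element_map`: a named list of GRanges with
#'   elements `upstream2k`, `utr5`, `cds`, `intron`, `utr3`, `downstream2k`,
#'   `cpg_island`, `repeat`; gene-linked elements keep a `gene_id` column.
#' @export
partition_gene_elements <- function(models, genome, cpg_islands = NULL,
                                    repeats = NULL, flank = 2000L) {
  spans <- gene_spans(models)
  spans <- with_genome_seqinfo(spans, genome)
  # flank() warns when clipped flanks run off a chromosome end; trim() is the
  # intended resolution, so the warning is noise here
  up <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::flank(spans, flank, start = TRUE)))
  dn <- GenomicRanges::trim(suppressWarnings(
    GenomicRanges::flank(spans, flank, start = FALSE)))
  up$gene_id <- spans$gene_id
  dn$gene_id <- spans$gene_id
  up <- up[BiocGenerics::width(up) > 0]
  dn <- dn[BiocGenerics::width(dn) > 0]
  em <- list(
    upstream2k = up,
    utr5 = models$utr5,
    cds = models$cds,
    intron = models$introns,
    utr3 = models$utr3,
    downstream2k = dn,
    cpg_island = if (is.null(cpg_islands)) GenomicRanges::GRanges() else cpg_islands,
    `repeat` = if (is.null(repeats)) GenomicRanges::GRanges() else repeats
  )
  attr(em, "flank") <- flank
  class(em) <- "element_map"
  em
}

#' @export
print.element_map <- function(x, ...) {
  n <- vapply(x, length, 0L)
  cat("element_map:", paste(sprintf("%s=%d", names(n), n), collapse = ", "), "\n")
  invisible(x)
}
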