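#' Simulation configuration
#'
#' Parameters of the synthetic two-group study. Defaults emulate the design
#' of the real experiment at desk scale: 49-bp single-end MeDIP reads, a
#' ~50% unique-mapping rate, fourfold planted methylation and expression
#' differences between the "abnormal" (group A) and "normal" (group B)
#' pools, and enough depth that every planted region expects well over 100
#' reads.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length_bp length of each chromosome.
#' @param n_genes genes placed (non-overlapping, both strands).
#' @param n_cpg_islands CpG-rich island regions planted in the sequence.
#' @param n_repeats_per_category repeats placed for each category.
#' @param repeat_categories repeat category labels.
#' @param read_length MeDIP read length in bp (49, matching the assay).
#' @param medip_depth unique MeDIP reads per group.
#' @param unique_rate unique-mapping rate used to back-compute total reads
#'   (~0.5 in the real libraries).
#' @param n_dmr_hyper,n_dmr_hypo,n_dmr_null planted methylation regions per
#'   class; null regions share the same enrichment in both groups.
#' @param dmr_width width of planted methylation regions (bp).
#' @param dmr_fold planted methylation fold change (> 1).
#' @param null_enrichment shared enrichment of null regions in both groups
#'   (> 1 makes them peaks, so they genuinely exercise the caller's
#'   false-positive gates).
#' @param n_deg_up,n_deg_down planted differentially expressed genes.
#' @param deg_fold planted expression fold change (> 1).
#' @param deg_base_rpkm expected RPKM of a planted DEG in its lower group.
#' @param rnaseq_library notional mapped tags per RNA library.
#' @param n_fastq_reads reads in the optional synthetic FASTQ.
#' @param fastq_contamination fraction of FASTQ reads violating the read
#'   filters (half excess-N, half low-quality).
#' @param seed integer seed; every generator derives its stream from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_chroms = 2L,
                              chrom_length_bp = 1000000L,
                              n_genes = 200L,
                              n_cpg_islands = 40L,
                              n_repeats_per_category = 30L,
                              repeat_categories = c(
                                "SINE/tRNA-Glu", "LINE/L1", "LINE/L2",
                                "LTR/ERVL-MaLR", "Simple_repeat",
                                "Low_complexity", "Satellite/centr"),
                              read_length = 49L,
                              medip_depth = 300000L,
                              unique_rate = 0.5,
                              n_dmr_hyper = 40L, n_dmr_hypo = 40L,
                              n_dmr_null = 200L,
                              dmr_width = 1000L,
                              dmr_fold = 4,
                              null_enrichment = 3,
                              n_deg_up = 20L, n_deg_down = 20L,
                              deg_fold = 4,
                              deg_base_rpkm = 40,
                              rnaseq_library = 2000000L,
                              n_fastq_reads = 2000L,
                              fastq_contamination = 0.1,
                              seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_chroms >= 1, chrom_length_bp >= 10000, n_genes >= 0,
              read_length >= 1, read_length <= chrom_length_bp,
              medip_depth > 0, unique_rate > 0, unique_rate <= 1,
              dmr_fold > 1, deg_fold > 1, fastq_contamination >= 0,
              fastq_contamination <= 1)
  })
  class(cfg) <- "simulation_config"
  cfg
}

# sample non-overlapping intervals of the given widths on the chromosomes,
# avoiding `occupied` (GRanges); bounded retries per interval
place_intervals <- function(widths, chrom_names, chrom_len, occupied,
                            max_tries = 200L) {
  occ <- lapply(chrom_names, function(ch) {
    if (length(occupied) == 0) return(cbind(start = numeric(0), end = numeric(0)))
    sel <- as.character(GenomeInfoDb::seqnames(occupied)) == ch
    cbind(start = BiocGenerics::start(occupied)[sel],
          end = BiocGenerics::end(occupied)[sel])
  })
  names(occ) <- chrom_names
  n <- length(widths)
  out_chr <- character(n); out_start <- integer(n)
  for (j in seq_len(n)) {
    w <- widths[j]
    done <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(chrom_names, 1)
      s <- sample.int(chrom_len - w, 1)
      e <- s + w - 1
      m <- occ[[ch]]
      if (nrow(m) == 0 || all(m[, 1] > e | m[, 2] < s)) {
        occ[[ch]] <- rbind(m, c(s, e))
        out_chr[j] <- ch; out_start[j] <- s
        done <- TRUE
        break
      }
    }
    if (!done) {
      stopf("could not place an interval of width %d after %d tries; reduce feature counts or widths",
            w, max_tries)
    }
  }
  if (n == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(out_chr, IRanges::IRanges(out_start, width = widths))
}

# CpG-depleted background sequence of length n
random_background_seq <- function(n) {
  v <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
              prob = c(0.32, 0.18, 0.18, 0.32))
  is_cpg <- which(v[-n] == "C" & v[-1] == "G")
  if (length(is_cpg)) v[is_cpg + 1] <- sample(c("A", "T"), length(is_cpg),
                                              replace = TRUE)
  paste(v, collapse = "")
}

# CpG-rich, GC-rich island sequence of (at least) length n, trimmed to n
random_island_seq <- function(n) {
  n_tokens <- n  # upper bound; CG tokens emit two bases
  tok <- sample(c("CG", "A", "C", "G", "T"), n_tokens, replace = TRUE,
                prob = c(0.15, 0.13, 0.295, 0.295, 0.13))
  substr(paste(tok, collapse = ""), 1, n)
}

#' Simulate a toy genome with annotations
#'
#' Generates a CpG-depleted random genome with planted CpG-rich islands
#' (recoverable by [detect_cpg_islands()]), non-overlapping gene models
#' (multi-exon, both strands) and repeat intervals. Fully reproducible from
#' the config seed.
#'
#' @param config a `simulation_config`.
#' @return list with `genome` (DNAStringSet), `models` (`gene_models`),
#'   `repeats` (GRanges with `category`), `island_truth` (GRanges of
#'   planted islands).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 1))
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  L <- config$chrom_length_bp

  # feature placement, all mutually non-overlapping
  occupied <- GenomicRanges::GRanges()
  island_w <- sample(1200:2000, config$n_cpg_islands, replace = TRUE)
  islands <- place_intervals(island_w, chroms, L, occupied)
  occupied <- c(occupied, islands)
  gene_w <- sample(2000:6000, config$n_genes, replace = TRUE)
  genes <- place_intervals(gene_w, chroms, L, occupied)
  occupied <- c(occupied, genes)
  n_rep <- config$n_repeats_per_category * length(config$repeat_categories)
  rep_w <- sample(150:800, n_rep, replace = TRUE)
  repeats <- place_intervals(rep_w, chroms, L, occupied)
  repeats$category <- rep(config$repeat_categories,
                          each = config$n_repeats_per_category)
  repeats$name <- sprintf("rep%d", seq_along(repeats))
  GenomicRanges::strand(repeats) <- "+"

  # sequence: background everywhere, island sequence inside planted islands
  seqs <- lapply(chroms, function(ch) random_background_seq(L))
  names(seqs) <- chroms
  for (i in seq_along(islands)) {
    ch <- as.character(GenomeInfoDb::seqnames(islands[i]))
    a <- BiocGenerics::start(islands[i]); b <- BiocGenerics::end(islands[i])
    substr(seqs[[ch]], a, b) <- random_island_seq(b - a + 1)
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- chroms

  models <- make_gene_models(genes, chroms)
  islands <- with_genome_seqinfo(islands, genome)
  list(genome = genome, models = models, repeats = repeats,
       island_truth = islands)
}

# build multi-exon gene models over placed spans; 2-5 exons, random strand
make_gene_models <- function(spans, chroms) {
  n <- length(spans)
  if (n == 0) return(empty_gene_models())
  strands <- sample(c("+", "-"), n, replace = TRUE)
  ids <- sprintf("gene%03d", seq_len(n))
  exon_rows <- list(); cds_rows <- list()
  gene_rows <- data.frame(gene_id = ids,
                          chrom = as.character(GenomeInfoDb::seqnames(spans)),
                          start = BiocGenerics::start(spans),
                          end = BiocGenerics::end(spans),
                          strand = strands, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    a <- gene_rows$start[i]; b <- gene_rows$end[i]
    w <- b - a + 1
    n_ex <- sample(2:5, 1)
    # exon/intron layout: alternate exon-intron blocks covering the span
    cuts <- sort(sample(seq(a + 100, b - 100, by = 50), 2 * n_ex - 2))
    bounds <- c(a, cuts, b)
    ex_start <- bounds[seq(1, length(bounds) - 1, by = 2)]
    ex_end <- bounds[seq(2, length(bounds), by = 2)]
    exon_rows[[i]] <- data.frame(gene_id = ids[i], chrom = gene_rows$chrom[i],
                                 start = ex_start, end = ex_end,
                                 strand = strands[i], stringsAsFactors = FALSE)
    # CDS: interior of the exon chain, leaving UTR stubs on both ends
    cds_rows[[i]] <- data.frame(gene_id = ids[i], chrom = gene_rows$chrom[i],
                                start = pmax(ex_start, ex_start[1] + 60),
                                end = pmin(ex_end, ex_end[length(ex_end)] - 60),
                                strand = strands[i], stringsAsFactors = FALSE)
    cds_rows[[i]] <- cds_rows[[i]][cds_rows[[i]]$end >= cds_rows[[i]]$start, ]
  }
  ex <- do.call(rbind, exon_rows)
  cd <- do.call(rbind, cds_rows)
  models_from_tables(gene_rows, ex, cd)
}

# assemble a gene_models object from plain exon/CDS tables; exons must be
# non-overlapping within a gene (the simulator guarantees this); all interval
# arithmetic is done on plain vectors and converted to GRanges once
models_from_tables <- function(gene_rows, ex, cd) {
  ids <- gene_rows$gene_id
  strand_of <- stats::setNames(gene_rows$strand, ids)
  f <- factor(ex$gene_id, ids)
  ex <- ex[order(as.integer(f), ex$start), ]
  f <- factor(ex$gene_id, ids)

  sp_start <- as.integer(tapply(ex$start, f, min))
  sp_end <- as.integer(tapply(ex$end, f, max))
  len_bp <- as.integer(tapply(ex$end - ex$start + 1L, f, sum))

  n <- nrow(ex)
  same <- n > 1 & c(ex$gene_id[-1] == ex$gene_id[-n], FALSE)
  in_start <- ex$end + 1L
  in_end <- c(ex$start[-1] - 1L, 0L)
  keep_in <- same & in_end >= in_start
  introns_df <- data.frame(gene_id = ex$gene_id[keep_in],
                           chrom = ex$chrom[keep_in],
                           start = in_start[keep_in], end = in_end[keep_in],
                           stringsAsFactors = FALSE)

  if (!is.null(cd) && nrow(cd) > 0) {
    fc <- factor(cd$gene_id, ids)
    cs <- tapply(cd$start, fc, min)[ex$gene_id]
    ce <- tapply(cd$end, fc, max)[ex$gene_id]
  } else {
    cs <- rep(NA_real_, n); ce <- rep(NA_real_, n)
  }
  has_cds <- !is.na(cs)
  # exon pieces left/right of the CDS span; exonic bases inside it are coding
  l_end <- pmin(ex$end, cs - 1)
  r_start <- pmax(ex$start, ce + 1)
  c_start <- pmax(ex$start, cs); c_end <- pmin(ex$end, ce)
  piece <- function(sel, start, end) {
    data.frame(gene_id = ex$gene_id[sel], chrom = ex$chrom[sel],
               start = start[sel], end = end[sel], stringsAsFactors = FALSE)
  }
  left <- piece(has_cds & l_end >= ex$start, ex$start, l_end)
  right <- piece(has_cds & ex$end >= r_start, r_start, ex$end)
  cds_df <- piece(has_cds & c_end >= c_start, c_start, c_end)
  minus_l <- strand_of[left$gene_id] == "-"
  minus_r <- strand_of[right$gene_id] == "-"
  u5_df <- rbind(left[!minus_l, ], right[minus_r, ])
  u3_df <- rbind(left[minus_l, ], right[!minus_r, ])

  mk <- function(df) {
    if (nrow(df) == 0) {
      g <- GenomicRanges::GRanges(); g$gene_id <- character(); return(g)
    }
    g <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$start, df$end),
                                strand = strand_of[df$gene_id])
    g$gene_id <- df$gene_id
    g
  }
  genes <- data.frame(
    gene_id = ids, chrom = gene_rows$chrom, start = sp_start, end = sp_end,
    strand = gene_rows$strand,
    tss = ifelse(gene_rows$strand == "-", sp_end, sp_start),
    tts = ifelse(gene_rows$strand == "-", sp_start, sp_end),
    length_bp = len_bp, stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = mk(ex), cds = mk(cds_df),
                 utr5 = mk(u5_df), utr3 = mk(u3_df),
                 introns = mk(introns_df)),
            class = "gene_models")
}

#' Plant the ground truth for methylation and expression
#'
#' Places the planted differentially methylated regions (hyper, hypo and
#' null) and assigns every gene an expected RPKM per group, with planted
#' up/down fold changes. Methylation regions preferentially sit inside gene
#' spans (so differential regions annotate to genes), with the remainder
#' intergenic. Group A is the abnormal group: `label = "hyper"` means
#' enrichment_A / enrichment_B > 1 and `label = "up"` means expression
#' higher in A.
#'
#' @param sim output of [simulate_genome()].
#' @param config a `simulation_config`.
#' @return object of class `truth_set`: list with `methyl_regions` (GRanges
#'   with enrichment_a, enrichment_b, label) and `gene_expression`
#'   (data.frame gene_id, mean_rpkm_a, mean_rpkm_b, label) and `seed`.
#' @export
plant_truth <- function(sim, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 2))
  models <- sim$models
  spans <- gene_spans(models)
  n_dmr <- config$n_dmr_hyper + config$n_dmr_hypo + config$n_dmr_null

  # genic placements: inside randomly chosen distinct gene spans wide enough
  wide <- spans[BiocGenerics::width(spans) >= config$dmr_width + 2]
  n_genic <- min(length(wide), floor(n_dmr * 0.3))
  genic_idx <- if (n_genic > 0) sample(seq_along(wide), n_genic) else integer()
  genic_chr <- character(0); genic_start <- integer(0)
  for (i in genic_idx) {
    a <- BiocGenerics::start(wide[i])
    b <- BiocGenerics::end(wide[i]) - config$dmr_width
    s <- if (b > a) sample(a:b, 1) else a
    genic_chr <- c(genic_chr, as.character(GenomeInfoDb::seqnames(wide[i])))
    genic_start <- c(genic_start, s)
  }
  genic <- GenomicRanges::GRanges(
    genic_chr, IRanges::IRanges(genic_start, width = config$dmr_width))
  inter <- place_intervals(rep(config$dmr_width, n_dmr - length(genic)),
                           names(sim$genome), config$chrom_length_bp,
                           c(GenomicRanges::granges(spans), genic))
  regions <- suppressWarnings(c(genic, inter))
  regions <- with_genome_seqinfo(regions, sim$genome)
  regions <- regions[sample(length(regions))]  # shuffle labels over placements
  lab <- c(rep("hyper", config$n_dmr_hyper), rep("hypo", config$n_dmr_hypo),
           rep("null", config$n_dmr_null))
  enr_a <- ifelse(lab == "hyper", config$dmr_fold,
                  ifelse(lab == "hypo", 1, config$null_enrichment))
  enr_b <- ifelse(lab == "hypo", config$dmr_fold,
                  ifelse(lab == "hyper", 1, config$null_enrichment))
  regions$enrichment_a <- enr_a
  regions$enrichment_b <- enr_b
  regions$label <- lab

  # expression truth: lognormal baseline spanning the low/medium/high tiers,
  # planted folds; group A = abnormal. A quarter of the planted DEGs are
  # complete on/off switches (expected RPKM 0 in one group), so the silent
  # expression tier is populated in each group's profile panel.
  ids <- models$genes$gene_id
  n <- length(ids)
  base <- exp(stats::rnorm(n, mean = log(10), sd = 1.5))
  lab_e <- rep("null", n)
  if (n > 0) {
    deg_idx <- sample(n, min(n, config$n_deg_up + config$n_deg_down))
    lab_e[deg_idx[seq_len(min(config$n_deg_up, length(deg_idx)))]] <- "up"
    if (length(deg_idx) > config$n_deg_up) {
      lab_e[deg_idx[(config$n_deg_up + 1):length(deg_idx)]] <- "down"
    }
  }
  base[lab_e != "null"] <- config$deg_base_rpkm
  mean_a <- ifelse(lab_e == "up", base * config$deg_fold, base)
  mean_b <- ifelse(lab_e == "down", base * config$deg_fold, base)
  off_up <- which(lab_e == "up")
  off_up <- off_up[seq_len(floor(length(off_up) / 4))]
  off_dn <- which(lab_e == "down")
  off_dn <- off_dn[seq_len(floor(length(off_dn) / 4))]
  mean_b[off_up] <- 0
  mean_a[off_dn] <- 0
  expr <- data.frame(gene_id = ids, mean_rpkm_a = mean_a,
                     mean_rpkm_b = mean_b, label = lab_e,
                     stringsAsFactors = FALSE)
  structure(list(methyl_regions = regions, gene_expression = expr,
                 seed = config$seed),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set (seed %s): %d methyl regions (%s), %d genes (%s)\n",
              format(x$seed), length(x$methyl_regions),
              paste(names(table(x$methyl_regions$label)),
                    table(x$methyl_regions$label), collapse = " ", sep = "="),
              nrow(x$gene_expression),
              paste(names(table(x$gene_expression$label)),
                    table(x$gene_expression$label), collapse = " ", sep = "=")))
  invisible(x)
}

#' Simulate MeDIP-seq aligned reads for one group
#'
#' Read start positions are drawn from a piecewise-constant intensity:
#' background rate 1 everywhere, multiplied by the truth region's
#' enrichment inside planted regions, rescaled so the expected unique read
#' total equals `config$medip_depth`. Per-segment counts are Poisson, so
#' the total is Poisson(depth). The total-read counter is back-computed
#' from the configured unique-mapping rate.
#'
#' @param genome the simulated genome (for chromosome lengths).
#' @param truth a `truth_set` (or `NULL` for a flat background).
#' @param config a `simulation_config`.
#' @param group `"abnormal"` (group A) or `"normal"` (group B).
#' @return an `aligned_reads` object.
#' @export
simulate_medip_reads <- function(genome, truth, config,
                                 group = c("abnormal", "normal")) {
  group <- match.arg(group)
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, if (group == "abnormal") 3 else 4))
  sl <- genome_seqlengths(genome)
  regions <- if (is.null(truth)) GenomicRanges::GRanges() else truth$methyl_regions
  enr <- if (group == "abnormal") regions$enrichment_a else regions$enrichment_b

  # piecewise segments: per chromosome, background minus regions + regions
  seg_chr <- character(); seg_start <- integer(); seg_end <- integer()
  seg_rate <- numeric()
  for (ch in names(sl)) {
    rr <- regions[as.character(GenomeInfoDb::seqnames(regions)) == ch]
    ee <- enr[as.character(GenomeInfoDb::seqnames(regions)) == ch]
    bg <- GenomicRanges::setdiff(
      GenomicRanges::GRanges(ch, IRanges::IRanges(1, sl[[ch]])),
      rr, ignore.strand = TRUE)
    seg_chr <- c(seg_chr, rep(ch, length(bg)), rep(ch, length(rr)))
    seg_start <- c(seg_start, BiocGenerics::start(bg), BiocGenerics::start(rr))
    seg_end <- c(seg_end, BiocGenerics::end(bg), BiocGenerics::end(rr))
    seg_rate <- c(seg_rate, rep(1, length(bg)), ee)
  }
  w <- seg_end - seg_start + 1
  mass <- sum(as.numeric(w) * seg_rate)
  lam <- config$medip_depth * (w * seg_rate) / mass
  counts <- stats::rpois(length(lam), lam)
  starts <- unlist(lapply(seq_along(counts), function(i) {
    if (counts[i] == 0) return(integer())
    seg_start[i] + sample.int(w[i], counts[i], replace = TRUE) - 1L
  }))
  chrs <- rep(seg_chr, counts)
  # clamp so reads stay on the chromosome
  starts <- pmin(starts, sl[chrs] - config$read_length + 1L)
  reads <- GenomicRanges::GRanges(
    chrs, IRanges::IRanges(starts, width = config$read_length),
    strand = sample(c("+", "-"), length(starts), replace = TRUE))
  reads <- with_genome_seqinfo(reads, genome)
  urc <- length(reads)
  aligned_reads(reads, group = group,
                total_reads = round(urc / config$unique_rate),
                mapped_reads = round(urc / config$unique_rate * 0.74))
}

#' Simulate RNA-seq tag counts (and optional FASTQ) for one group
#'
#' Per-gene counts are Poisson with mean
#' `rpkm * length_kb * library / 1e6` from the truth table's expected RPKM
#' for the group. The optional FASTQ holds `config$n_fastq_reads` reads of
#' which `config$fastq_contamination` violate the read filters (half with
#' >10% N bases, half with >50% bases at quality <= 5), for exercising
#' [filter_reads()].
#'
#' @param models a `gene_models` object.
#' @param truth a `truth_set`.
#' @param config a `simulation_config`.
#' @param group `"abnormal"` or `"normal"`.
#' @param fastq optional path; when given, a synthetic FASTQ is written.
#' @return list with `counts` (named vector), `library_size` (configured
#'   notional mapped total) and `fastq` (path or `NULL`).
#' @export
simulate_rnaseq <- function(models, truth, config,
                            group = c("abnormal", "normal"), fastq = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, if (group == "abnormal") 5 else 6))
  expr <- truth$gene_expression
  if (!all(expr$gene_id %in% models$genes$gene_id)) {
    stopf("truth table references genes absent from the models")
  }
  len_kb <- models$genes$length_bp[match(expr$gene_id, models$genes$gene_id)] / 1000
  mean_rpkm <- if (group == "abnormal") expr$mean_rpkm_a else expr$mean_rpkm_b
  lam <- mean_rpkm * len_kb * config$rnaseq_library / 1e6
  counts <- stats::setNames(stats::rpois(length(lam), lam), expr$gene_id)

  fastq_path <- NULL
  if (!is.null(fastq)) {
    n <- config$n_fastq_reads
    n_bad <- round(n * config$fastq_contamination)
    n_bad_n <- floor(n_bad / 2); n_bad_q <- n_bad - n_bad_n
    rl <- config$read_length
    mk_seq <- function(n_reads, n_frac) {
      vapply(seq_len(n_reads), function(i) {
        v <- sample(c("A", "C", "G", "T"), rl, replace = TRUE)
        if (n_frac > 0) {
          k <- ceiling(n_frac * rl)
          v[sample(rl, k)] <- "N"
        }
        paste(v, collapse = "")
      }, "")
    }
    mk_qual <- function(n_reads, lowq_frac) {
      vapply(seq_len(n_reads), function(i) {
        q <- sample(30:40, rl, replace = TRUE)
        if (lowq_frac > 0) {
          k <- ceiling(lowq_frac * rl)
          q[sample(rl, k)] <- sample(0:5, k, replace = TRUE)
        }
        intToUtf8(q + 33L)
      }, "")
    }
    seqs <- c(mk_seq(n - n_bad, 0), mk_seq(n_bad_n, 0.2), mk_seq(n_bad_q, 0))
    quals <- c(mk_qual(n - n_bad, 0), mk_qual(n_bad_n, 0), mk_qual(n_bad_q, 0.6))
    ord <- sample(n)
    dss <- Biostrings::DNAStringSet(seqs[ord])
    names(dss) <- sprintf("read%06d", seq_len(n))
    qs <- Biostrings::QualityScaledDNAStringSet(
      dss, Biostrings::PhredQuality(Biostrings::BStringSet(quals[ord])))
    Biostrings::writeQualityScaledXStringSet(qs, fastq)
    fastq_path <- fastq
  }
  list(counts = counts, library_size = config$rnaseq_library,
       fastq = fastq_path)
}

#' Write simulation fixtures to disk
#'
#' Serialises a full simulated data set as plain-text files: genome FASTA,
#' gene-model GTF, repeats BED6+1, per-group read BEDs, per-group count
#' TSVs, truth TSVs and a JSON manifest recording the configuration and
#' seed.
#'
#' @param outdir output directory (created if needed).
#' @param sim output of [simulate_genome()].
#' @param truth a `truth_set`.
#' @param reads named list of `aligned_reads` (names = group labels).
#' @param counts named list from [simulate_rnaseq()] per group.
#' @param config the `simulation_config` used.
#' @return invisibly, a named vector of file paths.
#' @export
write_fixtures <- function(outdir, sim, truth, reads, counts, config) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  p <- function(f) file.path(outdir, f)

  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  paths["genome"] <- p("genome.fa")

  write_gtf(sim$models, p("genes.gtf"))
  paths["gtf"] <- p("genes.gtf")

  rep_df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(sim$repeats)),
    start = BiocGenerics::start(sim$repeats) - 1L,
    end = BiocGenerics::end(sim$repeats),
    name = sim$repeats$name, score = 0,
    strand = as.character(GenomicRanges::strand(sim$repeats)),
    category = sim$repeats$category)
  utils::write.table(rep_df, p("repeats.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths["repeats"] <- p("repeats.bed")

  for (g in names(reads)) {
    rr <- reads[[g]]$reads
    bed <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(rr)),
      start = BiocGenerics::start(rr) - 1L,
      end = BiocGenerics::end(rr),
      name = ".", score = 0,
      strand = as.character(GenomicRanges::strand(rr)))
    f <- p(sprintf("reads_%s.bed", g))
    utils::write.table(bed, f, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[sprintf("reads_%s", g)] <- f
  }

  for (g in names(counts)) {
    f <- p(sprintf("counts_%s.tsv", g))
    utils::write.table(
      data.frame(gene_id = names(counts[[g]]$counts),
                 count = as.integer(counts[[g]]$counts)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[sprintf("counts_%s", g)] <- f
  }

  tm <- truth$methyl_regions
  utils::write.table(
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(tm)),
               start = BiocGenerics::start(tm), end = BiocGenerics::end(tm),
               enrichment_a = tm$enrichment_a, enrichment_b = tm$enrichment_b,
               label = tm$label),
    p("truth_methylation.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  paths["truth_methylation"] <- p("truth_methylation.tsv")

  utils::write.table(truth$gene_expression, p("truth_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths["truth_expression"] <- p("truth_expression.tsv")

  manifest <- c(unclass(config),
                list(groups = names(reads),
                     unique_mapped = lapply(reads, `[[`, "unique_mapped"),
                     total_reads = lapply(reads, `[[`, "total_reads"),
                     mapped_reads = lapply(reads, `[[`, "mapped_reads")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths["manifest"] <- p("manifest.json")
  invisible(paths)
}

# minimal GTF writer (exon + CDS features, gene_id/transcript_id attributes)
write_gtf <- function(models, path) {
  fmt <- function(gr, type) {
    if (length(gr) == 0) return(character())
    sprintf("%s\tclonemethyl\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
            as.character(GenomeInfoDb::seqnames(gr)), type,
            BiocGenerics::start(gr), BiocGenerics::end(gr),
            as.character(GenomicRanges::strand(gr)),
            gr$gene_id, gr$gene_id)
  }
  lines <- c(fmt(models$exons, "exon"), fmt(models$cds, "CDS"))
  writeLines(lines, path)
  invisible(path)
}
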