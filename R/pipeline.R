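#' Pipeline run configuration
#'
#' Bundles the simulation settings and the analysis thresholds for
#' [run_pipeline()]. The configuration (including the seed) is serialised
#' verbatim into the run's JSON summary, so a run can be reproduced
#' bit-identically.
#'
#' @param outdir output directory for all stage outputs.
#' @param seed integer master seed.
#' @param sim a `simulation_config`; defaults to the standard synthetic
#'   study at this seed.
#' @param window window size for depth normalisation (bp).
#' @param peak_window window size for peak calling (bp).
#' @param peak_p per-window Poisson significance threshold.
#' @param fold_min minimum normalised methylation fold change (strict).
#' @param alpha chi-square p and BH q threshold for methylation calls.
#' @param fdr_max FDR threshold for expression calls.
#' @param lfc_min minimum |log2 ratio| for expression calls.
#' @param flank flank width for gene elements and profiles (bp).
#' @return a `run_config` list.
#' @export
run_config <- function(outdir, seed = 1L, sim = simulation_config(seed = seed),
                       window = 10000L, peak_window = 100L, peak_p = 0.05,
                       fold_min = 2, alpha = 0.05, fdr_max = 0.001,
                       lfc_min = 1, flank = 2000L) {
  stopifnot(window > 0, peak_window > 0, peak_p > 0, fold_min > 0,
            alpha > 0, fdr_max > 0, lfc_min > 0, flank > 0)
  cfg <- list(outdir = outdir, seed = as.integer(seed), sim = sim,
              window = as.integer(window),
              peak_window = as.integer(peak_window), peak_p = peak_p,
              fold_min = fold_min, alpha = alpha, fdr_max = fdr_max,
              lfc_min = lfc_min, flank = as.integer(flank),
              groups = c(a = "abnormal", b = "normal"))
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

curve_df <- function(curve, group, tier = NA_character_) {
  data.frame(group = group, tier = tier, bin = curve$bin, zone = curve$zone,
             value = curve$value, stringsAsFactors = FALSE)
}

#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate -> methylome profiling -> differential methylation
#' -> expression -> integration on one synthetic data set, writing every
#' stage's table under `config$outdir` plus a machine-readable
#' `summary.json`. Rerunning with the same configuration reproduces every
#' output byte for byte.
#'
#' Stage outputs: `fixtures/` (FASTA/GTF/BED/TSV inputs + manifest),
#' `alignment_summary.tsv`, `element_proportions.tsv`, `repeat_tests.tsv`,
#' `window_profile_<group>.tsv`, `peaks_<group>.tsv`, `dmr_regions.tsv`,
#' `dmr_summary.tsv`, `dmr_by_chromosome.tsv`, `dmgs.tsv`, `deg_table.tsv`,
#' `tier_profiles.tsv`, `overlap_genes.tsv`, `summary.json`.
#'
#' @param config a `run_config`.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with every stage's in-memory result.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  say("[simulate] genome + truth + reads (seed %d)", config$seed)
  sim <- simulate_genome(config$sim)
  truth <- plant_truth(sim, config$sim)
  reads <- list(
    abnormal = simulate_medip_reads(sim$genome, truth, config$sim, "abnormal"),
    normal = simulate_medip_reads(sim$genome, truth, config$sim, "normal"))
  rna <- list(
    abnormal = simulate_rnaseq(sim$models, truth, config$sim, "abnormal"),
    normal = simulate_rnaseq(sim$models, truth, config$sim, "normal"))
  write_fixtures(file.path(outdir, "fixtures"), sim, truth, reads, rna,
                 config$sim)

  say("[medip] window profiles, elements, peaks, repeats")
  islands <- detect_cpg_islands(sim$genome)
  emap <- partition_gene_elements(sim$models, sim$genome,
                                  cpg_islands = islands,
                                  repeats = sim$repeats,
                                  flank = config$flank)
  aln_summary <- do.call(rbind, lapply(reads, summarize_alignment))
  write_tsv(aln_summary, file.path(outdir, "alignment_summary.tsv"))

  props <- do.call(rbind, lapply(names(reads), function(g) {
    cbind(group = g, element_read_proportions(reads[[g]], emap))
  }))
  write_tsv(props, file.path(outdir, "element_proportions.tsv"))

  profiles <- list()
  peaks <- list()
  for (g in names(reads)) {
    wp <- normalize_windows(reads[[g]], sim$genome, window = config$window)
    write_tsv(data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(wp$windows)),
      start = BiocGenerics::start(wp$windows),
      end = BiocGenerics::end(wp$windows),
      rc = wp$windows$rc, norm = wp$windows$norm),
      file.path(outdir, sprintf("window_profile_%s.tsv", g)))
    profiles[[g]] <- wp
    pk <- call_peaks(reads[[g]], sim$genome, window = config$peak_window,
                     p_threshold = config$peak_p)
    write_tsv(data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(pk$peaks)),
      start = BiocGenerics::start(pk$peaks),
      end = BiocGenerics::end(pk$peaks),
      rc = pk$peaks$rc, p = pk$peaks$p),
      file.path(outdir, sprintf("peaks_%s.tsv", g)))
    peaks[[g]] <- pk
  }

  rep_counts <- lapply(reads, count_repeat_reads, repeats = sim$repeats)
  rep_tests <- repeat_category_test(
    rep_counts$abnormal, reads$abnormal$unique_mapped,
    rep_counts$normal, reads$normal$unique_mapped)
  write_tsv(rep_tests, file.path(outdir, "repeat_tests.tsv"))

  say("[dmr] union regions + chi-square/FDR/fold calls")
  regions <- union_peak_regions(peaks$abnormal, peaks$normal)
  mr <- differential_methylation_test(regions, reads$abnormal, reads$normal,
                                      fold_min = config$fold_min,
                                      p_max = config$alpha,
                                      q_max = config$alpha)
  write_tsv(data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(mr)),
    start = BiocGenerics::start(mr), end = BiocGenerics::end(mr),
    rc_a = mr$rc_a, rc_b = mr$rc_b, norm_a = mr$norm_a, norm_b = mr$norm_b,
    fold = mr$fold, p = mr$p, q = mr$q, call = mr$call),
    file.path(outdir, "dmr_regions.tsv"))
  ann <- annotate_dmrs(mr, emap, sim$models)
  write_tsv(ann$summary, file.path(outdir, "dmr_summary.tsv"))
  write_tsv(ann$by_chromosome, file.path(outdir, "dmr_by_chromosome.tsv"))
  write_tsv(ann$dmgs, file.path(outdir, "dmgs.tsv"))

  say("[rnaseq] RPKM + digital expression test")
  lens <- stats::setNames(sim$models$genes$length_bp, sim$models$genes$gene_id)
  # library sizes are the simulated libraries' mapped totals (the gene
  # universe here is a small genome slice, so column sums understate them)
  degs <- call_degs(rna$normal$counts, rna$abnormal$counts, lens,
                    n_normal = rna$normal$library_size,
                    n_abnormal = rna$abnormal$library_size,
                    fdr_max = config$fdr_max, lfc_min = config$lfc_min)
  write_tsv(as.data.frame(degs), file.path(outdir, "deg_table.tsv"))

  say("[integrate] tier profiles + DMG x DEG overlap")
  tier_rows <- list()
  tiers <- list()
  for (g in names(reads)) {
    tp <- expression_stratified_profiles(reads[[g]], degs, sim$models,
                                         group = g, flank = config$flank,
                                         genome = sim$genome)
    tiers[[g]] <- tp
    for (tt in names(tp)) {
      tier_rows[[paste(g, tt)]] <- curve_df(tp[[tt]], g, tt)
    }
  }
  write_tsv(do.call(rbind, tier_rows), file.path(outdir, "tier_profiles.tsv"))

  deg_ids <- degs$gene_id[degs$call != "none"]
  overlap <- overlap_dmg_deg(ann$dmgs$gene_id, deg_ids)
  both <- degs[degs$gene_id %in% overlap$intersection, , drop = FALSE]
  both$methylation_direction <-
    ann$dmgs$direction[match(both$gene_id, ann$dmgs$gene_id)]
  write_tsv(as.data.frame(both), file.path(outdir, "overlap_genes.tsv"))

  summary <- list(
    config = serializable_config(config),
    n_peaks = lapply(peaks, function(p) length(p$peaks)),
    peak_genome_coverage = lapply(peaks, peak_genome_coverage,
                                  genome = sim$genome),
    n_dmr_hyper = sum(mr$call == "hyper"),
    n_dmr_hypo = sum(mr$call == "hypo"),
    n_dmgs = nrow(ann$dmgs),
    n_deg_up = sum(degs$call == "up"),
    n_deg_down = sum(degs$call == "down"),
    n_overlap = length(overlap$intersection),
    pct_of_dmgs = overlap$pct_of_dmgs,
    pct_of_degs = overlap$pct_of_degs)
  # no timings inside summary.json: outputs must be byte-identical on rerun
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] %s (%.1f s)",
      outdir, as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(sim = sim, truth = truth, reads = reads, islands = islands,
                 element_map = emap, profiles = profiles, peaks = peaks,
                 repeat_tests = rep_tests, methyl_regions = mr,
                 dmr_annotation = ann, degs = degs, tiers = tiers,
                 overlap = overlap, summary = summary))
}

serializable_config <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out
}
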