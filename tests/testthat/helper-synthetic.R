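# shared fixtures, built in code and memoised across test files

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a small-but-complete synthetic study used by most integration-style tests
small_config <- function(seed = 42L) {
  simulation_config(
    n_chroms = 1L, chrom_length_bp = 300000L, n_genes = 40L,
    n_cpg_islands = 8L, n_repeats_per_category = 4L,
    medip_depth = 60000L,
    n_dmr_hyper = 10L, n_dmr_hypo = 10L, n_dmr_null = 30L,
    n_deg_up = 8L, n_deg_down = 8L,
    n_fastq_reads = 500L,
    seed = seed)
}

small_study <- function() {
  cached("small_study", {
    cfg <- small_config()
    sim <- simulate_genome(cfg)
    truth <- plant_truth(sim, cfg)
    list(
      cfg = cfg, sim = sim, truth = truth,
      reads_a = simulate_medip_reads(sim$genome, truth, cfg, "abnormal"),
      reads_b = simulate_medip_reads(sim$genome, truth, cfg, "normal"))
  })
}

# flat (no-enrichment) reads over the small genome
flat_reads <- function(depth = 60000L, seed = 7L) {
  st <- small_study()
  cfg <- small_config(seed = seed)
  cfg$medip_depth <- as.integer(depth)
  simulate_medip_reads(st$sim$genome, NULL, cfg, "abnormal")
}

# quick constructors for handcrafted cases
toy_genome <- function(lengths = c(chr1 = 10000L)) {
  seqs <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(lengths)
  g
}

mk_reads <- function(chrom, starts, width = 49L, group = "abnormal", ...) {
  aligned_reads(GenomicRanges::GRanges(
    chrom, IRanges::IRanges(as.integer(starts), width = width)),
    group = group, ...)
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

gtf_line <- function(chrom, type, start, end, strand, gene) {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
          chrom, type, start, end, strand, gene, gene)
}

# interval Jaccard between one truth interval and the detections hitting it
jaccard_with_hits <- function(detected, truth_iv) {
  hit <- detected[GenomicRanges::countOverlaps(detected, truth_iv) > 0]
  if (length(hit) == 0) return(0)
  inter <- sum(BiocGenerics::width(GenomicRanges::intersect(
    GenomicRanges::granges(hit), GenomicRanges::granges(truth_iv),
    ignore.strand = TRUE)))
  uni <- sum(BiocGenerics::width(GenomicRanges::union(
    GenomicRanges::granges(hit), GenomicRanges::granges(truth_iv),
    ignore.strand = TRUE)))
  inter / uni
}
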