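#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic two-group study.
#
# Builds the toy genome (2 x 1 Mb), gene models, repeat annotation and
# planted truth (40 hyper / 40 hypo / 200 null methylation regions at
# fourfold enrichment; 20 up / 20 down genes at fourfold expression change),
# then simulates 49-bp MeDIP reads (~300k unique per group, ~50% unique
# mapping rate) and RNA-seq tag counts for both pools, and writes everything
# under results/fixtures/.

suppressPackageStartupMessages(library(clonemethyl))

seed <- 1L
cfg <- simulation_config(seed = seed)
message("simulating genome and annotations (seed ", seed, ") ...")
sim <- simulate_genome(cfg)
truth <- plant_truth(sim, cfg)
reads <- list(
  abnormal = simulate_medip_reads(sim$genome, truth, cfg, "abnormal"),
  normal   = simulate_medip_reads(sim$genome, truth, cfg, "normal"))
dir.create("results/fixtures", recursive = TRUE, showWarnings = FALSE)
rna <- list(
  abnormal = simulate_rnaseq(sim$models, truth, cfg, "abnormal",
                             fastq = file.path("results", "fixtures",
                                               "reads_abnormal.fastq")),
  normal   = simulate_rnaseq(sim$models, truth, cfg, "normal"))
paths <- write_fixtures("results/fixtures", sim, truth, reads, rna, cfg)

message("wrote ", length(paths), " fixture files:")
for (p in paths) message("  ", p)
message(sprintf("planted truth: %d methylation regions, %d genes (%d DEGs)",
                length(truth$methyl_regions), nrow(truth$gene_expression),
                sum(truth$gene_expression$label != "null")))
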