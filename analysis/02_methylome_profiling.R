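#!/usr/bin/env Rscript
# Stage 2 — methylome profiling from the simulated fixtures.
#
# Reads the stage-1 fixtures back through the package's parsers (so this
# stage exercises the same path a real BED/GTF/FASTA data set would take),
# then produces: the alignment summary table, 10-kb window-normalised depth
# profiles (RC * 1e6 / URC), per-element read proportions, CpG islands,
# Poisson peaks (100-bp windows, p < 0.05) with genome coverage, and the
# repeat-category u-tests.

suppressPackageStartupMessages({library(clonemethyl); library(GenomicRanges)})

fx <- "results/fixtures"
manifest <- jsonlite::read_json(file.path(fx, "manifest.json"))
genome <- read_genome_fasta(file.path(fx, "genome.fa"))
models <- read_gene_models(file.path(fx, "genes.gtf"), genome = genome)
repeats <- read_repeat_annotation(file.path(fx, "repeats.bed"))
reads <- lapply(c(abnormal = "abnormal", normal = "normal"), function(g) {
  load_alignments(file.path(fx, sprintf("reads_%s.bed", g)), group = g,
                  total_reads = manifest$total_reads[[g]],
                  mapped_reads = manifest$mapped_reads[[g]])
})

dir.create("results", showWarnings = FALSE)

summary_tab <- do.call(rbind, lapply(reads, summarize_alignment))
write.table(summary_tab, "results/alignment_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("alignment summary (unique mapping rates emulate ~50%):")
print(summary_tab, row.names = FALSE)

islands <- detect_cpg_islands(genome)
message(sprintf("detected %d CpG islands", length(islands)))
emap <- partition_gene_elements(models, genome, cpg_islands = islands,
                                repeats = repeats)

for (g in names(reads)) {
  wp <- normalize_windows(reads[[g]], genome, window = 10000L)
  write.table(data.frame(chrom = as.character(seqnames(wp$windows)),
                         start = start(wp$windows), end = end(wp$windows),
                         rc = wp$windows$rc, norm = wp$windows$norm),
              sprintf("results/window_profile_%s.tsv", g), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

props <- do.call(rbind, lapply(names(reads), function(g) {
  cbind(group = g, element_read_proportions(reads[[g]], emap))
}))
write.table(props, "results/element_proportions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("read proportions by element (repeats and introns dominate):")
print(props[props$element %in% c("repeat", "intron"), ], row.names = FALSE)

for (g in names(reads)) {
  pk <- call_peaks(reads[[g]], genome, window = 100L, p_threshold = 0.05)
  cov <- peak_genome_coverage(pk, genome)
  message(sprintf("%s: %d peaks covering %.2f%% of the genome",
                  g, length(pk$peaks), 100 * cov))
  write.table(data.frame(chrom = as.character(seqnames(pk$peaks)),
                         start = start(pk$peaks), end = end(pk$peaks),
                         rc = pk$peaks$rc, p = pk$peaks$p),
              sprintf("results/peaks_%s.tsv", g), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

cnt <- lapply(reads, count_repeat_reads, repeats = repeats)
rt <- repeat_category_test(cnt$abnormal, reads$abnormal$unique_mapped,
                           cnt$normal, reads$normal$unique_mapped)
write.table(rt, "results/repeat_tests.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("repeat categories with |u| > 1.96: %d of %d",
                sum(rt$significant), nrow(rt)))
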