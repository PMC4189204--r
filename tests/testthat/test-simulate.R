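test_that("the whole generator is deterministic under a fixed seed", {
  cfg <- small_config(seed = 5L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$models$genes, b$models$genes)
  expect_identical(as.data.frame(a$repeats), as.data.frame(b$repeats))

  ta <- plant_truth(a, cfg)
  tb <- plant_truth(b, cfg)
  expect_identical(as.data.frame(ta$methyl_regions), as.data.frame(tb$methyl_regions))
  expect_identical(ta$gene_expression, tb$gene_expression)

  ra <- simulate_medip_reads(a$genome, ta, cfg, "abnormal")
  rb <- simulate_medip_reads(b$genome, tb, cfg, "abnormal")
  expect_identical(as.data.frame(ra$reads), as.data.frame(rb$reads))

  ca <- simulate_rnaseq(a$models, ta, cfg, "normal")
  cb <- simulate_rnaseq(b$models, tb, cfg, "normal")
  expect_identical(ca$counts, cb$counts)
})

test_that("fixture files are byte-identical across reruns of one seed", {
  cfg <- small_config(seed = 9L)
  outs <- lapply(1:2, function(i) {
    sim <- simulate_genome(cfg)
    truth <- plant_truth(sim, cfg)
    reads <- list(abnormal = simulate_medip_reads(sim$genome, truth, cfg, "abnormal"))
    rna <- list(abnormal = simulate_rnaseq(sim$models, truth, cfg, "abnormal"))
    d <- file.path(tempfile(), "fx")
    write_fixtures(d, sim, truth, reads, rna, cfg)
    d
  })
  f1 <- list.files(outs[[1]])
  expect_true(length(f1) >= 6)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(outs[[1]], f))),
                     unname(tools::md5sum(file.path(outs[[2]], f))),
                     info = f)
  }
})

test_that("a gene-free configuration still yields a valid genome", {
  cfg <- small_config(seed = 3L)
  cfg$n_genes <- 0L
  cfg$n_deg_up <- 0L; cfg$n_deg_down <- 0L
  sim <- simulate_genome(cfg)
  expect_equal(Biostrings::width(sim$genome),
               rep(cfg$chrom_length_bp, cfg$n_chroms))
  expect_equal(nrow(sim$models$genes), 0)
  truth <- plant_truth(sim, cfg)
  expect_equal(nrow(truth$gene_expression), 0)
})

test_that("planted CpG islands are recovered with Jaccard >= 0.8 each", {
  st <- small_study()
  detected <- detect_cpg_islands(st$sim$genome)
  jac <- vapply(seq_along(st$sim$island_truth), function(i) {
    jaccard_with_hits(detected, st$sim$island_truth[i])
  }, 0)
  expect_true(all(jac >= 0.8))
})

test_that("flat MeDIP intensity gives Poisson-like window counts", {
  rs <- flat_reads(depth = 60000L)
  st <- small_study()
  wp <- normalize_windows(rs, st$sim$genome, window = 1000L)
  rc <- wp$windows$rc
  expect_gte(length(rc), 100)
  disp <- var(rc) / mean(rc)
  expect_gt(disp, 0.8)
  expect_lt(disp, 1.2)
})

test_that("planted methylation enrichment yields the planted count ratio", {
  st <- small_study()
  hyper <- st$truth$methyl_regions[st$truth$methyl_regions$label == "hyper"]
  rc_a <- countOverlaps(hyper, st$reads_a$reads, ignore.strand = TRUE)
  rc_b <- countOverlaps(hyper, st$reads_b$reads, ignore.strand = TRUE)
  expect_true(all(rc_b >= 100))  # deep enough for a tight ratio
  ratio <- mean(rc_a) / mean(rc_b)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("null truth regions have equal expected rates in both groups", {
  st <- small_study()
  nulls <- st$truth$methyl_regions[st$truth$methyl_regions$label == "null"]
  expect_true(all(nulls$enrichment_a == nulls$enrichment_b))
  rc_a <- countOverlaps(nulls, st$reads_a$reads, ignore.strand = TRUE)
  rc_b <- countOverlaps(nulls, st$reads_b$reads, ignore.strand = TRUE)
  # totals over all nulls agree within sampling error (~4 sigma)
  tot <- rc_a + rc_b
  expect_lt(abs(sum(rc_a) - sum(rc_b)) / sqrt(sum(tot)), 4)
})

test_that("zero-expression genes always yield zero counts", {
  st <- small_study()
  truth <- st$truth
  silent_a <- truth$gene_expression$gene_id[truth$gene_expression$mean_rpkm_a == 0]
  expect_gt(length(silent_a), 0)
  rna <- simulate_rnaseq(st$sim$models, truth, st$cfg, "abnormal")
  expect_true(all(rna$counts[silent_a] == 0))
})

test_that("planted expression folds are recovered in raw counts", {
  st <- small_study()
  truth <- st$truth$gene_expression
  ra <- simulate_rnaseq(st$sim$models, st$truth, st$cfg, "abnormal")
  rb <- simulate_rnaseq(st$sim$models, st$truth, st$cfg, "normal")
  up <- truth$gene_id[truth$label == "up" & truth$mean_rpkm_b > 0]
  expect_true(all(rb$counts[up] >= 50))
  ratio <- mean(ra$counts[up]) / mean(rb$counts[up])
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("FASTQ contamination fraction matches the configured rate", {
  st <- small_study()
  f <- tempfile(fileext = ".fastq")
  simulate_rnaseq(st$sim$models, st$truth, st$cfg, "abnormal", fastq = f)
  res <- filter_reads(f)
  removed_frac <- 1 - res$report$clean / res$report$input
  expect_gt(removed_frac, 0.08)
  expect_lt(removed_frac, 0.12)
  expect_equal(res$report$clean + res$report$removed_adaptor +
                 res$report$removed_ambiguous + res$report$removed_low_quality,
               res$report$input)
})

test_that("fixtures round-trip through the file parsers", {
  cfg <- small_config(seed = 13L)
  sim <- simulate_genome(cfg)
  truth <- plant_truth(sim, cfg)
  reads <- list(abnormal = simulate_medip_reads(sim$genome, truth, cfg, "abnormal"))
  rna <- list(abnormal = simulate_rnaseq(sim$models, truth, cfg, "abnormal"))
  d <- file.path(tempfile(), "fx")
  paths <- write_fixtures(d, sim, truth, reads, rna, cfg)

  g2 <- read_genome_fasta(paths[["genome"]])
  expect_identical(as.character(g2), as.character(sim$genome))

  m2 <- read_gene_models(paths[["gtf"]], genome = g2)
  expect_equal(m2$genes[order(m2$genes$gene_id), ],
               sim$models$genes[order(sim$models$genes$gene_id), ],
               ignore_attr = TRUE)

  r2 <- read_repeat_annotation(paths[["repeats"]])
  expect_equal(as.data.frame(granges(r2)), as.data.frame(granges(sim$repeats)))

  a2 <- load_alignments(paths[["reads_abnormal"]], format = "bed",
                        group = "abnormal")
  expect_equal(as.data.frame(granges(a2$reads)),
               as.data.frame(granges(sort(reads$abnormal$reads, ignore.strand = TRUE))))

  cts <- utils::read.table(paths[["counts_abnormal"]], header = TRUE, sep = "\t")
  expect_equal(setNames(as.numeric(cts$count), cts$gene_id),
               rna$abnormal$counts[cts$gene_id])

  manifest <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(manifest$seed, cfg$seed)
  tm <- utils::read.table(paths[["truth_methylation"]], header = TRUE, sep = "\t")
  expect_equal(nrow(tm), length(truth$methyl_regions))
})
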