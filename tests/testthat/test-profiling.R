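test_that("window normalisation applies RC*1e6/URC and conserves reads", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 50000)))
  set.seed(1)
  starts <- sample.int(49000, 500, replace = TRUE)
  rs <- mk_reads("chr1", starts)
  wp <- normalize_windows(rs, genome, window = 10000L)
  expect_equal(sum(wp$windows$rc), 500)           # every read assigned once
  expect_equal(wp$windows$norm, wp$windows$rc * 1e6 / 500)
  expect_equal(sum(wp$windows$norm), 1e6)         # conservation identity
  expect_true(all(wp$windows$rc[wp$windows$rc == 0] == 0))

  # linearity: duplicating every read doubles RC, normalised values fixed
  # only through URC, so explicit doubling of RC at fixed URC doubles norm
  rs2 <- mk_reads("chr1", c(starts, starts))
  wp2 <- normalize_windows(rs2, genome, window = 10000L)
  expect_equal(wp2$windows$rc, wp$windows$rc * 2L)
})

test_that("reads are assigned to windows by start position", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 20000)))
  # read straddles the window boundary: start 9990 -> window 1
  rs <- mk_reads("chr1", 9990)
  wp <- normalize_windows(rs, genome, window = 10000L)
  expect_equal(wp$windows$rc, c(1L, 0L))
})

test_that("element read proportions count a read in every class it overlaps", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 10000)))
  lines <- gtf_line("chr1", "exon", c(3001, 6001), c(4000, 7000), "+", "g1")
  m <- read_gene_models(write_lines_tmp(lines, ".gtf"))
  reps <- GRanges("chr1", IRanges(4500, 4700))
  reps$category <- "SINE/tRNA-Glu"
  em <- partition_gene_elements(m, genome, repeats = reps)

  # all reads inside the intron [4001, 6000]
  rs <- mk_reads("chr1", c(4100, 4200, 4300))
  pr <- element_read_proportions(rs, em)
  expect_equal(pr$fraction[pr$element == "intron"], 1.0)
  expect_equal(pr$fraction[pr$element == "cds"], 0.0)

  # one read overlapping both the repeat and the intron counts in both
  rs2 <- mk_reads("chr1", 4480)
  pr2 <- element_read_proportions(rs2, em)
  expect_equal(pr2$fraction[pr2$element == "intron"], 1.0)
  expect_equal(pr2$fraction[pr2$element == "repeat"], 1.0)
})

test_that("uniform reads give element fractions near genomic fractions", {
  st <- small_study()
  rs <- flat_reads(depth = 60000L)
  em <- partition_gene_elements(st$sim$models, st$sim$genome,
                                repeats = st$sim$repeats)
  pr <- element_read_proportions(rs, em)
  glen <- sum(as.numeric(Biostrings::width(st$sim$genome)))
  for (cl in c("intron", "cds", "upstream2k", "repeat")) {
    gr <- reduce(granges(em[[cl]]), ignore.strand = TRUE)
    # a read overlaps the class iff its start falls within the class widened
    # left by read length - 1 (exact expectation under uniform starts)
    wid <- reduce(suppressWarnings(resize(gr, width(gr) + 48L, fix = "end")),
                  ignore.strand = TRUE)
    expected <- sum(as.numeric(width(wid))) / glen
    obs <- pr$fraction[pr$element == cl]
    tol <- 5 * sqrt(expected * (1 - expected) / rs$unique_mapped) + 0.002
    expect_lt(abs(obs - expected), tol)
  }
})

test_that("metagene profile is flat for uniform reads over equal-size genes", {
  set.seed(11)
  genome <- toy_genome(c(chr1 = 500000L))
  spans <- GRanges("chr1", IRanges(seq(10000, 460000, by = 11000), width = 4000),
                   strand = rep(c("+", "-"), length.out = 41))
  cfg <- small_config(seed = 8L)
  cfg$medip_depth <- 200000L
  rs <- simulate_medip_reads(genome, NULL, cfg, "abnormal")
  pc <- metagene_profile(rs, spans, kind = "gene", genome = genome)
  expect_equal(nrow(pc), 80)
  expect_true(all(pc$value > 0))
  expect_lt(max(pc$value) / min(pc$value), 1.2)
})

test_that("reads confined to gene bodies leave flank bins empty", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 30000)))
  spans <- GRanges("chr1", IRanges(10001, 14000), strand = "+")
  rs <- mk_reads("chr1", seq(10500, 13400, by = 10))
  pc <- metagene_profile(rs, spans, kind = "gene", genome = genome)
  expect_true(all(pc$value[pc$zone %in% c("upstream", "downstream")] == 0))
  expect_gt(sum(pc$value[pc$zone == "body"]), 0)
})

test_that("island metagene recovers planted island enrichment", {
  st <- small_study()
  truth_isl <- st$sim$island_truth
  # plant 4x enrichment on the islands themselves
  regions <- granges(truth_isl)
  regions$enrichment_a <- 4
  regions$enrichment_b <- 1
  regions$label <- "hyper"
  truth <- structure(list(methyl_regions = regions,
                          gene_expression = st$truth$gene_expression,
                          seed = 1L), class = "truth_set")
  rs <- simulate_medip_reads(st$sim$genome, truth, st$cfg, "abnormal")
  pc <- metagene_profile(rs, truth_isl, kind = "island", genome = st$sim$genome)
  expect_equal(nrow(pc), 60)
  body <- mean(pc$value[pc$zone == "body"])
  flank <- mean(pc$value[pc$zone != "body"])
  expect_gt(body, 2 * flank)
})

test_that("metagene profile ignores read and region input order", {
  st <- small_study()
  spans <- gene_spans(st$sim$models)
  rs <- st$reads_a
  set.seed(3)
  shuffled <- aligned_reads(rs$reads[sample(length(rs$reads))],
                            group = rs$group, total_reads = rs$total_reads,
                            mapped_reads = rs$mapped_reads)
  p1 <- metagene_profile(rs, spans, kind = "gene", genome = st$sim$genome)
  p2 <- metagene_profile(shuffled, spans[sample(length(spans))],
                         kind = "gene", genome = st$sim$genome)
  expect_equal(p1$value, p2$value)
})

test_that("regions too short to bin are skipped with a warning", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 10000)))
  spans <- GRanges("chr1", IRanges(c(1001, 5001), width = c(20, 4000)))
  rs <- mk_reads("chr1", seq(5001, 8900, by = 100))
  expect_warning(pc <- metagene_profile(rs, spans, kind = "gene",
                                        genome = genome),
                 "skipped")
  expect_equal(attr(pc, "n_regions"), 1L)
})
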