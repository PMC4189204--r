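fastq_record <- function(name, seq, qual) c(paste0("@", name), seq, "+", qual)

test_that("read filters apply the adaptor, N and quality rules in order", {
  adaptor <- "AGATCGGAAGAGC"
  q30 <- function(n) strrep("?", n)             # Q30
  q4 <- function(n) strrep("%", n)              # Q4 (<= 5)
  clean_seq <- strrep("ACGT", 12)               # 48 bp within 49-format
  lines <- c(
    fastq_record("clean", strrep("A", 49), q30(49)),
    # 6 N of 49 = 12.2% > 10%
    fastq_record("ambig", paste0(strrep("N", 6), strrep("A", 43)), q30(49)),
    # 25 of 49 bases at Q4 = 51% > 50%
    fastq_record("lowq", strrep("A", 49), paste0(q4(25), q30(24))),
    # ends with a 10-bp adaptor prefix: trimmed, 39 bp remain
    fastq_record("adapt", paste0(strrep("G", 39), substr(adaptor, 1, 10)), q30(49)),
    # 15 bp + 34-bp adaptor overlap... trimmed to 15 < 20: dropped
    fastq_record("short", paste0(strrep("G", 15), substr(adaptor, 1, 13),
                                 strrep("A", 21)), q30(49)))
  # the 'short' read has adaptor mid-sequence, not suffix; craft a true one
  lines <- c(lines[1:16],
             fastq_record("short2", paste0(strrep("G", 15), substr(adaptor, 1, 13)),
                          q30(28)))
  f <- write_lines_tmp(lines, ".fastq")
  res <- filter_reads(f, adaptor = adaptor)
  rep <- res$report
  expect_equal(rep$input, 5)
  expect_equal(rep$removed_ambiguous, 1)
  expect_equal(rep$removed_low_quality, 1)
  expect_equal(rep$removed_adaptor, 1)
  expect_equal(rep$clean, 2)
  expect_true("clean" %in% names(res$reads))
  expect_equal(as.character(res$reads[["clean"]]), strrep("A", 49))
  expect_equal(nchar(as.character(res$reads[["adapt"]])), 39)

  # boundary: exactly 10% N (4/40) and exactly 50% low quality are retained
  edge <- c(fastq_record("n10", paste0(strrep("N", 4), strrep("A", 36)), q30(40)),
            fastq_record("q50", strrep("A", 40), paste0(q4(20), q30(20))))
  res2 <- filter_reads(write_lines_tmp(edge, ".fastq"))
  expect_equal(res2$report$clean, 2)
})

test_that("RPKM follows count * 1e9 / (length * library)", {
  expect_equal(compute_rpkm(10, 1000, 1e6), 10)
  expect_equal(compute_rpkm(0, 1000, 1e6), 0)
  expect_equal(compute_rpkm(10, 1000, 2e6), 5)   # doubling library halves it
  expect_error(compute_rpkm(1, 0, 1e6), "positive")
  # conservation: sum(rpkm * length) * library / 1e9 returns the counts
  set.seed(8)
  counts <- rpois(50, 40); len <- sample(500:5000, 50)
  rpkm <- compute_rpkm(counts, len, 3e6)
  expect_equal(sum(rpkm * len) * 3e6 / 1e9, sum(counts))
})

test_that("digital expression test matches brute-force summation", {
  expect_equal(ac_test(5, 0, 1e6, 1e6), 0.03125)
  for (x in c(0, 1, 3, 10)) expect_equal(ac_test(x, x, 2e6, 2e6), 1)

  grid <- expand.grid(x = c(0, 1, 2, 5, 13, 20), y = c(0, 1, 3, 7, 15, 20),
                      r = c(0.5, 1, 2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(ac_test(g$x, g$y, 1e6, 1e6 * g$r),
                 ac_p_oracle(g$x, g$y, g$r), tolerance = 1e-10,
                 info = sprintf("x=%d y=%d r=%g", g$x, g$y, g$r))
  }

  # distribution normalises for x up to 50
  for (r in c(0.5, 1, 2)) {
    for (x in c(0, 7, 25, 50)) {
      expect_equal(sum(ac_pmf_oracle(0:20000, x, r)), 1, tolerance = 1e-10)
    }
  }

  # the conditional lower tail is the negative binomial CDF (cross-check)
  expect_equal(sum(ac_pmf_oracle(0:7, 12, 2)),
               pnbinom(7, size = 13, prob = 1 / 3), tolerance = 1e-12)
})

test_that("digital expression test is near-symmetric and monotone", {
  # the conditional statistic is only approximately exchange-symmetric (a
  # known property): the pmf is exactly symmetric at equal library sizes,
  # p-values of the two orientations stay within a small factor, and the
  # significance decisions agree
  expect_equal(ac_pmf_oracle(7, 12, 1), ac_pmf_oracle(12, 7, 1))
  set.seed(9)
  for (i in 1:10) {
    x <- rpois(1, 40); y <- rpois(1, 15)
    n1 <- 1e6; n2 <- 1.7e6
    p1 <- ac_test(x, y, n1, n2)
    p2 <- ac_test(y, x, n2, n1)
    expect_lt(abs(log(p1 / p2)), log(2.5))
    expect_equal(p1 < 0.001, p2 < 0.001)
  }
  expect_equal(ac_test(8, 8, 2e6, 2e6), ac_test(8, 8, 2e6, 2e6))
  x <- 20
  p <- ac_test(x, c(20, 25, 30, 40, 60, 90), 1e6, 1e6)
  expect_true(all(diff(p) <= 0))
  p2 <- ac_test(x, c(20, 15, 10, 5, 1), 1e6, 1e6)
  expect_true(all(diff(p2) <= 0))
})

test_that("DEG calling applies RPKM, fold and FDR thresholds", {
  lens <- setNames(rep(1000, 6), paste0("g", 1:6))
  normal <- setNames(c(100, 100, 400, 0, 0, 0), names(lens))
  abnormal <- setNames(c(820, 130, 95, 60, 3, 0), names(lens))
  rec <- call_degs(normal, abnormal, lens, n_normal = 1e6, n_abnormal = 1e6)
  expect_s3_class(rec, "expression_records")
  expect_equal(rec$rpkm_normal[1], 100)
  expect_equal(rec$log2_ratio[1], log2(820 / 100))
  expect_equal(rec$call[1], "up")       # strong fold, tiny p
  expect_equal(rec$call[2], "none")     # fold below 2 (log2 < 1)
  expect_equal(rec$call[3], "down")
  # zero in normal: infinite ratio, callable on count evidence
  expect_equal(rec$log2_ratio[4], Inf)
  expect_equal(rec$call[4], "up")
  expect_equal(rec$call[5], "none")     # 3 tags: never near FDR <= 0.001
  expect_true(is.na(rec$p[6]))          # untestable, no tags at all
  expect_true(is.na(rec$log2_ratio[6]))

  # the minimum-count gate for one-sided genes binds at looser thresholds:
  # same q-eligible evidence, below vs above the 5-count minimum
  n2 <- setNames(c(0, 0, 300), paste0("h", 1:3))
  a2 <- setNames(c(4, 8, 300), paste0("h", 1:3))
  l2 <- setNames(rep(1000, 3), paste0("h", 1:3))
  rec2 <- call_degs(n2, a2, l2, n_normal = 1e6, n_abnormal = 1e6,
                    fdr_max = 0.2, min_count_one_sided = 5)
  expect_equal(rec2$call, c("none", "up", "none"))
})

test_that("expression tiers follow the RPKM cut-points", {
  rec <- data.frame(
    gene_id = paste0("g", 1:6),
    rpkm_normal = c(0, 0.5, 5, 50, 1500, 1),
    rpkm_abnormal = c(0, 0.5, 5, 50, 1500, 1))
  out <- classify_expression_tiers(rec)
  expect_equal(out$tier_normal,
               c("silent", "low", "medium", "high", "excluded", "low"))
  # rpkm exactly 1 is low (right-closed intervals)
  expect_equal(out$tier_normal[6], "low")
  # silent-in-both and excluded-in-both genes leave the profile analyses
  expect_equal(out$excluded_from_profiles,
               c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))

  mixed <- classify_expression_tiers(data.frame(
    gene_id = "g", rpkm_normal = 1500, rpkm_abnormal = 400))
  expect_false(mixed$excluded_from_profiles)
})

test_that("planted expression truth is recovered with null control", {
  st <- small_study()
  ra <- simulate_rnaseq(st$sim$models, st$truth, st$cfg, "abnormal")
  rb <- simulate_rnaseq(st$sim$models, st$truth, st$cfg, "normal")
  lens <- setNames(st$sim$models$genes$length_bp, st$sim$models$genes$gene_id)
  rec <- call_degs(rb$counts, ra$counts, lens,
                   n_normal = rb$library_size, n_abnormal = ra$library_size)
  truth <- st$truth$gene_expression
  m <- merge(truth, rec, by = "gene_id")
  sens <- mean(m$call[m$label != "null"] == m$label[m$label != "null"])
  expect_gte(sens, 0.9)
  null_rate <- mean(m$call[m$label == "null"] != "none")
  expect_lte(null_rate, 0.01)
})
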