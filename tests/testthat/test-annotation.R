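test_that("FASTA reader keys records by first header token and uppercases", {
  f <- write_lines_tmp(c(">chr1 some description", "acgt",
                         ">chr2", "GGCC", "ttaa"), ".fa")
  g <- read_genome_fasta(f)
  expect_identical(names(g), c("chr1", "chr2"))
  expect_identical(as.character(g[["chr1"]]), "ACGT")
  expect_identical(as.character(g[["chr2"]]), "GGCCTTAA")

  dup <- write_lines_tmp(c(">chr1", "AC", ">chr1", "GT"), ".fa")
  expect_error(read_genome_fasta(dup), "duplicate.*chr1")
  empty <- write_lines_tmp(character(), ".fa")
  expect_error(read_genome_fasta(empty), "empty")
})

test_that("gene models collapse exons and derive introns and UTRs", {
  lines <- c(
    gtf_line("chr1", "exon", 101, 200, "+", "gplus"),
    gtf_line("chr1", "exon", 301, 400, "+", "gplus"),
    gtf_line("chr1", "CDS", 151, 200, "+", "gplus"),
    gtf_line("chr1", "CDS", 301, 350, "+", "gplus"),
    gtf_line("chr1", "exon", 501, 600, "-", "gminus"),
    gtf_line("chr1", "exon", 701, 800, "-", "gminus"))
  f <- write_lines_tmp(lines, ".gtf")
  m <- read_gene_models(f)

  gp <- m$genes[m$genes$gene_id == "gplus", ]
  expect_equal(c(gp$start, gp$end, gp$tss, gp$tts), c(101, 400, 101, 400))
  gm <- m$genes[m$genes$gene_id == "gminus", ]
  expect_equal(c(gm$tss, gm$tts), c(800, 501))  # minus strand: TSS at max

  intr <- m$introns[m$introns$gene_id == "gplus"]
  expect_equal(c(start(intr), end(intr)), c(201, 300))
  # UTRs by interval subtraction: exonic bases outside the CDS span
  expect_equal(c(start(m$utr5[m$utr5$gene_id == "gplus"]),
                 end(m$utr5[m$utr5$gene_id == "gplus"])), c(101, 150))
  expect_equal(c(start(m$utr3[m$utr3$gene_id == "gplus"]),
                 end(m$utr3[m$utr3$gene_id == "gplus"])), c(351, 400))
  expect_equal(m$genes$length_bp, c(200L, 200L))
})

test_that("CDS interior of a single exon leaves both flanking UTR parts", {
  lines <- c(gtf_line("chr1", "exon", 1001, 1200, "+", "g1"),
             gtf_line("chr1", "CDS", 1051, 1150, "+", "g1"))
  m <- read_gene_models(write_lines_tmp(lines, ".gtf"))
  # independent oracle: plain interval subtraction of the CDS span
  exon <- IRanges::IRanges(1001, 1200)
  cds_span <- IRanges::IRanges(1051, 1150)
  parts <- IRanges::setdiff(exon, cds_span)
  expect_equal(start(m$utr5), start(parts)[1])
  expect_equal(end(m$utr5), end(parts)[1])
  expect_equal(start(m$utr3), start(parts)[2])
  expect_equal(end(m$utr3), end(parts)[2])
})

test_that("gene model reader rejects inconsistent inputs with identifiers", {
  bad_cds <- c(gtf_line("chr1", "exon", 101, 200, "+", "gbad"),
               gtf_line("chr1", "CDS", 250, 300, "+", "gbad"))
  expect_error(read_gene_models(write_lines_tmp(bad_cds, ".gtf")), "gbad")

  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 150)))
  over <- gtf_line("chr1", "exon", 101, 200, "+", "gover")
  expect_error(read_gene_models(write_lines_tmp(over, ".gtf"), genome = genome),
               "gover")

  malformed <- c("chr1\ttest\texon\tnotanumber\t200\t.\t+\t.\tgene_id \"x\";")
  expect_error(read_gene_models(write_lines_tmp(malformed, ".gtf")), "line 1")
})

test_that("CpG island detection follows the length/GC/obs-exp criteria", {
  allA <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 300)))
  expect_length(detect_cpg_islands(allA), 0)

  cg <- Biostrings::DNAStringSet(c(chr1 = strrep("CG", 150)))
  isl <- detect_cpg_islands(cg)
  expect_length(isl, 1)
  expect_equal(c(start(isl), end(isl)), c(1, 300))
  expect_equal(isl$gc_fraction, 1.0)
  expect_equal(isl$obs_exp_cpg, (150 * 300) / (150 * 150))  # = 2

  # a qualifying CpG-rich block of only 150 bp must not be reported
  flanked <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("AT", 150), strrep("CG", 75), strrep("AT", 150))))
  expect_length(detect_cpg_islands(flanked), 0)
})

test_that("emitted islands re-satisfy their invariants when re-measured", {
  st <- small_study()
  isl <- detect_cpg_islands(st$sim$genome)
  expect_gt(length(isl), 0)
  for (i in seq_along(isl)) {
    s <- Biostrings::subseq(st$sim$genome[[as.character(seqnames(isl[i]))]],
                            start(isl[i]), end(isl[i]))
    L <- length(s)
    nC <- Biostrings::countPattern("C", s)
    nG <- Biostrings::countPattern("G", s)
    nCpG <- Biostrings::countPattern("CG", s)
    expect_gt(L, 200)
    expect_gt((nC + nG) / L, 0.50)
    expect_gt(nCpG * L / (nC * nG), 0.60)
    expect_equal(isl$gc_fraction[i], (nC + nG) / L)
    expect_equal(isl$obs_exp_cpg[i], nCpG * L / (nC * nG))
  }
})

test_that("island coordinates mirror under reverse complementation", {
  st <- small_study()
  isl <- detect_cpg_islands(st$sim$genome)
  rc <- Biostrings::reverseComplement(st$sim$genome)
  isl_rc <- detect_cpg_islands(rc)
  sl <- setNames(Biostrings::width(st$sim$genome), names(st$sim$genome))
  mirrored <- GenomicRanges::GRanges(
    seqnames(isl_rc),
    IRanges::IRanges(sl[as.character(seqnames(isl_rc))] - end(isl_rc) + 1,
                     sl[as.character(seqnames(isl_rc))] - start(isl_rc) + 1))
  expect_equal(as.data.frame(GenomicRanges::granges(sort(mirrored)))[1:3],
               as.data.frame(GenomicRanges::granges(sort(isl)))[1:3])
})

test_that("gene elements partition each gene span exactly", {
  st <- small_study()
  em <- partition_gene_elements(st$sim$models, st$sim$genome)
  for (g in st$sim$models$genes$gene_id) {
    pieces <- c(
      GenomicRanges::granges(em$utr5[em$utr5$gene_id == g]),
      GenomicRanges::granges(em$cds[em$cds$gene_id == g]),
      GenomicRanges::granges(em$intron[em$intron$gene_id == g]),
      GenomicRanges::granges(em$utr3[em$utr3$gene_id == g]))
    got <- GenomicRanges::reduce(pieces, ignore.strand = TRUE)
    row <- st$sim$models$genes[st$sim$models$genes$gene_id == g, ]
    expect_equal(length(got), 1)
    expect_equal(c(start(got), end(got)), c(row$start, row$end))
    # no overlaps between the pieces of one gene
    expect_equal(sum(width(pieces)), sum(width(got)))
  }
})

test_that("flanks are strand-aware and clipped at chromosome ends", {
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 10000)))
  lines <- c(gtf_line("chr1", "exon", 5001, 8000, "+", "gplus"),
             gtf_line("chr1", "exon", 5001, 8000, "-", "gminus"),
             gtf_line("chr1", "exon", 501, 1500, "+", "gedge"))
  m <- read_gene_models(write_lines_tmp(lines, ".gtf"))
  em <- partition_gene_elements(m, genome, flank = 2000L)
  up <- em$upstream2k
  expect_equal(c(start(up[up$gene_id == "gplus"]), end(up[up$gene_id == "gplus"])),
               c(3001, 5000))
  expect_equal(c(start(up[up$gene_id == "gminus"]), end(up[up$gene_id == "gminus"])),
               c(8001, 10000))
  expect_equal(c(start(up[up$gene_id == "gedge"]), end(up[up$gene_id == "gedge"])),
               c(1, 500))  # clipped at the chromosome start
  dn <- em$downstream2k
  expect_equal(c(start(dn[dn$gene_id == "gminus"]), end(dn[dn$gene_id == "gminus"])),
               c(3001, 5000))
})

test_that("repeat BED reader validates the category column", {
  ok <- "chr1\t0\t100\trep1\t0\t+\tSINE/tRNA-Glu"
  r <- read_repeat_annotation(write_lines_tmp(ok, ".bed"))
  expect_equal(start(r), 1)  # BED is 0-based half-open
  expect_equal(end(r), 100)
  expect_equal(r$category, "SINE/tRNA-Glu")
  bad <- "chr1\t0\t100\trep1\t0\t+"
  expect_error(read_repeat_annotation(write_lines_tmp(bad, ".bed")), "line 1")
})
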