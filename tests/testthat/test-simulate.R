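test_that("the shearing model validates its window and degenerates cleanly", {
  expect_error(shearing_model(size_selection = c(350, 100)))
  expect_error(shearing_model(fragment_mean = 1000, fragment_sd = 0), "empty")
  expect_error(shearing_model(fragment_mean = 1000, fragment_sd = 1e-9,
                              size_selection = c(100, 350)), "empty")
  d <- sample_fragment_distances(shearing_model(fragment_sd = 0), 100, seed = 1)
  expect_true(all(d == 200 - 48))
})

test_that("fragment distances are deterministic under a seed and well summarized", {
  m <- shearing_model()
  d1 <- sample_fragment_distances(m, 5000, seed = 10)
  d2 <- sample_fragment_distances(m, 5000, seed = 10)
  expect_identical(d1, d2)
  s <- distance_summary(d1)
  expect_equal(s$n_tags, 5000L)
  expect_equal(sum(s$counts), 5000L)
  expect_gte(s$frac_within_300, 0.9)
})

test_that("transcriptome generation is deterministic and honors its knobs", {
  tr1 <- make_transcriptome(n_genes = 25, seed = 100)
  tr2 <- make_transcriptome(n_genes = 25, seed = 100)
  expect_identical(tr1$genome, tr2$genome)
  expect_identical(tr1$transcripts, tr2$transcripts)
  d1 <- tempfile(); d2 <- tempfile()
  write_transcriptome(tr1, d1); write_transcriptome(tr2, d2)
  for (f in c("genome.fa", "transcripts.fa", "annotation.gff3"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_error(make_transcriptome(n_genes = 1, paralog_fraction = 0.5),
               "at least 2")
})

test_that("paralog-free transcriptomes have unique 3' 300-mers; families share them", {
  tr <- make_transcriptome(n_genes = 30, paralog_fraction = 0, seed = 101)
  tails <- vapply(tr$transcripts[endsWith(tx_id, ".1"), tx_id], function(t) {
    s <- tr$tx_seqs[[t]]
    substr(s, nchar(s) - 299L, nchar(s))
  }, character(1))
  expect_equal(anyDuplicated(tails), 0L)

  trp <- make_transcriptome(n_genes = 30, paralog_fraction = 0.2, seed = 102)
  expect_gt(nrow(trp$paralogs), 0L)
  fam <- trp$paralogs[family == 1, gene_id]
  t3 <- vapply(paste0(fam, ".1"), function(t) {
    s <- trp$tx_seqs[[t]]
    substr(s, nchar(s) - 299L, nchar(s))
  }, character(1))
  expect_equal(unname(t3[1]), unname(t3[2]))
})

test_that("generated transcript lengths match the configured mean", {
  tr <- make_transcriptome(n_genes = 200, mean_length = 1500, sd_log = 0.35,
                           paralog_fraction = 0, apa_fraction = 0, seed = 103)
  len <- tr$transcripts$length
  se <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - 1500), 3 * se + 20)  # +20: flooring bias margin
})

test_that("a written transcriptome round-trips through the GFF3 loader", {
  tr <- make_transcriptome(n_genes = 20, seed = 104)
  dir <- tempfile()
  paths <- write_transcriptome(tr, dir)
  idx_file <- load_annotation(paths[["annotation"]])
  idx_mem <- as_annotation_index(tr)
  expect_setequal(idx_file$genes$gene_id, idx_mem$genes$gene_id)
  lf <- idx_file$longest[order(gene_id)]
  lm <- idx_mem$longest[order(gene_id)]
  expect_equal(lf$three_prime_end, lm$three_prime_end)
  expect_setequal(idx_file$rrna_genes, idx_mem$rrna_genes)
})

test_that("library simulation is deterministic and conserves truth", {
  tr <- make_transcriptome(n_genes = 20, seed = 105)
  lib1 <- simulate_library(tr, n_reads = 2000, barcode = "ACGT", seed = 106)
  lib2 <- simulate_library(tr, n_reads = 2000, barcode = "ACGT", seed = 106)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(lib1$reads, f1); write_fastq(lib2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(lib1$truth$counts[, sum(n)], 2000L)
  expect_true(all(startsWith(lib1$reads$seq, "ACGT")))
})

test_that("per-gene APA usage in truth matches the configured split", {
  tr <- make_transcriptome(n_genes = 30, apa_fraction = 0.2, seed = 107)
  expect_gt(nrow(tr$apa), 0)
  usage <- tr$apa[, .(u = sum(usage)), by = gene_id]
  expect_true(all(abs(usage$u - 1) < 1e-12))
  lib <- simulate_library(tr, n_reads = 50000, seed = 108)
  g <- tr$apa$gene_id[1]
  sites <- lib$truth$sites[gene_id == g & orientation == "sense"]
  sites <- merge(sites, tr$apa[gene_id == g], by.x = "polya", by.y = "polya")
  frac <- sites$n / sum(sites$n)
  expect_true(all(abs(frac - sites$usage) < 3 * sqrt(0.3 * 0.7 / sum(sites$n))))
})

test_that("simulated read sequences come from the transcript 3' ends", {
  tr <- make_transcriptome(n_genes = 15, paralog_fraction = 0,
                           antisense_fraction = 0, apa_fraction = 0, seed = 109)
  lib <- simulate_library(tr, n_reads = 200, seed = 110)
  tt <- lib$truth$reads
  for (i in sample.int(200, 20)) {
    s <- tr$tx_seqs[[tt$unit_id[i]]]
    L <- nchar(s)
    d <- tt$distance[i]
    expect_equal(lib$reads$seq[i],
                 substr(s, L - d + 1L, L - d + min(36L, d)), info = i)
  }
})

test_that("substitution errors appear at roughly the requested rate", {
  tr <- make_transcriptome(n_genes = 10, paralog_fraction = 0,
                           antisense_fraction = 0, apa_fraction = 0, seed = 111)
  clean <- simulate_library(tr, n_reads = 500, error_rate = 0, seed = 112)
  noisy <- simulate_library(tr, n_reads = 500, error_rate = 0.05, seed = 112)
  # same draws up to the error step: alignments identical
  expect_equal(clean$alignments, noisy$alignments)
  mism <- sum(vapply(seq_len(500), function(i) {
    a <- strsplit(clean$reads$seq[i], "")[[1]]
    b <- strsplit(noisy$reads$seq[i], "")[[1]]
    sum(a != b)
  }, numeric(1)))
  total <- sum(nchar(clean$reads$seq))
  expect_gt(mism / total, 0.03)
  expect_lt(mism / total, 0.07)
})

test_that("realized tag distances follow the shearing model (KS distance)", {
  tr <- make_transcriptome(n_genes = 30, min_length = 1000, apa_fraction = 0,
                           paralog_fraction = 0, antisense_fraction = 0,
                           seed = 113)
  lib <- simulate_library(tr, n_reads = 20000, seed = 114)
  ref <- sample_fragment_distances(shearing_model(), 20000, seed = 115)
  ks <- suppressWarnings(stats::ks.test(lib$truth$reads$distance, ref))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("SAM round-trip preserves simulated alignments", {
  tr <- make_transcriptome(n_genes = 10, seed = 116)
  lib <- simulate_library(tr, n_reads = 300, seed = 117)
  sam <- tempfile(fileext = ".sam")
  write_sam(lib$alignments, vapply(tr$genome, nchar, integer(1)), sam)
  back <- read_alignments(sam, "genome")
  orig <- lib$alignments[order(read_id, chrom, start)]
  got <- back[order(read_id, chrom, start)]
  expect_equal(got$read_id, orig$read_id)
  expect_equal(got$start, orig$start)
  expect_equal(got$end, orig$end)
  expect_equal(got$strand, orig$strand)
})
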