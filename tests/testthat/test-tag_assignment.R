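test_that("the assignment cascade handles each rule case", {
  idx <- toy_index()

  # unique sense alignment inside a gene
  r <- assign_read(aln1("chr1", 1500, 1535, "+"), idx)
  expect_equal(r$outcome, "assigned")
  expect_equal(r$targets$gene_id, "geneA")
  expect_equal(r$targets$orientation, "sense")
  expect_equal(r$targets$weight, 1)

  # paralog-style split across two genes
  r <- assign_read(rbind(aln1("chr1", 1500, 1535, "+"),
                         aln1("chr1", 5500, 5535, "+")), idx)
  expect_equal(sort(r$targets$gene_id), c("geneA", "geneB"))
  expect_equal(r$targets$weight, c(0.5, 0.5))

  # overlapping gene limits: both genes become candidates
  r <- assign_read(aln1("chr1", 12700, 12735, "+"), idx)
  expect_setequal(r$targets$gene_id, c("geneO1", "geneO2"))
  expect_equal(sum(r$targets$weight), 1)

  # antisense to geneZ but within geneY's downstream window -> sense of geneY
  r <- assign_read(aln1("chr1", 8150, 8185, "+"), idx)
  expect_equal(r$targets$gene_id, "geneY")
  expect_equal(r$targets$orientation, "sense")

  # antisense with no window rescue -> antisense tag of the overlapped gene
  r <- assign_read(aln1("chr1", 20500, 20535, "+"), idx)
  expect_equal(r$targets$gene_id, "geneX")
  expect_equal(r$targets$orientation, "antisense")

  # no overlap at all -> unassigned
  r <- assign_read(aln1("chr1", 40000, 40035, "+"), idx)
  expect_equal(r$outcome, "unassigned")
  expect_equal(nrow(r$targets), 0L)
})

test_that("reads hitting more than max_genes genes are discarded", {
  genes <- data.table(gene_id = sprintf("m%02d", 1:11), chrom = "chr1",
                      strand = "+", start = seq(1000L, 101000L, by = 10000L),
                      end = seq(1000L, 101000L, by = 10000L) + 999L)
  tx <- genes[, .(tx_id = paste0(gene_id, ".1"), gene_id, start, end,
                  length = 1000L)]
  idx <- build_annotation_index(genes, tx)
  aln <- genes[, .(read_id = "r", chrom, start = start + 10L,
                   end = start + 45L, strand = "+", source = "genome")]
  r <- assign_read(aln, idx)
  expect_equal(r$outcome, "discarded_multigene")
  r10 <- assign_read(aln[1:10], idx)
  expect_equal(r10$outcome, "assigned")
  expect_equal(r10$targets$weight, rep(0.1, 10))
})

test_that("transcript-pass alignments collapse splice variants to one candidate", {
  gff <- system.file("extdata", "toy.gff3", package = "exprss")
  idx <- load_annotation(gff)
  aln <- data.table(read_id = "r", chrom = c("geneA.1", "geneA.2"),
                    start = c(700L, 700L), end = c(735L, 735L),
                    strand = "+", source = "transcript")
  r <- assign_read(aln, idx)
  expect_equal(r$targets$gene_id, "geneA")
  expect_equal(r$targets$weight, 1)
  # minus-strand transcript alignment is an antisense tag
  ras <- assign_read(aln1("geneB.1", 100, 135, "-", source = "transcript"), idx)
  expect_equal(ras$targets$orientation, "antisense")
})

test_that("assign_library enforces the two-pass contract and merges passes", {
  idx <- toy_index()
  g <- aln1("chr1", 1500, 1535, "+", read_id = "r1")
  t <- data.table(read_id = "r1", chrom = "geneA.1", start = 1L, end = 36L,
                  strand = "+")
  expect_error(assign_library(g, t, idx), "both")
  t2 <- copy(t)[, read_id := "r2"]
  a <- assign_library(g, t2, toy_index())
  expect_equal(a$summary$n_assigned, 2L)
  # empty transcript pass is identical to genome-only assignment
  a1 <- assign_library(g, NULL, idx)
  expect_equal(a1$targets, assign_library(g, t2[0], idx)$targets)
})

test_that("a ten-read toy library matches hand computation", {
  idx <- toy_index()
  aln <- rbind(
    aln1("chr1", 1100, 1135, "+", read_id = "q01"),   # geneA sense
    aln1("chr1", 1200, 1235, "+", read_id = "q02"),   # geneA sense
    rbind(aln1("chr1", 1300, 1335, "+", read_id = "q03"),
          aln1("chr1", 5300, 5335, "+", read_id = "q03")),  # A/B split
    aln1("chr1", 12700, 12735, "+", read_id = "q04"), # O1/O2 overlap split
    aln1("chr1", 8150, 8185, "+", read_id = "q05"),   # window rescue -> geneY
    aln1("chr1", 20500, 20535, "+", read_id = "q06"), # antisense geneX
    aln1("chr1", 20500, 20535, "-", read_id = "q07"), # sense geneX
    aln1("chr1", 40000, 40035, "+", read_id = "q08"), # unassigned
    aln1("chr1", 5500, 5535, "+", read_id = "q09"),   # geneB sense
    aln1("chr1", 7100, 7135, "+", read_id = "q10")    # geneY sense
  )
  a <- assign_library(aln, NULL, idx)
  expect_equal(a$summary$n_assigned, 9L)
  expect_equal(a$summary$n_unassigned, 1L)
  expect_equal(a$summary$frac_antisense, (1 / 9), tolerance = 1e-12)
  cm <- build_count_matrix(list(s = a), idx)
  sense <- SummarizedExperiment::assay(cm, "sense")[, 1]
  anti <- SummarizedExperiment::assay(cm, "antisense")[, 1]
  expect_equal(unname(sense[c("geneA", "geneB", "geneY", "geneO1", "geneO2", "geneX")]),
               c(2.5, 1.5, 2, 0.5, 0.5, 1))
  expect_equal(unname(anti["geneX"]), 1)
  expect_equal(sum(sense) + sum(anti), 9)
})

test_that("weights conserve mass and counts match per-sample assigned totals", {
  ann <- random_annotation(40, seed = 11)
  reads <- random_reads(400, seed = 12)
  a <- assign_library(reads, NULL, ann$index)
  sums <- a$targets[, .(s = sum(weight)), by = read_id]
  expect_true(all(abs(sums$s - 1) < 1e-9))
  cm <- build_count_matrix(list(x = a), ann$index)
  total <- sum(SummarizedExperiment::assay(cm, "sense")) +
    sum(SummarizedExperiment::assay(cm, "antisense"))
  expect_equal(total, a$summary$n_assigned, tolerance = 1e-9)
})

test_that("assignment agrees with the brute-force oracle on random reads", {
  ann <- random_annotation(40, seed = 21)
  reads <- random_reads(300, seed = 22)
  a <- assign_library(reads, NULL, ann$index)
  for (id in unique(reads$read_id)) {
    got_out <- a$reads[read_id == id, outcome]
    got <- a$targets[read_id == id][order(gene_id)]
    exp <- oracle_assign_read(as.data.frame(reads[read_id == id]),
                              as.data.frame(ann$genes))
    expect_equal(got_out, exp$outcome, info = id)
    if (exp$outcome == "assigned") {
      expect_equal(got$gene_id, exp$targets$gene, info = id)
      expect_equal(got$orientation, exp$targets$orient, info = id)
      expect_equal(got$weight, exp$targets$weight, info = id)
    }
  }
})

test_that("flipping read strands swaps sense and antisense when windows are off", {
  # spaced, non-overlapping genes (no convergent pairs), downstream windows
  # disabled, so rules (1) and (3) are exact mirrors of each other
  tr <- make_transcriptome(n_genes = 40, antisense_fraction = 0,
                           paralog_fraction = 0, apa_fraction = 0, seed = 31)
  idx <- as_annotation_index(tr, window_bp = 0)
  reads <- random_reads(300, seed = 32, multi_fraction = 0)
  a1 <- assign_library(reads, NULL, idx)
  flipped <- copy(reads)[, strand := ifelse(strand == "+", "-", "+")]
  a2 <- assign_library(flipped, NULL, idx)
  t1 <- a1$targets[order(read_id, gene_id)]
  t2 <- a2$targets[order(read_id, gene_id)]
  expect_equal(t1$gene_id, t2$gene_id)
  expect_equal(t1$weight, t2$weight)
  expect_true(all(t1$orientation != t2$orientation))
})

test_that("alignments on unknown chromosomes warn and leave the read unassigned", {
  idx <- toy_index()
  expect_warning(r <- assign_read(aln1("chrNope", 100, 135, "+"), idx),
                 "unknown")
  expect_equal(r$outcome, "unassigned")
})

test_that("rRNA decoy mass is reported in the assignment summary", {
  gff <- system.file("extdata", "toy.gff3", package = "exprss")
  idx <- load_annotation(gff)
  aln <- rbind(aln1("chr2", 300, 335, "+", read_id = "a"),
               aln1("chr1", 500, 535, "+", read_id = "b"))
  a <- assign_library(aln, NULL, idx)
  expect_equal(a$summary$frac_rrna, 0.5)
})
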