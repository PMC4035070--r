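test_that("distance profile counts only unique sense genome tags and conserves mass", {
  tr <- make_transcriptome(n_genes = 30, paralog_fraction = 0, seed = 41)
  idx <- as_annotation_index(tr)
  lib <- simulate_library(tr, n_reads = 5000, seed = 42)
  a <- assign_library(lib$alignments, NULL, idx)
  p <- distance_profile(a, idx)
  expect_s3_class(p, "distance_profile")
  expect_equal(sum(p$counts), p$n_tags)
  # tags from antisense units are excluded: profile holds at most the sense reads
  expect_lte(p$n_tags, lib$truth$counts[orientation == "sense", sum(n)])
  expect_gte(p$frac_within_300, 0.9)
})

test_that("tags placed exactly at 3' ends land in the zero bin", {
  idx <- toy_index()
  ends <- idx$longest[gene_id %in% c("geneA", "geneB"), three_prime_end]
  aln <- data.table(read_id = sprintf("e%02d", 1:10),
                    chrom = "chr1",
                    start = rep(ends, 5), end = rep(ends, 5) + 35L,
                    strand = "+", source = "genome")
  # geneB is on '+' in toy_index? it is; both ends give distance 0 tags
  a <- assign_library(aln, NULL, idx)
  p <- distance_profile(a, idx)
  expect_equal(p$modal_bin, 0L)
  expect_equal(unname(p$counts[as.character(0)]), p$n_tags)
})

test_that("empty input yields an empty, flagged profile", {
  idx <- toy_index()
  a <- assign_library(aln1("chr1", 40000, 40035, "+"), NULL, idx)
  p <- distance_profile(a, idx)
  expect_equal(p$n_tags, 0L)
  expect_true(is.na(p$frac_within_300))
  expect_true(is.na(p$modal_bin))
})

test_that("APA calling separates distant sites and collapses close ones", {
  set.seed(51)
  mk_cluster <- function(center, n, sd = 15) round(rnorm(n, center, sd))
  # two clusters 400 bp apart: both called
  pos <- c(mk_cluster(2000, 50), mk_cluster(2400, 50))
  calls <- call_apa_sites(pos, strand = "+", gene_id = "g")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$kind, c("primary", "alternative"))
  expect_true(all(abs(sort(calls$position) - c(2000, 2400)) <= 25))
  # pairwise separation invariant
  expect_gt(abs(diff(calls$position)), 200)
  # two clusters 100 bp apart: collapse to one call
  pos2 <- c(mk_cluster(2000, 50), mk_cluster(2100, 50))
  expect_equal(nrow(call_apa_sites(pos2, strand = "+")), 1L)
  # single cluster: one primary call at the mode within a bin
  pos3 <- mk_cluster(5000, 50)
  c3 <- call_apa_sites(pos3, strand = "+")
  expect_equal(c3$kind, "primary")
  expect_lte(abs(c3$position - 5000), 25)
  expect_equal(c3$fraction, 1)
})

test_that("the 3'-most call is primary, strand-aware", {
  set.seed(52)
  pos <- c(round(rnorm(60, 1000, 10)), round(rnorm(40, 1500, 10)))
  plus <- call_apa_sites(pos, strand = "+")
  expect_equal(plus[kind == "primary", position], max(plus$position))
  minus <- call_apa_sites(pos, strand = "-")
  expect_equal(minus[kind == "primary", position], min(minus$position))
})

test_that("APA calls agree with the exhaustive oracle on random histograms", {
  set.seed(53)
  for (k in 1:25) {
    n_clusters <- sample(1:4, 1)
    centers <- sort(sample(seq(1000, 5000, by = 50), n_clusters))
    pos <- unlist(lapply(centers, function(cc)
      round(rnorm(sample(10:80, 1), cc, sample(c(5, 20, 40), 1)))))
    got <- sort(call_apa_sites(pos, strand = "+")$position)
    exp <- oracle_apa_positions(pos)
    expect_equal(got, exp, info = paste("case", k))
    if (length(got) > 1) expect_true(all(diff(got) > 200))
  }
})

test_that("planted sites >= 300 bp apart are each recovered within one bin", {
  set.seed(54)
  sites <- c(3000, 3400, 3900)
  pos <- unlist(lapply(sites, function(s) round(rnorm(60, s, 10))))
  calls <- call_apa_sites(pos, strand = "+")
  expect_equal(nrow(calls), 3L)
  expect_true(all(abs(sort(calls$position) - sites) <= 25))
})

test_that("antisense peaks are found when clustered and absent when diffuse", {
  set.seed(55)
  peak <- antisense_peak(round(rnorm(100, 7000, 30)), strand = "+", gene_id = "g")
  expect_equal(peak$kind, "antisense")
  expect_lte(abs(peak$position - 7000), 50)
  # 20 tags uniform over 5 kb: no bin accumulates enough mass
  diffuse <- antisense_peak(sample.int(5000, 20), strand = "+")
  expect_null(diffuse)
  expect_null(antisense_peak(integer(0)))
})

test_that("novel regions merge by gap and respect the support threshold", {
  mk <- function(starts, strand = "+")
    data.table(read_id = sprintf("n%03d", seq_along(starts)), chrom = "chr1",
               start = starts, end = starts + 35L, strand = strand)
  # 20 reads inside a 200-bp window -> one region with support 20
  r1 <- detect_novel_regions(mk(seq(10000, 10164, length.out = 20)))
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$support, 20L)
  # below min_support -> nothing
  expect_equal(nrow(detect_novel_regions(mk(seq(10000, 10100, length.out = 5)))), 0L)
  # two clusters separated by >100 bp gap -> two regions
  c1 <- seq(10000, 10100, length.out = 12)
  c2 <- seq(10400, 10500, length.out = 12)  # gap ~264 bp after read ends
  r2 <- detect_novel_regions(mk(c(c1, c2)))
  expect_equal(nrow(r2), 2L)
  # nearest-gene annotation
  idx <- toy_index()
  r3 <- detect_novel_regions(mk(seq(2300, 2400, length.out = 15)), idx)
  expect_equal(r3$nearest_gene, "geneA")
  expect_equal(r3$distance, 2300L - 2000L - 1L)
})

test_that("read-2 poly(A) sites are aggregated per gene and flagged", {
  idx <- toy_index()  # geneA '+' [1000, 2000], 3' end 2000
  mk2 <- function(ends, n_each = 1, proper = TRUE)
    data.table(read_id = sprintf("p%03d", seq_along(rep(ends, n_each))),
               chrom = "chr1", start = rep(ends, n_each) - 35L,
               end = rep(ends, n_each), strand = "-", proper = proper)
  # cluster at the annotated 3' end -> annotated
  r <- polya_sites_from_pairs(mk2(rep(2000L, 30)), idx)
  expect_equal(nrow(r), 1L)
  expect_equal(r$gene_id, "geneA")
  expect_true(r$annotated)
  expect_equal(r$kind, "read2_derived")
  expect_lte(abs(r$position - 2000), 25)
  # cluster 300 bp upstream -> novel
  r2 <- polya_sites_from_pairs(mk2(rep(1700L, 30)), idx)
  expect_false(r2$annotated)
  # improper pairs are excluded and counted
  r3 <- polya_sites_from_pairs(rbind(mk2(rep(2000L, 30)),
                                     mk2(rep(2000L, 5), proper = FALSE)), idx)
  expect_equal(attr(r3, "n_excluded"), 5L)
})

test_that("simulated paired reads verify annotated poly(A) sites", {
  tr <- make_transcriptome(n_genes = 20, apa_fraction = 0, paralog_fraction = 0,
                           antisense_fraction = 0, seed = 61)
  idx <- as_annotation_index(tr)
  lib <- simulate_library(tr, n_reads = 3000, paired = TRUE, seed = 62)
  calls <- polya_sites_from_pairs(lib$read2_alignments, idx)
  expect_gt(nrow(calls), 0L)
  expect_true(all(calls$annotated))
  truth_sites <- lib$truth$sites[orientation == "sense"]
  m <- merge(calls, truth_sites, by = "gene_id")
  expect_true(all(abs(m$position - m$polya) <= 13))
})

test_that("BED export writes one record per call", {
  set.seed(63)
  calls <- call_apa_sites(round(rnorm(50, 1000, 10)), strand = "+",
                          gene_id = "geneA")
  calls[, chrom := "chr1"]
  bed <- tempfile(fileext = ".bed")
  export_bed(calls, bed)
  lines <- readLines(bed)
  expect_equal(length(lines), nrow(calls))
  expect_match(lines[1], "^chr1\t")
})
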