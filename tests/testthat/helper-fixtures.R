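# Shared fixture builders: small annotations and read tables constructed in
# code so no binary data ships with the package.

library(data.table)

# A hand-sized annotation exercising every branch of the assignment cascade:
# paralogs, an antisense-overlap gene, a downstream-window rescue pair and an
# overlapping gene pair.
toy_index <- function(window_bp = 500) {
  genes <- data.table(
    gene_id = c("geneA", "geneB", "geneY", "geneZ", "geneX", "geneO1", "geneO2"),
    chrom = "chr1",
    strand = c("+", "+", "+", "-", "-", "+", "+"),
    start = c(1000L, 5000L, 7000L, 8100L, 20000L, 12000L, 12500L),
    end = c(2000L, 6000L, 8000L, 9100L, 21000L, 13000L, 13500L),
    biotype = c(rep("protein_coding", 6L), "protein_coding")
  )
  tx <- genes[, .(tx_id = paste0(gene_id, ".1"), gene_id, start, end,
                  length = end - start + 1L)]
  build_annotation_index(genes, tx, window_bp = window_bp)
}

# one-row alignment helper
aln1 <- function(chrom, start, end, strand, source = "genome", read_id = "r") {
  data.table(read_id = read_id, chrom = chrom, start = start, end = end,
             strand = strand, source = source)
}

# read table helper
make_reads <- function(seqs, quals = NULL, ids = NULL, offset = 33L) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  r <- data.table(id = ids, seq = seqs, qual = quals)
  setattr(r, "phred_offset", offset)
  r
}

# random annotation with overlapping and nested genes on two chromosomes,
# for property tests against the brute-force oracle
random_annotation <- function(n_genes = 50, chrom_len = 50000, seed = 1,
                              window_bp = 500) {
  set.seed(seed)
  start <- sample.int(chrom_len - 3500L, n_genes, replace = TRUE)
  len <- sample(300:3000, n_genes, replace = TRUE)
  genes <- data.table(
    gene_id = sprintf("rg%03d", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    start = start, end = start + len - 1L,
    biotype = "protein_coding"
  )
  tx <- genes[, .(tx_id = paste0(gene_id, ".1"), gene_id, start, end,
                  length = end - start + 1L)]
  list(genes = genes,
       index = build_annotation_index(genes, tx, window_bp = window_bp))
}

# random single- or multi-alignment reads over a random annotation
random_reads <- function(n_reads = 1000, chrom_len = 50000, seed = 2,
                         multi_fraction = 0.2) {
  set.seed(seed)
  one <- function(read_id) {
    s <- sample.int(chrom_len - 36L, 1L)
    data.table(read_id = read_id, chrom = sample(c("chr1", "chr2"), 1L),
               start = s, end = s + 35L,
               strand = sample(c("+", "-"), 1L), source = "genome")
  }
  rbindlist(lapply(seq_len(n_reads), function(i) {
    id <- sprintf("rr%05d", i)
    n_aln <- if (runif(1) < multi_fraction) sample(2:4, 1L) else 1L
    rbindlist(replicate(n_aln, one(id), simplify = FALSE))
  }))
}
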