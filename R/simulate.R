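#' Fragment-size model of acoustically sheared cDNA
#'
#' Double-stranded cDNA is sheared to a target size and gel size-selected;
#' the tag read then starts where the shear breakpoint fell, upstream of the
#' poly(A)-anchored primer. The model: fragment length ~ Normal(
#' `fragment_mean`, `fragment_sd`) truncated to the size-selection window,
#' and tag-start distance = fragment length minus the `primer_len` bases of
#' oligo-dT primer included in the fragment, floored at 1. With the defaults
#' (200 +/- 30 bp, window 100-350 bp, 48 bp primer) tags peak ~150 bp
#' upstream of the poly(A) site and nearly all fall within 300 bp.
#'
#' @param fragment_mean Mean sheared fragment length in bp (default 200).
#' @param fragment_sd Fragment-length standard deviation in bp (default 30).
#' @param primer_len Length of the oligo-dT/flow-cell primer contained in
#'   each fragment (default 48 bp).
#' @param size_selection Gel size-selection window `c(low, high)` in bp
#'   (default `c(100, 350)`).
#' @return Object of class `shearing_model`.
#' @export
shearing_model <- function(fragment_mean = 200, fragment_sd = 30,
                           primer_len = 48, size_selection = c(100, 350)) {
  stopifnot(length(size_selection) == 2L,
            size_selection[1] < size_selection[2],
            size_selection[1] > 0, fragment_sd >= 0, primer_len >= 0)
  if (fragment_sd == 0 &&
      (fragment_mean < size_selection[1] || fragment_mean > size_selection[2]))
    stop("fragment window empty: degenerate distribution outside size selection")
  if (fragment_sd > 0) {
    mass <- pnorm(size_selection[2], fragment_mean, fragment_sd) -
            pnorm(size_selection[1], fragment_mean, fragment_sd)
    if (mass <= 0) stop("fragment window empty after truncation")
  }
  structure(list(fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 primer_len = primer_len, size_selection = size_selection),
            class = "shearing_model")
}

#' @export
print.shearing_model <- function(x, ...) {
  cat(sprintf("shearing_model: fragments %g +/- %g bp in [%g, %g], primer %g bp\n",
              x$fragment_mean, x$fragment_sd, x$size_selection[1],
              x$size_selection[2], x$primer_len))
  invisible(x)
}

# truncated-normal fragment lengths, rounded to integer bp
.draw_fragments <- function(model, n) {
  if (model$fragment_sd == 0) return(rep(round(model$fragment_mean), n))
  lo <- pnorm(model$size_selection[1], model$fragment_mean, model$fragment_sd)
  hi <- pnorm(model$size_selection[2], model$fragment_mean, model$fragment_sd)
  round(qnorm(runif(n, lo, hi), model$fragment_mean, model$fragment_sd))
}

#' Sample tag-start distances from the shearing model
#'
#' Draws fragment lengths from the truncated Normal of the model and
#' converts them to tag-start distances (fragment minus primer, floored at
#' 1 bp). Summarize with [distance_summary()].
#'
#' @param model A [shearing_model()].
#' @param n Number of draws.
#' @param seed Optional RNG seed for reproducibility.
#' @return Integer vector of distances in bp.
#' @examples
#' d <- sample_fragment_distances(shearing_model(), 10000, seed = 1)
#' distance_summary(d)
#' @export
sample_fragment_distances <- function(model, n, seed = NULL) {
  stopifnot(is(model, "shearing_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  as.integer(pmax(1, .draw_fragments(model, n) - model$primer_len))
}

#' Summarize a distance sample
#'
#' @param distances Integer distances (bp), e.g. from
#'   [sample_fragment_distances()].
#' @param bin_width Histogram bin width (default 10 bp); bin left edges at
#'   multiples of `bin_width`.
#' @return list with `counts` (per-bin, named by left edge), `n_tags`,
#'   `frac_within_300` (share in \[0, 300\] bp) and `modal_bin` (left edge
#'   of the most populated bin).
#' @export
distance_summary <- function(distances, bin_width = 10L) {
  .bin_distances(as.integer(distances), bin_width)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a synthetic annotated transcriptome
#'
#' Builds a small genome with single-exon gene models and the structural
#' features that make tag assignment non-trivial: paralog families sharing
#' an identical 3'-terminal region (forcing multi-mapping), genes with an
#' alternative upstream poly(A) isoform, unannotated antisense transcripts
#' with defined poly(A) sites inside host genes, and rRNA decoy loci. Genes
#' are spaced by `intergenic_gap` so that downstream windows of neighbours
#' do not overlap gene bodies. Deterministic for a fixed seed.
#'
#' @param n_genes Number of genes (default 60).
#' @param mean_length Mean transcript length in bp (default 1500, lognormal
#'   with `sd_log` spread, floored at `min_length`).
#' @param sd_log Lognormal sdlog of transcript lengths (default 0.35).
#' @param min_length Minimum transcript length (default 500 bp).
#' @param paralog_fraction Fraction of genes placed in two-member paralog
#'   families with identical 3'-most `shared_3prime` bp (default 0.1).
#' @param apa_fraction Fraction of genes given a second, upstream poly(A)
#'   isoform (default 0.1); the upstream site sits `apa_offset_range` bp
#'   above the annotated 3' end and is used with frequency `apa_usage[2]`.
#' @param antisense_fraction Fraction of genes carrying a polyadenylated
#'   antisense transcript (default 0.17).
#' @param apa_usage Usage of the (3'-most, upstream) poly(A) sites, summing
#'   to 1 (default `c(0.7, 0.3)`).
#' @param apa_offset_range Range (bp) of the upstream-site offset
#'   (default 300-600).
#' @param shared_3prime Length of the identical 3' region within a paralog
#'   family (default 300 bp).
#' @param n_rrna Number of rRNA decoy genes (default 2).
#' @param intergenic_gap Distance between consecutive genes (default
#'   1000 bp).
#' @param n_chrom Number of chromosomes genes are spread over (default 2).
#' @param seed Optional RNG seed.
#' @return Object of class `synthetic_transcriptome`: gene/transcript
#'   tables, genome and per-isoform mRNA sequences, and truth tables for
#'   APA sites, antisense transcripts and paralog families.
#' @export
make_transcriptome <- function(n_genes = 60, mean_length = 1500,
                               sd_log = 0.35, min_length = 500,
                               paralog_fraction = 0.1, apa_fraction = 0.1,
                               antisense_fraction = 0.17,
                               apa_usage = c(0.7, 0.3),
                               apa_offset_range = c(300, 600),
                               shared_3prime = 300, n_rrna = 2,
                               intergenic_gap = 1000, n_chrom = 2,
                               seed = NULL) {
  stopifnot(paralog_fraction >= 0, paralog_fraction <= 1,
            apa_fraction >= 0, apa_fraction <= 1,
            antisense_fraction >= 0, antisense_fraction <= 1,
            abs(sum(apa_usage) - 1) < 1e-9, n_genes >= 1)
  if (n_genes < 2 && paralog_fraction > 0)
    stop("paralog families need at least 2 genes")
  if (!is.null(seed)) set.seed(seed)

  len <- pmax(min_length,
              round(rlnorm(n_genes, log(mean_length) - sd_log^2 / 2, sd_log)))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  chrom <- paste0("chr", rep_len(seq_len(n_chrom), n_genes))
  gene_id <- sprintf("g%03d", seq_len(n_genes))
  biotype <- rep("protein_coding", n_genes)
  if (n_rrna > 0) biotype[seq_len(min(n_rrna, n_genes))] <- "rRNA"

  start <- integer(n_genes)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- cumsum(c(intergenic_gap, head(len[i], -1L) + intergenic_gap))
  }
  end <- start + len - 1L
  genes <- data.table(gene_id, chrom, strand, start, end, biotype)

  eligible <- which(biotype != "rRNA")
  n_apa <- round(apa_fraction * n_genes)
  apa_pool <- eligible[len[eligible] >= apa_offset_range[2] + 300]
  apa_genes <- sort(sample(apa_pool, min(n_apa, length(apa_pool))))

  n_par <- 2L * floor(paralog_fraction * n_genes / 2)
  par_pool <- setdiff(eligible, apa_genes)
  par_pool <- par_pool[len[par_pool] >= shared_3prime + 100]
  par_genes <- sort(sample(par_pool, min(n_par, length(par_pool))))
  paralogs <- if (length(par_genes) >= 2) {
    data.table(family = rep(seq_len(length(par_genes) %/% 2L), each = 2L),
               gene_id = gene_id[par_genes])
  } else data.table(family = integer(), gene_id = character())

  n_anti <- round(antisense_fraction * n_genes)
  anti_pool <- eligible[len[eligible] >= 800]
  anti_genes <- sort(sample(anti_pool, min(n_anti, length(anti_pool))))

  # genome sequences; then overwrite paralog partners' 3' termini
  genome <- vapply(unique(chrom), function(ch) {
    .random_dna(max(end[chrom == ch]) + intergenic_gap)
  }, character(1))

  sense_seq <- function(i) {
    s <- substr(genome[[chrom[i]]], start[i], end[i])
    if (strand[i] == "-") .revcomp(s) else s
  }
  if (nrow(paralogs)) {
    for (f in unique(paralogs$family)) {
      pair <- match(paralogs[family == f, gene_id], gene_id)
      donor <- sense_seq(pair[1])
      shared <- substr(donor, nchar(donor) - shared_3prime + 1L, nchar(donor))
      j <- pair[2]
      piece <- if (strand[j] == "-") .revcomp(shared) else shared
      g <- genome[[chrom[j]]]
      at <- if (strand[j] == "+") end[j] - shared_3prime + 1L else start[j]
      substr(g, at, at + shared_3prime - 1L) <- piece
      genome[[chrom[j]]] <- g
    }
  }

  tx <- vector("list", n_genes)
  apa_rows <- vector("list", length(apa_genes))
  for (i in seq_len(n_genes)) {
    tx[[i]] <- data.table(tx_id = paste0(gene_id[i], ".1"), gene_id = gene_id[i],
                          start = start[i], end = end[i], length = len[i])
  }
  for (k in seq_along(apa_genes)) {
    i <- apa_genes[k]
    off <- sample(seq(apa_offset_range[1], apa_offset_range[2]), 1L)
    s2 <- if (strand[i] == "+") start[i] else start[i] + off
    e2 <- if (strand[i] == "+") end[i] - off else end[i]
    tx[[i]] <- rbind(tx[[i]],
                     data.table(tx_id = paste0(gene_id[i], ".2"),
                                gene_id = gene_id[i],
                                start = s2, end = e2, length = len[i] - off))
    apa_rows[[k]] <- data.table(
      gene_id = gene_id[i],
      tx_id = paste0(gene_id[i], c(".1", ".2")),
      polya = if (strand[i] == "+") c(end[i], e2) else c(start[i], s2),
      usage = apa_usage)
  }
  transcripts <- rbindlist(tx)
  transcripts[, three_prime_end :=
                ifelse(genes$strand[match(gene_id, genes$gene_id)] == "+",
                       end, start)]
  apa <- if (length(apa_genes)) rbindlist(apa_rows) else
    data.table(gene_id = character(), tx_id = character(),
               polya = integer(), usage = numeric())

  antisense <- if (length(anti_genes)) {
    rbindlist(lapply(anti_genes, function(i) {
      a_len <- min(500L, len[i] - 200L)
      if (strand[i] == "+") {
        # antisense transcript on '-': genomic [polya, polya + a_len - 1]
        p <- start[i] + 100L
        data.table(gene_id = gene_id[i], chrom = chrom[i], strand = "-",
                   start = p, end = p + a_len - 1L, polya = p, length = a_len)
      } else {
        p <- end[i] - 100L
        data.table(gene_id = gene_id[i], chrom = chrom[i], strand = "+",
                   start = p - a_len + 1L, end = p, polya = p, length = a_len)
      }
    }))
  } else data.table(gene_id = character(), chrom = character(),
                    strand = character(), start = integer(), end = integer(),
                    polya = integer(), length = integer())

  # mRNA-oriented sequences per isoform (ending at its poly(A) site)
  gs <- genes$strand
  tx_seqs <- vapply(seq_len(nrow(transcripts)), function(r) {
    i <- match(transcripts$gene_id[r], gene_id)
    s <- substr(genome[[chrom[i]]], transcripts$start[r], transcripts$end[r])
    if (gs[i] == "-") .revcomp(s) else s
  }, character(1))
  names(tx_seqs) <- transcripts$tx_id

  anti_seqs <- if (nrow(antisense)) {
    v <- vapply(seq_len(nrow(antisense)), function(r) {
      s <- substr(genome[[antisense$chrom[r]]], antisense$start[r], antisense$end[r])
      if (antisense$strand[r] == "-") .revcomp(s) else s
    }, character(1))
    setNames(v, paste0(antisense$gene_id, ".as"))
  } else character()

  structure(list(genes = genes[], transcripts = transcripts[],
                 genome = genome, tx_seqs = tx_seqs,
                 apa = apa[], antisense = antisense[], anti_seqs = anti_seqs,
                 paralogs = paralogs[],
                 params = list(shared_3prime = shared_3prime,
                               apa_usage = apa_usage, seed = seed)),
            class = "synthetic_transcriptome")
}

#' @export
print.synthetic_transcriptome <- function(x, ...) {
  cat("synthetic_transcriptome:", nrow(x$genes), "genes on",
      length(x$genome), "chromosome(s);",
      nrow(x$apa) / 2, "APA gene(s),",
      nrow(x$antisense), "antisense transcript(s),",
      nrow(x$paralogs), "gene(s) in paralog families,",
      sum(x$genes$biotype == "rRNA"), "rRNA decoy(s)\n")
  invisible(x)
}

#' Annotation index of a synthetic transcriptome
#'
#' @param x A `synthetic_transcriptome`.
#' @param window_bp Downstream window width (default 500).
#' @return An `annotation_index` (see [build_annotation_index()]).
#' @export
as_annotation_index <- function(x, window_bp = 500) {
  stopifnot(is(x, "synthetic_transcriptome"))
  build_annotation_index(x$genes, x$transcripts[, .(tx_id, gene_id, start, end, length)],
                         window_bp = window_bp)
}

#' Write a synthetic transcriptome to FASTA + GFF3
#'
#' @param x A `synthetic_transcriptome`.
#' @param dir Output directory; writes `genome.fa`, `transcripts.fa`,
#'   `annotation.gff3`.
#' @return Invisible named character vector of the three paths.
#' @export
write_transcriptome <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gpath <- file.path(dir, "genome.fa")
  g <- Biostrings::DNAStringSet(x$genome)
  Biostrings::writeXStringSet(g, gpath)
  tpath <- file.path(dir, "transcripts.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$tx_seqs), tpath)

  apath <- file.path(dir, "annotation.gff3")
  genes <- x$genes
  tx <- merge(x$transcripts, genes[, .(gene_id, chrom, strand)], by = "gene_id")
  rows <- rbind(
    data.table(chrom = genes$chrom, start = genes$start, end = genes$end,
               strand = genes$strand, type = "gene", ID = genes$gene_id,
               Parent = NA_character_, biotype = genes$biotype),
    data.table(chrom = tx$chrom, start = tx$start, end = tx$end,
               strand = tx$strand, type = "mRNA", ID = tx$tx_id,
               Parent = tx$gene_id, biotype = NA_character_),
    data.table(chrom = tx$chrom, start = tx$start, end = tx$end,
               strand = tx$strand, type = "exon",
               ID = paste0(tx$tx_id, ".exon1"), Parent = tx$tx_id,
               biotype = NA_character_)
  )
  setorder(rows, chrom, start, type)
  gr <- GenomicRanges::GRanges(rows$chrom, IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  gr$type <- rows$type
  gr$ID <- rows$ID
  gr$Parent <- as(lapply(rows$Parent,
                         function(p) if (is.na(p)) character() else p),
                  "CharacterList")
  gr$biotype <- rows$biotype
  rtracklayer::export(gr, apath, format = "gff3")
  invisible(c(genome = gpath, transcripts = tpath, annotation = apath))
}

#' Simulate a sheared-cDNA tag library with ground truth
#'
#' Draws reads from a synthetic transcriptome under the shearing model: a
#' transcription unit (sense isoform, weighted by expression and poly(A)
#' usage, or antisense transcript) is sampled per read, a fragment length is
#' drawn, and read 1 starts `fragment - primer_len` bases upstream of the
#' unit's poly(A) site, reading towards it. The true genomic alignment of
#' every read is emitted alongside, including the extra alignments a
#' multi-mapping read would receive within a paralog family, so the
#' assignment stage can be exercised without running an external aligner.
#'
#' @param x A `synthetic_transcriptome` from [make_transcriptome()].
#' @param expression Named per-gene expression levels (any non-negative
#'   scale); default lognormal draws.
#' @param antisense_expression Named levels for antisense units; default
#'   0.3x the host gene's sense level.
#' @param shearing A [shearing_model()].
#' @param n_reads Number of read (pairs) to simulate.
#' @param barcode Optional barcode prepended to read 1.
#' @param read_length Read length in nt (default 36).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param paired Also simulate the poly(A)-junction-anchored read 2.
#' @param read_prefix Prefix for read ids (default `"read"`), useful to keep
#'   ids unique when pooling simulated samples.
#' @param seed Optional RNG seed; fixed seed gives byte-identical output.
#' @return Object of class `tag_library`: `reads` (and `read2` when paired)
#'   as data.tables of id/seq/qual, `alignments` (and `read2_alignments`)
#'   as genomic alignment tables for [assign_library()], and `truth` with
#'   per-(gene, orientation) counts, per-read provenance, and per-site
#'   poly(A) draws.
#' @export
simulate_library <- function(x, expression = NULL, antisense_expression = NULL,
                             shearing = shearing_model(), n_reads = 1e5,
                             barcode = NULL, read_length = 36,
                             error_rate = 0, paired = FALSE,
                             read_prefix = "read", seed = NULL) {
  stopifnot(is(x, "synthetic_transcriptome"), n_reads >= 1)
  if (!is.null(seed)) set.seed(seed)
  genes <- x$genes
  if (is.null(expression)) {
    expression <- setNames(rlnorm(nrow(genes), log(50), 1), genes$gene_id)
  }
  stopifnot(all(genes$gene_id %in% names(expression)),
            all(expression >= 0), any(expression > 0))

  # transcription units: sense isoforms (weight = expression x usage) and
  # antisense transcripts
  tx <- merge(x$transcripts, genes[, .(gene_id, chrom, strand)], by = "gene_id")
  tx[, usage := 1]
  if (nrow(x$apa)) {
    m <- match(tx$tx_id, x$apa$tx_id)
    tx[!is.na(m), usage := x$apa$usage[m[!is.na(m)]]]
  }
  units <- data.table(
    unit_id = tx$tx_id, gene_id = tx$gene_id, orientation = "sense",
    chrom = tx$chrom, mrna_strand = tx$strand, polya = tx$three_prime_end,
    max_d = tx$length,
    weight = expression[tx$gene_id] * tx$usage,
    seq = unname(x$tx_seqs[tx$tx_id])
  )
  if (nrow(x$antisense)) {
    av <- x$antisense
    aw <- if (is.null(antisense_expression))
      0.3 * expression[av$gene_id]
    else antisense_expression[av$gene_id]
    units <- rbind(units, data.table(
      unit_id = paste0(av$gene_id, ".as"), gene_id = av$gene_id,
      orientation = "antisense", chrom = av$chrom, mrna_strand = av$strand,
      polya = av$polya, max_d = av$length,
      weight = aw, seq = unname(x$anti_seqs[paste0(av$gene_id, ".as")])
    ))
  }
  units <- units[weight > 0]

  u <- sample.int(nrow(units), n_reads, replace = TRUE,
                  prob = units$weight / sum(units$weight))
  d <- pmax(1L, .draw_fragments(shearing, n_reads) - shearing$primer_len)
  d <- pmin(d, units$max_d[u])
  len <- pmin(read_length, d)
  L <- units$max_d[u]
  seq1 <- substring(units$seq[u], L - d + 1L, L - d + len)

  if (error_rate > 0) {
    n_err <- stats::rbinom(n_reads, len, error_rate)
    for (i in which(n_err > 0)) {
      ch <- strsplit(seq1[i], "")[[1]]
      at <- sample.int(len[i], n_err[i])
      ch[at] <- vapply(ch[at],
                       function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                       character(1))
      seq1[i] <- paste(ch, collapse = "")
    }
  }

  ids <- sprintf("%s%07d", read_prefix, seq_len(n_reads))
  plus <- units$mrna_strand[u] == "+"
  aln_start <- ifelse(plus, units$polya[u] - d + 1L, units$polya[u] + d - len)
  aln_end <- ifelse(plus, units$polya[u] - d + len, units$polya[u] + d - 1L)
  alignments <- data.table(read_id = ids, chrom = units$chrom[u],
                           start = as.integer(aln_start),
                           end = as.integer(aln_end),
                           strand = ifelse(plus, "+", "-"))

  # extra alignments within paralog families: reads falling entirely inside
  # the shared 3'-terminal region of a full-length sense isoform also align
  # to the corresponding position of every other family member
  if (nrow(x$paralogs)) {
    shared <- x$params$shared_3prime
    fam <- merge(x$paralogs,
                 data.table(gene_id = genes$gene_id,
                            g_strand = genes$strand, g_chrom = genes$chrom,
                            g3 = ifelse(genes$strand == "+", genes$end, genes$start)),
                 by = "gene_id")
    primary_full <- units$orientation[u] == "sense" &
      endsWith(units$unit_id[u], ".1") & d <= shared &
      units$gene_id[u] %in% fam$gene_id
    idx <- which(primary_full)
    if (length(idx)) {
      src <- data.table(read_id = ids[idx], gene_id = units$gene_id[u[idx]],
                        d = d[idx], len = len[idx])
      src <- merge(src, x$paralogs, by = "gene_id")
      mates <- merge(src, fam, by = "family", allow.cartesian = TRUE,
                     suffixes = c("", ".mate"))
      mates <- mates[gene_id.mate != gene_id]
      if (nrow(mates)) {
        mp <- mates$g_strand == "+"
        alignments <- rbind(alignments, data.table(
          read_id = mates$read_id, chrom = mates$g_chrom,
          start = as.integer(ifelse(mp, mates$g3 - mates$d + 1L,
                                    mates$g3 + mates$d - mates$len)),
          end = as.integer(ifelse(mp, mates$g3 - mates$d + mates$len,
                                  mates$g3 + mates$d - 1L)),
          strand = ifelse(mp, "+", "-")))
      }
    }
  }
  setorder(alignments, read_id)

  reads <- data.table(
    id = ids,
    seq = if (is.null(barcode)) seq1 else paste0(barcode, seq1),
    qual = strrep("I", len + if (is.null(barcode)) 0L else nchar(barcode))
  )
  setattr(reads, "phred_offset", 33L)

  read2 <- read2_aln <- NULL
  if (paired) {
    len2 <- pmin(read_length, L)
    read2 <- data.table(
      id = ids,
      seq = .revcomp(substring(units$seq[u], L - len2 + 1L, L)),
      qual = strrep("I", len2)
    )
    setattr(read2, "phred_offset", 33L)
    read2_aln <- data.table(
      read_id = ids, chrom = units$chrom[u],
      start = as.integer(ifelse(plus, units$polya[u] - len2 + 1L, units$polya[u])),
      end = as.integer(ifelse(plus, units$polya[u], units$polya[u] + len2 - 1L)),
      strand = ifelse(plus, "-", "+")
    )
  }

  truth_reads <- data.table(read_id = ids, gene_id = units$gene_id[u],
                            orientation = units$orientation[u],
                            unit_id = units$unit_id[u],
                            polya = units$polya[u], distance = d)
  truth_counts <- truth_reads[, .(n = .N), by = .(gene_id, orientation)]
  truth_sites <- truth_reads[, .(n = .N), by = .(gene_id, orientation, polya)]

  structure(list(reads = reads, read2 = read2,
                 alignments = alignments[], read2_alignments = read2_aln,
                 truth = list(counts = truth_counts[], reads = truth_reads[],
                              sites = truth_sites[]),
                 barcode = barcode,
                 params = list(shearing = shearing, n_reads = n_reads,
                               read_length = read_length,
                               error_rate = error_rate, seed = seed)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat("tag_library:", nrow(x$reads), "reads",
      if (!is.null(x$read2)) "(paired)" else "",
      "from", length(unique(x$truth$reads$gene_id)), "genes;",
      "barcode:", if (is.null(x$barcode)) "none" else x$barcode, "\n")
  invisible(x)
}

#' Write an alignment table as SAM
#'
#' Emits a minimal, valid SAM file (FLAG 0/16, MAPQ 255, full-match CIGAR,
#' no stored sequence) so that simulated alignments can exercise the same
#' SAM/BAM reading path as aligner output.
#'
#' @param alignments data.table(read_id, chrom, start, end, strand).
#' @param seq_lengths Named vector of reference sequence lengths.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, seq_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                   as.integer(seq_lengths)))
  a <- as.data.table(alignments)
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                  a$read_id, ifelse(a$strand == "-", 16L, 0L), a$chrom,
                  a$start, a$end - a$start + 1L)
  writeLines(c(hdr, body), path)
  invisible(path)
}
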