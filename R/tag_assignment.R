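#' Read alignments from SAM/BAM or a data frame
#'
#' Accepts a SAM or BAM file (SAM is converted on the fly) or an in-memory
#' data frame with columns `read_id`, `chrom`, `start`, `end`, `strand`
#' (1-based inclusive reference coordinates). For transcript-pass
#' alignments, `chrom` holds the transcript id.
#'
#' @param x File path or data frame.
#' @param source `"genome"` or `"transcript"`: which alignment pass this is.
#' @return data.table(read_id, chrom, start, end, strand, source).
#' @export
read_alignments <- function(x, source = c("genome", "transcript")) {
  source <- match.arg(source)
  if (is.character(x) && length(x) == 1L) {
    path <- x
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                               indexDestination = FALSE)
    }
    ga <- GenomicAlignments::readGAlignments(
      path, param = Rsamtools::ScanBamParam(what = "qname"))
    aln <- data.table(
      read_id = S4Vectors::mcols(ga)$qname,
      chrom = as.character(GenomeInfoDb::seqnames(ga)),
      start = GenomicAlignments::start(ga),
      end = GenomicAlignments::end(ga),
      strand = as.character(GenomicAlignments::strand(ga))
    )
  } else {
    aln <- as.data.table(x)[, .(read_id = as.character(read_id),
                                chrom = as.character(chrom),
                                start = as.integer(start),
                                end = as.integer(end),
                                strand = as.character(strand))]
  }
  stopifnot(all(aln$strand %in% c("+", "-")), all(aln$start <= aln$end))
  aln[, source := source]
  aln[]
}

# Candidate (gene, orientation) pairs per alignment row, applying the rule
# cascade at the alignment level:
#   sense overlap wins; otherwise antisense overlaps are tested against the
#   downstream windows on the read's strand (window hit => sense candidate
#   for the window's gene), and only failing that do they stay antisense.
.candidates <- function(aln, index) {
  cand <- list()
  gen <- aln[source == "genome"]
  if (nrow(gen)) {
    known <- gen$chrom %in% unique(index$genes$chrom)
    if (!all(known)) {
      warning(sum(!known), " alignment(s) on unknown chromosome(s): ",
              paste(head(unique(gen$chrom[!known])), collapse = ", "))
      gen <- gen[known]
    }
  }
  if (nrow(gen)) {
    gr <- GenomicRanges::GRanges(gen$chrom,
                                 IRanges::IRanges(gen$start, gen$end),
                                 strand = gen$strand)
    sense_fo <- GenomicRanges::findOverlaps(gr, index$gene_gr)
    sense <- data.table(
      aln_idx = gen$aln_idx[S4Vectors::queryHits(sense_fo)],
      gene_id = names(index$gene_gr)[S4Vectors::subjectHits(sense_fo)],
      orientation = "sense")
    anti_fo <- GenomicRanges::findOverlaps(BiocGenerics::invertStrand(gr),
                                           index$gene_gr)
    anti <- data.table(
      aln_idx = gen$aln_idx[S4Vectors::queryHits(anti_fo)],
      gene_id = names(index$gene_gr)[S4Vectors::subjectHits(anti_fo)],
      orientation = "antisense")

    # 5'-most aligned base, tested against downstream windows on the
    # read's own strand
    p <- ifelse(gen$strand == "+", gen$start, gen$end)
    pgr <- GenomicRanges::GRanges(gen$chrom, IRanges::IRanges(p, p),
                                  strand = gen$strand)
    win_fo <- GenomicRanges::findOverlaps(pgr, index$window_gr)
    win <- data.table(
      aln_idx = gen$aln_idx[S4Vectors::queryHits(win_fo)],
      gene_id = names(index$window_gr)[S4Vectors::subjectHits(win_fo)],
      orientation = "sense")

    no_sense <- setdiff(gen$aln_idx, sense$aln_idx)
    anti <- anti[aln_idx %in% no_sense]
    rescued_idx <- intersect(unique(anti$aln_idx), unique(win$aln_idx))
    cand <- list(sense,
                 win[aln_idx %in% rescued_idx],
                 anti[!aln_idx %in% rescued_idx])
  }
  tx <- aln[source == "transcript"]
  if (nrow(tx)) {
    g <- index$tx2gene[tx$chrom]
    if (anyNA(g)) {
      warning(sum(is.na(g)), " alignment(s) to unknown transcript(s): ",
              paste(head(unique(tx$chrom[is.na(g)])), collapse = ", "))
    }
    cand <- c(cand, list(data.table(
      aln_idx = tx$aln_idx[!is.na(g)],
      gene_id = unname(g[!is.na(g)]),
      orientation = ifelse(tx$strand[!is.na(g)] == "+", "sense", "antisense"))))
  }
  rbindlist(cand)
}

.assign_all <- function(aln, index, max_genes = 10L) {
  aln <- copy(aln)[, aln_idx := .I]
  cand <- .candidates(aln, index)
  if (!nrow(cand))
    cand <- data.table(aln_idx = integer(), gene_id = character(),
                       orientation = character())
  cand <- merge(cand, aln[, .(aln_idx, read_id)], by = "aln_idx")

  # collapse to one candidate per (read, gene); sense wins over antisense
  # when both arise from different alignments of the same read
  cand[, pri := orientation == "sense"]
  setorder(cand, read_id, gene_id, -pri)
  cand <- unique(cand, by = c("read_id", "gene_id"))
  cand[, pri := NULL]

  n_by_read <- cand[, .(n_genes = .N), by = read_id]

  # representative alignment = first record of the read
  reads <- aln[, .(n_alignments = .N,
                   chrom = chrom[1L],
                   tag_start = ifelse(strand[1L] == "+", start[1L], end[1L]),
                   strand = strand[1L],
                   source = source[1L]), by = read_id]
  reads <- merge(reads, n_by_read, by = "read_id", all.x = TRUE)
  reads[is.na(n_genes), n_genes := 0L]
  reads[, outcome := fifelse(n_genes == 0L, "unassigned",
                      fifelse(n_genes > max_genes, "discarded_multigene",
                              "assigned"))]

  targets <- merge(cand, reads[outcome == "assigned", .(read_id, n_genes)],
                   by = "read_id")
  targets[, weight := 1 / n_genes]
  targets <- targets[, .(read_id, gene_id, orientation, weight)]

  structure(list(reads = reads[], targets = targets[],
                 summary = .assignment_summary(reads, targets, index)),
            class = "tag_assignments")
}

.assignment_summary <- function(reads, targets, index) {
  n <- nrow(reads)
  assigned_w <- sum(targets$weight)
  sense_w <- sum(targets$weight[targets$orientation == "sense"])
  rrna_w <- sum(targets$weight[targets$gene_id %in% index$rrna_genes])
  list(
    n_reads = n,
    n_assigned = sum(reads$outcome == "assigned"),
    n_discarded = sum(reads$outcome == "discarded_multigene"),
    n_unassigned = sum(reads$outcome == "unassigned"),
    frac_assigned = if (n) sum(reads$outcome == "assigned") / n else NA_real_,
    frac_discarded = if (n) sum(reads$outcome == "discarded_multigene") / n else NA_real_,
    frac_unassigned = if (n) sum(reads$outcome == "unassigned") / n else NA_real_,
    frac_sense = if (assigned_w > 0) sense_w / assigned_w else NA_real_,
    frac_antisense = if (assigned_w > 0) 1 - sense_w / assigned_w else NA_real_,
    frac_rrna = if (assigned_w > 0) rrna_w / assigned_w else NA_real_
  )
}

#' @export
print.tag_assignments <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "tag_assignments: %d reads (%.1f%% assigned, %.1f%% discarded >max genes, %.1f%% unassigned)\n",
    s$n_reads, 100 * s$frac_assigned, 100 * s$frac_discarded,
    100 * s$frac_unassigned))
  if (!is.na(s$frac_sense))
    cat(sprintf("  assigned weight: %.1f%% sense / %.1f%% antisense; %.2f%% on rRNA loci\n",
                100 * s$frac_sense, 100 * s$frac_antisense, 100 * s$frac_rrna))
  invisible(x)
}

#' Assign one tag read to genes via the rule cascade
#'
#' Applies the tag-to-gene association rules to a single read's reportable
#' alignments:
#'
#' 1. an alignment in sense orientation within a gene's limits makes that
#'    gene a sense candidate; all splice variants of a gene collapse to one
#'    candidate;
#' 2. overlapping genes containing the alignment all become candidates;
#' 3. an alignment antisense to a gene is rescued to a *sense* candidate of
#'    a neighbouring gene when the read's 5'-most base lies within that
#'    gene's downstream window (default 500 bp past its 3' end, same strand
#'    as the read); otherwise the overlapped gene becomes an antisense
#'    candidate;
#' 4. reads whose candidate set exceeds `max_genes` genes are discarded;
#' 5. otherwise the read is split equally across its candidates
#'    (weight `1/n`);
#' 6. reads with no candidate gene are left unassigned (and feed
#'    novel-region detection).
#'
#' @param alignments Alignments of one read: data frame with columns
#'   `chrom`, `start`, `end`, `strand`, optionally `source`
#'   (`"genome"`/`"transcript"`, default genome) and `read_id`.
#' @param index An `annotation_index`.
#' @param max_genes Candidate-gene cap above which the read is discarded
#'   (default 10).
#' @return list with `read_id`, `outcome` (one of `"assigned"`,
#'   `"discarded_multigene"`, `"unassigned"`) and `targets`
#'   (data.table of `gene_id`, `orientation`, `weight`; weights sum to 1).
#' @export
assign_read <- function(alignments, index, max_genes = 10L) {
  aln <- as.data.table(alignments)
  if (!"source" %in% names(aln)) aln[, source := "genome"]
  if (!"read_id" %in% names(aln)) aln[, read_id := "read"]
  stopifnot(length(unique(aln$read_id)) == 1L)
  res <- .assign_all(aln, index, max_genes = max_genes)
  list(read_id = res$reads$read_id[1L],
       outcome = res$reads$outcome[1L],
       targets = res$targets[, .(gene_id, orientation, weight)])
}

#' Assign a whole library from two-pass alignments
#'
#' Consumes the genome-pass alignments and, optionally, the transcript-pass
#' alignments of the reads that failed to align to the genome, and runs the
#' rule cascade of [assign_read()] over every read. A read present in both
#' passes violates the two-pass contract and raises an error.
#'
#' @param genome Genome-pass alignments: SAM/BAM path or data frame
#'   (see [read_alignments()]).
#' @param transcript Transcript-pass alignments (chrom = transcript id), or
#'   `NULL`.
#' @param index An `annotation_index`.
#' @param max_genes See [assign_read()].
#' @return A `tag_assignments` object: list with `reads` (per-read outcome,
#'   alignment count and representative 5' position), `targets` (per-read
#'   weighted gene targets) and `summary` (assignment fractions, sense vs
#'   antisense split, rRNA fraction).
#' @export
assign_library <- function(genome, transcript = NULL, index, max_genes = 10L) {
  galn <- read_alignments(genome, "genome")
  if (!is.null(transcript)) {
    taln <- read_alignments(transcript, "transcript")
    both <- intersect(unique(galn$read_id), unique(taln$read_id))
    if (length(both))
      stop("read(s) present in both genome and transcript passes: ",
           paste(head(both), collapse = ", "))
    galn <- rbind(galn, taln)
  }
  .assign_all(galn, index, max_genes = max_genes)
}

#' Build a sense/antisense count matrix from per-sample assignments
#'
#' Aggregates fractional read weights into a genes x samples matrix with
#' separate sense and antisense layers, returned as a
#' [SummarizedExperiment::SummarizedExperiment] with assays `"sense"` and
#' `"antisense"`. Per sample, the total mass across both layers equals the
#' number of assigned reads (each assigned read contributes total weight 1).
#'
#' @param assignments Named list of `tag_assignments`, one per sample (a
#'   single object is treated as one sample named `"sample1"`).
#' @param index An `annotation_index`; its gene set defines the rows.
#' @return SummarizedExperiment with assays `sense` and `antisense`,
#'   `rowData` carrying `biotype`, and `colData` carrying per-sample
#'   assigned/discarded/unassigned read counts and the fraction of assigned
#'   weight on rRNA loci.
#' @export
build_count_matrix <- function(assignments, index) {
  if (is(assignments, "tag_assignments"))
    assignments <- list(sample1 = assignments)
  stopifnot(length(assignments) > 0, !is.null(names(assignments)))
  genes <- index$genes$gene_id
  samples <- names(assignments)
  sense <- matrix(0, nrow = length(genes), ncol = length(samples),
                  dimnames = list(genes, samples))
  anti <- sense
  cd <- data.table(sample_id = samples, assigned_reads = 0L,
                   discarded_reads = 0L, unassigned_reads = 0L,
                   rrna_fraction = NA_real_)
  for (j in seq_along(samples)) {
    a <- assignments[[j]]
    stopifnot(is(a, "tag_assignments"))
    tg <- a$targets
    bad <- setdiff(unique(tg$gene_id), genes)
    if (length(bad))
      stop("assignment targets gene(s) absent from the index: ",
           paste(head(bad), collapse = ", "))
    for (layer in c("sense", "antisense")) {
      sub <- tg[orientation == layer,
                .(w = sum(weight)), by = gene_id]
      m <- match(sub$gene_id, genes)
      if (layer == "sense") sense[m, j] <- sense[m, j] + sub$w
      else anti[m, j] <- anti[m, j] + sub$w
    }
    cd$assigned_reads[j] <- a$summary$n_assigned
    cd$discarded_reads[j] <- a$summary$n_discarded
    cd$unassigned_reads[j] <- a$summary$n_unassigned
    cd$rrna_fraction[j] <- a$summary$frac_rrna
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(sense = sense, antisense = anti),
    rowData = S4Vectors::DataFrame(gene_id = genes,
                                   biotype = index$genes$biotype,
                                   row.names = genes),
    colData = S4Vectors::DataFrame(cd, row.names = samples)
  )
}

#' Write a count matrix as TSV
#'
#' Long-to-wide export with one row per (gene, orientation) pair:
#' `gene_id<TAB>orientation<TAB>sample...`.
#'
#' @param se SummarizedExperiment from [build_count_matrix()] or
#'   [compute_tpm()].
#' @param path Output TSV path.
#' @param round Round values to integers (for count-only downstream tools).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(se, path, round = FALSE) {
  out <- rbindlist(lapply(c("sense", "antisense"), function(layer) {
    m <- SummarizedExperiment::assay(se, layer)
    if (round) m <- base::round(m)
    data.table(gene_id = rownames(m), orientation = layer, as.data.table(m))
  }))
  fwrite(out, path, sep = "\t")
  invisible(path)
}
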