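#' Distance-from-3'-end profile of uniquely aligned sense tags
#'
#' Histograms the signed distance between each tag's start and the 3' end of
#' the longest splice variant of its gene. Only reads that aligned uniquely
#' to the genome, in sense orientation, with a single target gene are
#' included, so the profile reflects the shearing geometry rather than
#' multi-mapping artifacts. Positive distances lie upstream (inside the
#' transcript); negative distances lie downstream of the annotated 3' end.
#'
#' @param assignments A `tag_assignments` object from [assign_library()].
#' @param index An `annotation_index`.
#' @param bin_width Histogram bin width in bp (default 10); bin left edges
#'   sit at multiples of `bin_width`.
#' @return Object of class `distance_profile`: list with `counts` (named by
#'   bin left edge), `bin_width`, `n_tags`, `frac_within_300` (share of tags
#'   with distance in \[0, 300\]) and `modal_bin` (left edge of the most
#'   populated bin). Empty input gives `n_tags = 0` and `NA` summaries.
#' @export
distance_profile <- function(assignments, index, bin_width = 10L) {
  stopifnot(is(assignments, "tag_assignments"), bin_width >= 1)
  tg <- assignments$targets[orientation == "sense"]
  tg <- tg[, if (.N == 1L) .SD, by = read_id]  # single-target reads only
  rd <- assignments$reads[outcome == "assigned" & n_alignments == 1L &
                            source == "genome",
                          .(read_id, chrom, tag_start)]
  tags <- merge(tg, rd, by = "read_id")
  if (!nrow(tags)) {
    return(structure(list(counts = integer(), bin_width = bin_width,
                          n_tags = 0L, frac_within_300 = NA_real_,
                          modal_bin = NA_integer_),
                     class = "distance_profile"))
  }
  d <- tag_distance_from_3prime(index, tags$gene_id, tags$tag_start)
  structure(c(.bin_distances(d, bin_width),
              list(bin_width = as.integer(bin_width))),
            class = "distance_profile")
}

.bin_distances <- function(d, bin_width) {
  left <- as.integer(floor(d / bin_width) * bin_width)
  counts <- table(left)
  list(counts = setNames(as.integer(counts), names(counts)),
       n_tags = length(d),
       frac_within_300 = mean(d >= 0 & d <= 300),
       modal_bin = as.integer(names(counts)[which.max(counts)]))
}

#' @export
print.distance_profile <- function(x, ...) {
  cat("distance_profile:", x$n_tags, "tags,", x$bin_width, "bp bins\n")
  if (x$n_tags > 0)
    cat(sprintf("  %.1f%% within [0, 300] bp of the 3' end; modal bin [%d, %d)\n",
                100 * x$frac_within_300, x$modal_bin, x$modal_bin + x$bin_width))
  invisible(x)
}

#' @export
plot.distance_profile <- function(x, ...) {
  left <- as.integer(names(x$counts))
  graphics::plot(left, x$counts, type = "h",
                 xlab = "distance from 3' end (bp)", ylab = "tags", ...)
  invisible(x)
}

#' Call poly(A) sites from tag positions of one gene
#'
#' Smoothed-histogram peak caller: tag positions are binned (`bin` bp), the
#' histogram is smoothed by a moving average over `smooth_bins` bins, local
#' maxima are collected and filtered by support and by their share of the
#' gene's tags, and surviving candidates are accepted greedily by descending
#' height, rejecting any candidate within `min_separation` of an accepted
#' call. Sites closer than `min_separation` therefore collapse into a single
#' call, matching the resolution limit of sheared-tag data. After selection,
#' every tag is attributed to its nearest accepted call, which yields each
#' call's final `support` and `fraction` (its share of the gene's tags).
#'
#' Candidate support is measured over the `smooth_bins`-bin window centred
#' on the candidate bin, so a peak split across two adjacent bins is not
#' penalised.
#'
#' @param positions Genomic tag-start positions of one gene, one
#'   orientation.
#' @param strand Gene strand; determines which call is 3'-most.
#' @param min_separation Minimum distance (bp) between calls; candidates at
#'   or below this distance from an accepted call are rejected
#'   (default 200).
#' @param min_support Minimum tags in the candidate window (default 5).
#' @param min_fraction Minimum share of the gene's tags in the candidate
#'   window (default 0.10).
#' @param smooth_bins Moving-average window in bins (default 3).
#' @param bin Histogram bin width in bp (default 25).
#' @param gene_id Optional gene id carried into the output.
#' @return data.table of class `polya_calls` with columns `gene_id`,
#'   `position` (bin midpoint), `support`, `fraction`, `kind` (`"primary"`
#'   for the 3'-most call, `"alternative"` otherwise), ordered 3'-most
#'   first. Zero rows when nothing passes the thresholds.
#' @export
call_apa_sites <- function(positions, strand = "+", min_separation = 200,
                           min_support = 5, min_fraction = 0.10,
                           smooth_bins = 3L, bin = 25L,
                           gene_id = NA_character_) {
  stopifnot(strand %in% c("+", "-"), bin >= 1, smooth_bins >= 1)
  empty <- data.table(gene_id = character(), position = numeric(),
                      support = numeric(), fraction = numeric(),
                      kind = character())
  setattr(empty, "class", c("polya_calls", class(empty)))
  if (!length(positions)) return(empty)

  n <- length(positions)
  left0 <- floor(min(positions) / bin)
  b <- floor(positions / bin) - left0 + 1L       # 1-based bin index
  counts <- tabulate(b, nbins = max(b))
  half <- (smooth_bins - 1L) %/% 2L
  padded <- c(rep(0, half), counts, rep(0, half))
  smoothed <- vapply(seq_along(counts),
                     function(i) mean(padded[i:(i + 2L * half)]), numeric(1))
  win_support <- vapply(seq_along(counts), function(i) {
    sum(counts[max(1L, i - half):min(length(counts), i + half)])
  }, numeric(1))

  lo <- c(-Inf, head(smoothed, -1L))
  hi <- c(tail(smoothed, -1L), -Inf)
  is_max <- smoothed >= lo & smoothed >= hi & counts > 0
  # collapse plateaus of equal smoothed height to their first bin
  is_max <- is_max & !(smoothed == lo & c(FALSE, head(is_max, -1L)))
  cand <- which(is_max & win_support >= min_support &
                  win_support / n >= min_fraction)
  if (!length(cand)) return(empty)

  centers <- (cand + left0 - 1L) * bin + bin / 2
  ord <- order(-smoothed[cand], -win_support[cand],
               if (strand == "+") -centers else centers)
  accepted <- integer()
  for (i in ord) {
    if (!length(accepted) ||
        all(abs(centers[i] - centers[accepted]) > min_separation))
      accepted <- c(accepted, i)
  }
  pos <- centers[accepted]

  # attribute every tag to its nearest accepted call
  nearest <- apply(abs(outer(positions, pos, "-")), 1L, which.min)
  support <- tabulate(nearest, nbins = length(pos))
  out <- data.table(gene_id = gene_id, position = pos,
                    support = as.numeric(support),
                    fraction = support / n)
  if (strand == "+") setorder(out, -position) else setorder(out, position)
  out[, kind := c("primary", rep("alternative", .N - 1L))]
  setattr(out, "class", c("polya_calls", class(out)))
  out[]
}

#' Locate the antisense tag peak of a gene
#'
#' Runs the poly(A) peak caller of [call_apa_sites()] on a gene's
#' antisense-layer tag positions and returns the strongest surviving peak,
#' interpreted as the poly(A) site of an antisense transcript, or `NULL`
#' when no candidate passes the support and fraction thresholds.
#'
#' @inheritParams call_apa_sites
#' @param ... Passed to [call_apa_sites()].
#' @return One-row `polya_calls` table with `kind = "antisense"`, or `NULL`.
#' @export
antisense_peak <- function(positions, strand = "+", gene_id = NA_character_, ...) {
  calls <- call_apa_sites(positions, strand = strand, gene_id = gene_id, ...)
  if (!nrow(calls)) return(NULL)
  top <- calls[which.max(support)]
  top[, kind := "antisense"]
  top[]
}

#' Detect novel transcription regions from unassigned reads
#'
#' Clusters the genomic alignments of reads that the rule cascade left
#' unassigned. Per strand, alignments closer than `merge_gap` are merged;
#' clusters supported by at least `min_support` reads are reported together
#' with their nearest annotated gene. Pooling unassigned reads across
#' samples before calling increases sensitivity.
#'
#' @param alignments data frame of unassigned genomic alignments
#'   (`read_id`, `chrom`, `start`, `end`, `strand`).
#' @param index An `annotation_index`, used for nearest-gene annotation
#'   (optional).
#' @param merge_gap Maximum gap (bp) merged into one region (default 100).
#' @param min_support Minimum supporting reads per region (default 10).
#' @return data.table of class `novel_regions`: `chrom`, `start`, `end`,
#'   `strand`, `support`, `nearest_gene`, `distance`.
#' @export
detect_novel_regions <- function(alignments, index = NULL, merge_gap = 100L,
                                 min_support = 10L) {
  aln <- as.data.table(alignments)
  if (!nrow(aln)) {
    out <- data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), support = integer(),
                      nearest_gene = character(), distance = integer())
    setattr(out, "class", c("novel_regions", class(out)))
    return(out)
  }
  gr <- GenomicRanges::GRanges(aln$chrom, IRanges::IRanges(aln$start, aln$end),
                               strand = aln$strand)
  reg <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L)
  support <- GenomicRanges::countOverlaps(reg, gr)
  keep <- support >= min_support
  reg <- reg[keep]
  out <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(reg)),
    start = GenomicRanges::start(reg),
    end = GenomicRanges::end(reg),
    strand = as.character(GenomicRanges::strand(reg)),
    support = as.integer(support[keep]),
    nearest_gene = NA_character_,
    distance = NA_integer_
  )
  if (!is.null(index) && nrow(out)) {
    hit <- GenomicRanges::distanceToNearest(reg, index$gene_gr,
                                            ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hit)
    out$nearest_gene[q] <- names(index$gene_gr)[S4Vectors::subjectHits(hit)]
    out$distance[q] <- S4Vectors::mcols(hit)$distance
  }
  setattr(out, "class", c("novel_regions", class(out)))
  out[]
}

#' Poly(A) sites from the junction-anchored second read
#'
#' In paired-end tag libraries, read 2 is primed at the poly(A) junction, so
#' its 3'-most genomic base in transcript orientation marks the poly(A)
#' site. Positions are attributed to the gene they fall in (on the mRNA
#' strand, i.e. the strand opposite the read-2 alignment), aggregated per
#' gene with [call_apa_sites()], and each call is flagged `annotated` when
#' it lies within `tolerance` bp of an annotated transcript 3' end of that
#' gene, `novel` otherwise.
#'
#' @param read2 data frame of read-2 alignments (`read_id`, `chrom`,
#'   `start`, `end`, `strand`), optionally with a logical `proper` column;
#'   improperly paired records are excluded and counted.
#' @param index An `annotation_index`.
#' @param tolerance Distance (bp) to an annotated 3' end below which a call
#'   is flagged annotated (default 50).
#' @param ... Passed to [call_apa_sites()].
#' @return `polya_calls` table with `kind = "read2_derived"` and an extra
#'   logical column `annotated`; attributes `n_excluded` (improper pairs)
#'   and `n_intergenic` (positions in no gene).
#' @export
polya_sites_from_pairs <- function(read2, index, tolerance = 50L, ...) {
  aln <- as.data.table(read2)
  n_excluded <- 0L
  if ("proper" %in% names(aln)) {
    n_excluded <- sum(!aln$proper)
    aln <- aln[proper == TRUE]
  }
  # mRNA strand is opposite the read-2 alignment strand; the poly(A) site is
  # the 3'-most base in transcript orientation
  mrna_strand <- ifelse(aln$strand == "+", "-", "+")
  pos <- ifelse(mrna_strand == "+", aln$end, aln$start)
  pgr <- GenomicRanges::GRanges(aln$chrom, IRanges::IRanges(pos, pos),
                                strand = mrna_strand)
  fo <- GenomicRanges::findOverlaps(pgr, index$gene_gr)
  hits <- data.table(position = pos[S4Vectors::queryHits(fo)],
                     gene_id = names(index$gene_gr)[S4Vectors::subjectHits(fo)])
  n_intergenic <- nrow(aln) - length(unique(S4Vectors::queryHits(fo)))

  ends <- index$transcripts[, .(gene_id, three_prime_end)]
  calls <- hits[, {
    s <- index$genes$strand[match(.BY$gid, index$genes$gene_id)]
    call_apa_sites(position, strand = s, gene_id = .BY$gid, ...)
  }, by = .(gid = gene_id)][, gid := NULL]
  if (nrow(calls)) {
    calls[, kind := "read2_derived"]
    calls[, annotated := {
      e <- ends[gene_id == .BY$gene_id2, three_prime_end]
      vapply(position, function(p) any(abs(p - e) <= tolerance), logical(1))
    }, by = .(gene_id2 = gene_id)]
  } else {
    calls[, annotated := logical()]
  }
  out <- calls
  setattr(out, "class", c("polya_calls", class(calls)))
  setattr(out, "n_excluded", n_excluded)
  setattr(out, "n_intergenic", n_intergenic)
  out
}

#' Export poly(A) calls or novel regions as BED6
#'
#' @param x A `polya_calls` or `novel_regions` table.
#' @param path Output BED path. Scores are read support; names are gene ids
#'   or region ids.
#' @return `path`, invisibly.
#' @export
export_bed <- function(x, path) {
  if (inherits(x, "novel_regions")) {
    gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end),
                                 strand = x$strand)
    gr$name <- sprintf("region_%d", seq_len(nrow(x)))
    gr$score <- x$support
  } else {
    stopifnot("chrom" %in% names(x) || all(!is.na(x$gene_id)))
    chrom <- if ("chrom" %in% names(x)) x$chrom else x$gene_id
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(round(x$position), round(x$position)))
    gr$name <- paste0(x$gene_id, ":", x$kind)
    gr$score <- x$support
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
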