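#' Load a gene annotation into an indexed, strand-aware structure
#'
#' Reads a GFF3 or GTF annotation and builds the index used by tag
#' assignment and 3'-end profiling: gene spans, per-transcript 3' ends,
#' the longest splice variant of every gene, and the downstream window
#' extending `window_bp` bases past each gene's 3' end on its sense strand.
#' That window is what rescues antisense-looking tags that really belong to
#' the 3' UTR overhang of a neighbouring gene.
#'
#' Coordinates are 1-based inclusive (GRanges convention). Gene limits are
#' the full annotated span including introns and UTRs; transcript length is
#' the summed exon length.
#'
#' @param file Path to a GFF3 (`ID`/`Parent` attributes) or GTF
#'   (`gene_id`/`transcript_id` attributes) file. Transcripts without exon
#'   records fall back to their own span as a single exon.
#' @param window_bp Width, in genomic bp, of the downstream window past each
#'   gene's 3' end (default 500).
#' @param rrna_ids Optional character vector of gene ids to flag as rRNA in
#'   addition to genes whose biotype contains "rRNA".
#' @return An object of class `annotation_index`.
#' @examples
#' gff <- system.file("extdata", "toy.gff3", package = "exprss")
#' idx <- load_annotation(gff)
#' idx$genes
#' @export
load_annotation <- function(file, window_bp = 500, rrna_ids = NULL) {
  stopifnot(length(file) == 1L, file.exists(file), window_bp >= 0)
  gr <- rtracklayer::import(file)
  cols <- names(S4Vectors::mcols(gr))
  tabs <- if ("Parent" %in% cols || "ID" %in% cols) {
    .annotation_tables_gff3(gr)
  } else if ("gene_id" %in% cols) {
    .annotation_tables_gtf(gr)
  } else {
    stop("annotation has neither GFF3 ID/Parent nor GTF gene_id attributes: ",
         file)
  }
  build_annotation_index(tabs$genes, tabs$transcripts, window_bp = window_bp,
                         rrna_ids = rrna_ids)
}

.first_chr <- function(x) {
  if (is(x, "CharacterList")) {
    vapply(x, function(v) if (length(v)) v[[1L]] else NA_character_,
           character(1))
  } else {
    as.character(x)
  }
}

# Feature types treated as transcripts when their Parent is a gene.
.TX_TYPES <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "rRNA", "tRNA",
               "snRNA", "snoRNA", "miRNA", "pseudogenic_transcript",
               "antisense_RNA", "pre_miRNA")

.annotation_tables_gff3 <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(mc)) .first_chr(mc$Parent) else rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no 'gene' features found in GFF3 annotation")
  gid <- id[is_gene]
  if (anyNA(gid)) stop("gene feature without ID attribute")
  biotype <- rep("protein_coding", sum(is_gene))
  for (key in c("biotype", "gene_biotype", "locus_type")) {
    if (key %in% names(mc)) {
      v <- as.character(mc[[key]])[is_gene]
      biotype[!is.na(v)] <- v[!is.na(v)]
      break
    }
  }
  genes <- data.table(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    biotype = biotype
  )

  is_tx <- type %in% .TX_TYPES & !is.na(parent)
  if (any(is_tx & !(parent %in% gid)))
    stop("transcript feature(s) with unknown parent gene: ",
         paste(head(id[is_tx & !(parent %in% gid)]), collapse = ", "))
  tx <- data.table(
    tx_id = id[is_tx],
    gene_id = parent[is_tx],
    start = GenomicRanges::start(gr)[is_tx],
    end = GenomicRanges::end(gr)[is_tx]
  )
  if (anyNA(tx$tx_id)) stop("transcript feature without ID attribute")

  is_exon <- type == "exon" & !is.na(parent) & parent %in% tx$tx_id
  exons <- data.table(
    tx_id = parent[is_exon],
    start = GenomicRanges::start(gr)[is_exon],
    end = GenomicRanges::end(gr)[is_exon]
  )
  # transcripts without exon records: their span is the single exon
  missing <- setdiff(tx$tx_id, exons$tx_id)
  if (length(missing))
    exons <- rbind(exons, tx[tx_id %in% missing, .(tx_id, start, end)])
  list(genes = genes, transcripts = merge(tx, .exon_summary(exons), by = "tx_id"))
}

.annotation_tables_gtf <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  keep <- type == "exon"
  if (!any(keep)) stop("no 'exon' features found in GTF annotation")
  ex <- data.table(
    gene_id = as.character(mc$gene_id)[keep],
    tx_id = as.character(mc$transcript_id)[keep],
    chrom = as.character(GenomicRanges::seqnames(gr))[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    start = GenomicRanges::start(gr)[keep],
    end = GenomicRanges::end(gr)[keep]
  )
  if (anyNA(ex$gene_id) || anyNA(ex$tx_id))
    stop("GTF exon without gene_id or transcript_id")
  biot <- rep("protein_coding", length(gr))
  if ("gene_biotype" %in% names(mc)) {
    v <- as.character(mc$gene_biotype)
    biot[!is.na(v)] <- v[!is.na(v)]
  }
  ex$biotype <- biot[keep]
  genes <- ex[, .(chrom = chrom[1L], strand = strand[1L],
                  start = min(start), end = max(end),
                  biotype = biotype[1L]), by = gene_id]
  txspan <- ex[, .(gene_id = gene_id[1L], start = min(start), end = max(end)),
               by = tx_id]
  tx <- merge(txspan, .exon_summary(ex[, .(tx_id, start, end)]), by = "tx_id")
  list(genes = genes, transcripts = tx)
}

.exon_summary <- function(exons) {
  exons[, .(length = sum(end - start + 1L),
            exon_min = min(start), exon_max = max(end)), by = tx_id]
}

#' Build an annotation index from gene and transcript tables
#'
#' Lower-level constructor behind [load_annotation()], used directly by the
#' simulator so that a synthetic transcriptome need not round-trip through a
#' GFF3 file.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `start`, `end` (1-based inclusive) and optionally `biotype`.
#' @param transcripts data.frame with columns `tx_id`, `gene_id`, `start`,
#'   `end`, `length` (summed exon length).
#' @param window_bp,rrna_ids See [load_annotation()].
#' @return `annotation_index` object: a list with `genes`, `transcripts`,
#'   `longest` (the longest splice variant per gene and its 3' end),
#'   strand-aware GRanges for gene spans and downstream windows, and the
#'   rRNA gene set.
#' @export
build_annotation_index <- function(genes, transcripts, window_bp = 500,
                                   rrna_ids = NULL) {
  genes <- as.data.table(genes)
  tx <- as.data.table(transcripts)
  if (!"biotype" %in% names(genes)) genes[, biotype := "protein_coding"]
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in annotation")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (!all(tx$gene_id %in% genes$gene_id))
    stop("transcript with unknown parent gene: ",
         paste(head(setdiff(tx$gene_id, genes$gene_id)), collapse = ", "))
  if (!nrow(tx)) stop("annotation contains no transcripts")

  tx <- merge(tx, genes[, .(gene_id, chrom, strand)], by = "gene_id",
              suffixes = c("", ".gene"))
  bad <- merge(tx, genes[, .(gene_id, gstart = start, gend = end)],
               by = "gene_id")[start < gstart | end > gend]
  if (nrow(bad))
    stop("transcript outside its gene span: ",
         paste(head(bad$tx_id), collapse = ", "))
  tx[, three_prime_end := ifelse(strand == "+", end, start)]

  # longest splice variant per gene; ties broken by transcript id
  setorder(tx, gene_id, -length, tx_id)
  longest <- tx[, .SD[1L], by = gene_id][, .(gene_id, tx_id, length, three_prime_end)]

  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  names(gene_gr) <- genes$gene_id

  win_start <- ifelse(genes$strand == "+", genes$end + 1L,
                      pmax(1L, genes$start - as.integer(window_bp)))
  win_end <- ifelse(genes$strand == "+", genes$end + as.integer(window_bp),
                    genes$start - 1L)
  empty <- win_end < win_start  # window_bp = 0 or window clipped at position 1
  win_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(ifelse(empty, 1L, win_start),
                              ifelse(empty, 0L, win_end)),
    strand = genes$strand
  )
  names(win_gr) <- genes$gene_id

  rrna <- union(genes[grepl("rRNA", biotype, ignore.case = TRUE), gene_id],
                intersect(rrna_ids, genes$gene_id))
  idx <- list(
    genes = genes[], transcripts = tx[], longest = longest[],
    gene_gr = gene_gr, window_gr = win_gr,
    tx2gene = setNames(tx$gene_id, tx$tx_id),
    window_bp = window_bp, rrna_genes = rrna
  )
  class(idx) <- "annotation_index"
  idx
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("annotation_index:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts on",
      length(unique(x$genes$chrom)), "sequence(s);",
      "downstream window", x$window_bp, "bp;",
      length(x$rrna_genes), "rRNA gene(s)\n")
  invisible(x)
}

#' Signed distance from a tag start to a gene's 3' end
#'
#' Measures how far upstream of the 3' end a tag begins, the quantity
#' histogrammed in 3'-distance profiles. The 3' end of the *longest* splice
#' variant is used, so tags shared between variants are placed consistently.
#' Positive values lie upstream of the 3' end (inside the transcript),
#' negative values downstream of it.
#'
#' @param index An `annotation_index`.
#' @param gene_id Gene id(s); recycled against `tag_start`.
#' @param tag_start Genomic position(s) of the tag's 5'-most aligned base
#'   (1-based).
#' @return Integer vector of signed distances in bp.
#' @examples
#' gff <- system.file("extdata", "toy.gff3", package = "exprss")
#' idx <- load_annotation(gff)
#' tag_distance_from_3prime(idx, "geneA", 850)
#' @export
tag_distance_from_3prime <- function(index, gene_id, tag_start) {
  stopifnot(is(index, "annotation_index"))
  m <- match(gene_id, index$longest$gene_id)
  if (anyNA(m)) stop("unknown gene_id: ",
                     paste(head(unique(gene_id[is.na(m)])), collapse = ", "))
  e <- index$longest$three_prime_end[m]
  s <- index$genes$strand[match(gene_id, index$genes$gene_id)]
  as.integer(ifelse(s == "+", e - tag_start, tag_start - e))
}

#' Query genes overlapping an interval, by orientation
#'
#' Returns, for an oriented genomic interval, the genes it overlaps in sense
#' orientation, the genes it overlaps in antisense orientation, and the genes
#' whose downstream (post-3'-end) window on the query strand contains it.
#'
#' @param index An `annotation_index`.
#' @param chrom Chromosome name.
#' @param start,end Interval (1-based inclusive).
#' @param strand Query strand, `"+"` or `"-"`.
#' @return A list with character vectors `sense`, `antisense`, `downstream`.
#' @export
query_overlaps <- function(index, chrom, start, end, strand) {
  stopifnot(is(index, "annotation_index"), strand %in% c("+", "-"))
  if (!chrom %in% as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(index$gene_gr))) &&
      !chrom %in% unique(index$genes$chrom)) {
    warning("unknown chromosome: ", chrom)
    return(list(sense = character(), antisense = character(),
                downstream = character()))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  GenomeInfoDb::seqlevels(q) <- GenomeInfoDb::seqlevels(index$gene_gr)
  sense <- names(index$gene_gr)[S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(q, index$gene_gr))]
  anti <- names(index$gene_gr)[S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(BiocGenerics::invertStrand(q), index$gene_gr))]
  down <- names(index$window_gr)[S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(q, index$window_gr))]
  list(sense = sense, antisense = anti, downstream = down)
}
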