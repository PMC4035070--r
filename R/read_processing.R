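#' Read a FASTQ file into a read table
#'
#' Reads are held as a `data.table` with columns `id`, `seq`, `qual` and an
#' attribute `phred_offset` recording the quality encoding. Parsing is done
#' by Biostrings; plain and gzipped files are accepted.
#'
#' @param path FASTQ file.
#' @param offset Phred offset: 33, 64, or `"auto"` to detect from the first
#'   10,000 reads (any quality character below `'@'` implies 33; all
#'   characters at or above `'B'` imply 64; anything else is ambiguous and
#'   raises an error asking for an explicit offset).
#' @return data.table(id, seq, qual) with attribute `phred_offset`.
#' @export
read_fastq <- function(path, offset = "auto") {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  reads <- data.table(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities)
  )
  setattr(reads, "phred_offset", .resolve_phred_offset(reads$qual, offset))
  reads
}

#' Write a read table to FASTQ
#'
#' @param reads data.table(id, seq, qual), qualities in phred+33.
#' @param path Output file; `.gz` suffix compresses.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$id
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

.resolve_phred_offset <- function(qual, offset = "auto", n_scan = 10000L) {
  if (!identical(offset, "auto")) {
    offset <- as.integer(offset)
    stopifnot(offset %in% c(33L, 64L))
    return(offset)
  }
  v <- as.integer(charToRaw(paste(head(qual, n_scan), collapse = "")))
  if (!length(v)) return(33L)
  if (any(v < 64L)) return(33L)       # below '@': must be phred+33
  if (all(v >= 66L)) return(64L)      # all at or above 'B': phred+64
  stop("phred offset ambiguous; pass offset = 33 or offset = 64 explicitly")
}

# per-read fraction of bases with quality >= q
.qual_frac_ge <- function(qual, q, offset) {
  widths <- nchar(qual)
  ints <- as.integer(charToRaw(paste(qual, collapse = "")))
  ok <- (ints - offset) >= q
  grp <- rep.int(seq_along(qual), widths)
  n_ok <- rowsum(as.integer(ok), grp, reorder = TRUE)[, 1L]
  n_ok / widths
}

# shift quality strings between phred encodings
.convert_qual <- function(qual, from, to = 33L) {
  if (from == to) return(qual)
  widths <- nchar(qual)
  raw <- as.raw(as.integer(charToRaw(paste(qual, collapse = ""))) - (from - to))
  chunks <- rawToChar(raw)
  substring(chunks, cumsum(c(1L, head(widths, -1L))),
            cumsum(widths))
}

#' Filtering parameters for tag reads
#'
#' Mirrors the FASTX-toolkit settings used for tag libraries: a read passes
#' the quality filter when at least `min_percent` % of its bases have
#' quality >= `min_quality` (both bounds inclusive) and it contains no `N`.
#'
#' @param min_quality Minimum per-base phred quality (default 20).
#' @param min_percent Minimum percentage of bases at that quality
#'   (default 50).
#' @param artifact_max_other A read is an artifact when the number of bases
#'   that are not its most frequent base is at most this value (default 3);
#'   this removes near-homopolymers such as poly(A) ligation products.
#' @param nlaiii_adapter 3' adapter clipped from NlaIII-DGE reads.
#' @param nlaiii_min_len Minimum clipped tag length kept (default 18).
#' @param phred_offset 33, 64 or `"auto"`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_quality = 20, min_percent = 50,
                          artifact_max_other = 3,
                          nlaiii_adapter = "TCGTATGCCGTCTTC",
                          nlaiii_min_len = 18, phred_offset = "auto") {
  stopifnot(min_percent > 0, min_percent <= 100, min_quality >= 0)
  structure(list(min_quality = min_quality, min_percent = min_percent,
                 artifact_max_other = artifact_max_other,
                 nlaiii_adapter = nlaiii_adapter,
                 nlaiii_min_len = nlaiii_min_len,
                 phred_offset = phred_offset),
            class = "filter_config")
}

.reads_offset <- function(reads, config) {
  off <- attr(reads, "phred_offset")
  if (!is.null(off)) off else .resolve_phred_offset(reads$qual, config$phred_offset)
}

#' Quality-filter reads
#'
#' Discards reads containing `N` and reads where fewer than
#' `config$min_percent` % of bases reach quality `config$min_quality`.
#'
#' @param reads data.table(id, seq, qual).
#' @param config A [filter_config()].
#' @return list with `reads` (passing reads) and `tally`
#'   (`n_input`, `n_pass`, `n_reject_n`, `n_reject_quality`).
#' @export
quality_filter <- function(reads, config = filter_config()) {
  offset <- .reads_offset(reads, config)
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  frac <- .qual_frac_ge(reads$qual, config$min_quality, offset)
  ok_q <- 100 * frac >= config$min_percent
  pass <- !has_n & ok_q
  out <- reads[pass]
  setattr(out, "phred_offset", offset)
  list(reads = out,
       tally = list(n_input = nrow(reads), n_pass = sum(pass),
                    n_reject_n = sum(has_n),
                    n_reject_quality = sum(!has_n & !ok_q)))
}

#' Remove near-homopolymer artifact reads
#'
#' A read is removed when all but at most `config$artifact_max_other` of its
#' bases are the same base, the signature of poly(A)/poly(T) ligation
#' artifacts.
#'
#' @inheritParams quality_filter
#' @return list with `reads` (kept reads) and `n_removed`.
#' @export
artifact_filter <- function(reads, config = filter_config()) {
  len <- nchar(reads$seq)
  max_base <- rep(0L, nrow(reads))
  for (b in c("A", "C", "G", "T", "N")) {
    cnt <- len - nchar(gsub(b, "", reads$seq, fixed = TRUE))
    max_base <- pmax(max_base, cnt)
  }
  artifact <- (len - max_base) <= config$artifact_max_other
  out <- reads[!artifact]
  setattr(out, "phred_offset", attr(reads, "phred_offset"))
  list(reads = out, n_removed = sum(artifact))
}

#' Define a barcode set for demultiplexing
#'
#' Barcodes are 3-6 nt and sit at the start of read 1. In `exprss` mode
#' assignment requires a perfect prefix match, so the set must be
#' prefix-free (no barcode may be a prefix of another); this is checked at
#' construction. In `nlaiii` mode up to one mismatch is tolerated.
#'
#' @param sample_ids Unique sample names.
#' @param barcodes Barcode sequences (A/C/G/T), one per sample.
#' @param mode `"exprss"` (exact prefix) or `"nlaiii"` (<= 1 mismatch).
#' @return A `barcode_set`.
#' @export
barcode_set <- function(sample_ids, barcodes, mode = c("exprss", "nlaiii")) {
  mode <- match.arg(mode)
  barcodes <- toupper(barcodes)
  stopifnot(length(sample_ids) == length(barcodes),
            !anyDuplicated(sample_ids), !anyDuplicated(barcodes))
  len <- nchar(barcodes)
  if (any(len < 3L | len > 6L))
    stop("barcode lengths must be between 3 and 6 nt")
  if (any(grepl("[^ACGT]", barcodes)))
    stop("barcodes may only contain A/C/G/T")
  if (mode == "exprss") {
    for (i in seq_along(barcodes)) {
      pref <- barcodes[startsWith(barcodes, barcodes[i])]
      if (length(pref) > 1L)
        stop("barcode set is not prefix-free: '", barcodes[i],
             "' is a prefix of '", setdiff(pref, barcodes[i])[1L], "'")
    }
  }
  structure(list(table = data.table(sample_id = as.character(sample_ids),
                                    barcode = barcodes, len = len),
                 mode = mode),
            class = "barcode_set")
}

#' Read a sample sheet (sample_id TAB barcode)
#'
#' @param path TSV file with two columns, optional header.
#' @param mode Passed to [barcode_set()].
#' @return A `barcode_set`.
#' @export
read_barcode_table <- function(path, mode = c("exprss", "nlaiii")) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, col.names = c("sample_id", "barcode"))
  if (grepl("[^ACGTacgt]", tab$barcode[1L]))  # header row
    tab <- tab[-1L, , drop = FALSE]
  barcode_set(tab$sample_id, tab$barcode, mode = match.arg(mode))
}

# number of mismatches between the length-k prefix of each seq and barcode bc
.prefix_mismatches <- function(seqs, bc) {
  k <- nchar(bc)
  mm <- ifelse(nchar(seqs) >= k, 0L, NA_integer_)
  for (p in seq_len(k)) {
    mm <- mm + (substr(seqs, p, p) != substr(bc, p, p))
  }
  mm
}

#' Demultiplex reads by their barcode prefix
#'
#' In `exprss` mode a read is assigned to a sample when its prefix equals
#' that sample's barcode exactly (barcodes are tested longest-first, which
#' together with the prefix-free requirement makes the result
#' order-independent). In `nlaiii` mode a read is assigned when exactly one
#' barcode matches its prefix with at most one mismatch; reads matching two
#' barcodes are routed to the unassigned stream. Assigned reads have the
#' barcode trimmed off. Every input read lands in exactly one output stream.
#'
#' @param reads data.table(id, seq, qual).
#' @param barcodes A [barcode_set()].
#' @return list with `samples` (named list of read tables), `unassigned`
#'   (read table), and `summary` (data.table of per-sample counts plus the
#'   `"<unassigned>"` row).
#' @export
demultiplex <- function(reads, barcodes) {
  stopifnot(is(barcodes, "barcode_set"))
  tab <- barcodes$table[order(-len)]
  n <- nrow(reads)
  assigned <- rep(NA_character_, n)
  trim_len <- integer(n)

  if (barcodes$mode == "exprss") {
    for (i in seq_len(nrow(tab))) {
      un <- which(is.na(assigned))
      hit <- un[substr(reads$seq[un], 1L, tab$len[i]) == tab$barcode[i]]
      assigned[hit] <- tab$sample_id[i]
      trim_len[hit] <- tab$len[i]
    }
  } else {
    mm <- vapply(seq_len(nrow(tab)),
                 function(i) .prefix_mismatches(reads$seq, tab$barcode[i]),
                 integer(n))
    mm <- matrix(mm, nrow = n)
    hits <- !is.na(mm) & mm <= 1L
    n_hit <- rowSums(hits)
    uniq <- which(n_hit == 1L)
    which_bc <- max.col(hits[uniq, , drop = FALSE], ties.method = "first")
    assigned[uniq] <- tab$sample_id[which_bc]
    trim_len[uniq] <- tab$len[which_bc]
  }

  offset <- attr(reads, "phred_offset")
  split_reads <- function(keep, trim) {
    out <- data.table(id = reads$id[keep],
                      seq = substring(reads$seq[keep], trim + 1L),
                      qual = substring(reads$qual[keep], trim + 1L))
    setattr(out, "phred_offset", offset)
    out
  }
  samples <- lapply(setNames(barcodes$table$sample_id, barcodes$table$sample_id),
                    function(s) {
                      keep <- which(!is.na(assigned) & assigned == s)
                      split_reads(keep, trim_len[keep])
                    })
  un <- which(is.na(assigned))
  unassigned <- split_reads(un, 0L)
  summary <- rbind(
    data.table(sample_id = barcodes$table$sample_id,
               n_reads = vapply(samples, nrow, integer(1))),
    data.table(sample_id = "<unassigned>", n_reads = length(un))
  )
  list(samples = samples, unassigned = unassigned, summary = summary)
}

#' Prepare NlaIII-DGE reads for alignment
#'
#' Clips the 3' adapter and everything after it, discards reads without the
#' adapter or with a clipped tag shorter than `config$nlaiii_min_len`, then
#' restores the NlaIII recognition site `CATG` at the 5' end with constant
#' quality `"FFFF"` (phred+33 value 37 per base). Qualities are emitted in
#' phred+33 regardless of the input encoding.
#'
#' @inheritParams quality_filter
#' @return list with `reads` (tag reads ready for alignment) and `tally`
#'   (`n_input`, `n_no_adapter`, `n_too_short`, `n_pass`).
#' @export
nlaiii_preprocess <- function(reads, config = filter_config()) {
  offset <- .reads_offset(reads, config)
  qual33 <- .convert_qual(reads$qual, from = offset, to = 33L)
  pos <- regexpr(config$nlaiii_adapter, reads$seq, fixed = TRUE)
  has_adapter <- pos > 0L
  tag <- substr(reads$seq, 1L, pmax(0L, pos - 1L))
  long_enough <- nchar(tag) >= config$nlaiii_min_len
  keep <- has_adapter & long_enough
  out <- data.table(
    id = reads$id[keep],
    seq = paste0("CATG", tag[keep]),
    qual = paste0("FFFF", substr(qual33[keep], 1L, nchar(tag[keep])))
  )
  setattr(out, "phred_offset", 33L)
  list(reads = out,
       tally = list(n_input = nrow(reads),
                    n_no_adapter = sum(!has_adapter),
                    n_too_short = sum(has_adapter & !long_enough),
                    n_pass = nrow(out)))
}

#' Per-cycle base balance of a barcode set
#'
#' Barcode sets for tag libraries are designed so that an equimolar pool
#' shows a near-equal share of all four bases at each of the first 5-6
#' sequencing cycles. Cycles beyond a barcode's length are padded with a
#' uniform A/C/G/T placeholder (the insert contributes all four bases there
#' in expectation).
#'
#' @param barcodes A [barcode_set()] or a character vector of barcodes.
#' @return list with `fractions` (4 x 6 matrix, rows A/C/G/T, columns
#'   cycles 1-6; each column sums to 1) and `max_deviation`, the largest
#'   absolute deviation from 0.25.
#' @export
barcode_balance <- function(barcodes) {
  bc <- if (is(barcodes, "barcode_set")) barcodes$table$barcode else toupper(barcodes)
  stopifnot(length(bc) >= 2L)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, nrow = 4L, ncol = 6L, dimnames = list(bases, paste0("cycle", 1:6)))
  for (b in bc) {
    for (cyc in 1:6) {
      if (cyc <= nchar(b)) {
        counts[substr(b, cyc, cyc), cyc] <- counts[substr(b, cyc, cyc), cyc] + 1
      } else {
        counts[, cyc] <- counts[, cyc] + 0.25
      }
    }
  }
  fractions <- counts / length(bc)
  list(fractions = fractions, max_deviation = max(abs(fractions - 0.25)))
}
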