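# Independent brute-force re-implementations used as oracles. These are
# written as plain loops over plain tables, deliberately sharing no code with
# the package internals.

# Rule cascade for one read, evaluated the slow way.
oracle_assign_read <- function(aln, genes, window_bp = 500, max_genes = 10,
                               tx2gene = NULL) {
  cand <- data.frame(gene = character(), orient = character())
  for (r in seq_len(nrow(aln))) {
    row <- as.list(aln[r, ])
    if (identical(row$source, "transcript")) {
      g <- tx2gene[[row$chrom]]
      if (!is.null(g))
        cand <- rbind(cand, data.frame(
          gene = g, orient = if (row$strand == "+") "sense" else "antisense"))
      next
    }
    overlaps <- function(j) genes$chrom[j] == row$chrom &&
      genes$start[j] <= row$end && genes$end[j] >= row$start
    sense <- anti <- character()
    for (j in seq_len(nrow(genes))) {
      if (!overlaps(j)) next
      if (genes$strand[j] == row$strand) sense <- c(sense, genes$gene_id[j])
      else anti <- c(anti, genes$gene_id[j])
    }
    if (length(sense)) {
      cand <- rbind(cand, data.frame(gene = sense, orient = "sense"))
    } else if (length(anti)) {
      p <- if (row$strand == "+") row$start else row$end
      win <- character()
      for (j in seq_len(nrow(genes))) {
        if (genes$chrom[j] != row$chrom || genes$strand[j] != row$strand) next
        inside <- if (genes$strand[j] == "+")
          p > genes$end[j] && p <= genes$end[j] + window_bp
        else
          p < genes$start[j] && p >= genes$start[j] - window_bp
        if (inside) win <- c(win, genes$gene_id[j])
      }
      if (length(win))
        cand <- rbind(cand, data.frame(gene = win, orient = "sense"))
      else
        cand <- rbind(cand, data.frame(gene = anti, orient = "antisense"))
    }
  }
  cand <- unique(cand)
  # a gene reached both ways counts once, as sense
  dup <- cand$gene[cand$orient == "sense"]
  cand <- cand[cand$orient == "sense" | !(cand$gene %in% dup), ]
  n <- nrow(cand)
  if (n == 0) return(list(outcome = "unassigned", targets = cand))
  if (n > max_genes) return(list(outcome = "discarded_multigene", targets = cand[0, ]))
  cand$weight <- 1 / n
  list(outcome = "assigned", targets = cand[order(cand$gene), ])
}

# Exhaustive peak caller: every local maximum of the smoothed histogram is a
# candidate; selection is greedy by height with a pairwise separation check.
oracle_apa_positions <- function(positions, min_separation = 200,
                                 min_support = 5, min_fraction = 0.10,
                                 smooth_bins = 3, bin = 25) {
  n <- length(positions)
  left0 <- floor(min(positions) / bin)
  nb <- floor(max(positions) / bin) - left0 + 1
  counts <- rep(0, nb)
  for (p in positions) {
    b <- floor(p / bin) - left0 + 1
    counts[b] <- counts[b] + 1
  }
  half <- (smooth_bins - 1) %/% 2
  sm <- win <- rep(0, nb)
  for (i in seq_len(nb)) {
    lo <- max(1, i - half); hi <- min(nb, i + half)
    win[i] <- sum(counts[lo:hi])
    sm[i] <- sum(counts[lo:hi], rep(0, smooth_bins - (hi - lo + 1))) / smooth_bins
  }
  raw <- rep(FALSE, nb)
  for (i in seq_len(nb)) {
    if (counts[i] == 0) next
    left_ok <- i == 1 || sm[i] >= sm[i - 1]
    right_ok <- i == nb || sm[i] >= sm[i + 1]
    raw[i] <- left_ok && right_ok
  }
  is_max <- raw
  for (i in seq_len(nb)[-1]) {
    if (raw[i] && raw[i - 1] && sm[i] == sm[i - 1]) is_max[i] <- FALSE
  }
  cands <- which(is_max & win >= min_support & win / n >= min_fraction)
  if (!length(cands)) return(numeric())
  centers <- (cands + left0 - 1) * bin + bin / 2
  ord <- order(-sm[cands], -win[cands], -centers)
  acc <- numeric()
  for (i in ord) {
    if (all(abs(centers[i] - acc) > min_separation)) acc <- c(acc, centers[i])
  }
  sort(acc)
}
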