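#' Tags-per-million normalization
#'
#' Scales each sample's counts to tags per million: `count / total * 1e6`,
#' where the denominator is the sample's total assigned tag mass summed over
#' *both* the sense and antisense layers (both layers come from a single
#' sequencing pool, so they share one library size). Consequently the TPM
#' values of the two layers of a sample jointly sum to 1e6.
#'
#' @param counts SummarizedExperiment from [build_count_matrix()] with
#'   assays `sense` and `antisense`.
#' @return SummarizedExperiment of the same shape with TPM-scaled assays;
#'   the source totals are kept in `colData$library_size`.
#' @export
compute_tpm <- function(counts) {
  s <- SummarizedExperiment::assay(counts, "sense")
  a <- SummarizedExperiment::assay(counts, "antisense")
  totals <- colSums(s) + colSums(a)
  if (any(totals <= 0))
    stop("sample(s) with zero assigned tags: ",
         paste(colnames(s)[totals <= 0], collapse = ", "))
  tpm <- SummarizedExperiment::SummarizedExperiment(
    assays = list(sense = sweep(s, 2L, totals, "/") * 1e6,
                  antisense = sweep(a, 2L, totals, "/") * 1e6),
    rowData = SummarizedExperiment::rowData(counts),
    colData = SummarizedExperiment::colData(counts)
  )
  SummarizedExperiment::colData(tpm)$library_size <- totals
  tpm
}

.layer_matrix <- function(x, layer = "sense") {
  if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x, layer)
  else as.matrix(x)
}

#' Detection filter on mean TPM over replicates
#'
#' A gene counts as detected when its mean TPM across a condition's
#' replicates reaches `min_tpm` (inclusive) and at least `min_reps`
#' replicates are available. `mode = "each"` instead requires `min_tpm` in
#' every one of at least `min_reps` replicates, a stricter reading of the
#' same criterion.
#'
#' @param tpm SummarizedExperiment from [compute_tpm()] or a TPM matrix
#'   (genes x samples).
#' @param samples Columns forming the replicate group (default all).
#' @param min_tpm Detection threshold in TPM (default 1).
#' @param min_reps Minimum replicate count (default 4); fewer replicates is
#'   an error.
#' @param mode `"mean"` (default) or `"each"`.
#' @param layer Assay layer when `tpm` is a SummarizedExperiment.
#' @return data.table(gene_id, mean_tpm, n_replicates_used, detected).
#' @export
detection_filter <- function(tpm, samples = NULL, min_tpm = 1, min_reps = 4,
                             mode = c("mean", "each"), layer = "sense") {
  mode <- match.arg(mode)
  m <- .layer_matrix(tpm, layer)
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  if (ncol(m) < min_reps)
    stop("need at least ", min_reps, " replicates, got ", ncol(m))
  means <- rowMeans(m)
  detected <- if (mode == "mean") means >= min_tpm
              else rowSums(m >= min_tpm) >= min_reps
  data.table(gene_id = rownames(m), mean_tpm = means,
             n_replicates_used = ncol(m), detected = detected)
}

#' Log2 fold change between condition means
#'
#' `log2((mean(treatment) + pseudocount) / (mean(control) + pseudocount))`,
#' computed per gene on TPM values. The pseudocount (default 1 TPM) damps
#' fold changes of weakly expressed genes.
#'
#' @param control,treatment TPM matrices (genes x replicates) or per-gene
#'   vectors of condition means, with matching genes.
#' @param pseudocount Added to both means before the ratio (default 1).
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_change <- function(control, treatment, pseudocount = 1) {
  mc <- if (is.matrix(control)) rowMeans(control) else control
  mt <- if (is.matrix(treatment)) rowMeans(treatment) else treatment
  stopifnot(length(mc) == length(mt))
  log2((mt + pseudocount) / (mc + pseudocount))
}

#' Pairwise replicate correlation of log-scale expression
#'
#' Pearson correlation of `log10(TPM + 1)` for every sample pair, the
#' standard replicate-quality view for tag count data. Zero-variance samples
#' yield `NA` entries and a warning.
#'
#' @inheritParams detection_filter
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
replicate_correlation <- function(tpm, layer = "sense") {
  m <- .layer_matrix(tpm, layer)
  stopifnot(ncol(m) >= 2)
  lm10 <- log10(m + 1)
  sds <- apply(lm10, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance sample(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
  r <- suppressWarnings(cor(lm10, method = "pearson"))
  diag(r) <- 1
  r
}

#' Fraction of detected genes with a detected antisense transcript
#'
#' Applies [detection_filter()] to the sense and antisense layers and
#' reports the share of sense-detected genes that also pass detection on the
#' antisense layer.
#'
#' @inheritParams detection_filter
#' @return list with `n_detected_sense`, `n_detected_antisense` (among
#'   sense-detected genes) and `fraction`.
#' @export
antisense_detected_fraction <- function(tpm, samples = NULL, min_tpm = 1,
                                        min_reps = 4) {
  s <- detection_filter(tpm, samples, min_tpm, min_reps, layer = "sense")
  a <- detection_filter(tpm, samples, min_tpm, min_reps, layer = "antisense")
  det_s <- s[detected == TRUE, gene_id]
  det_a <- a[detected == TRUE, gene_id]
  both <- intersect(det_s, det_a)
  list(n_detected_sense = length(det_s),
       n_detected_antisense = length(both),
       fraction = if (length(det_s)) length(both) / length(det_s) else NA_real_)
}

#' Export integer counts and a design table for external DE tools
#'
#' Differential-expression testing itself is delegated to negative-binomial
#' count packages (edgeR, DESeq2, baySeq); this writes what they consume: a
#' rounded integer count matrix (sense layer) and a sample-to-condition
#' design table.
#'
#' @param counts SummarizedExperiment from [build_count_matrix()].
#' @param design Named character vector or data.frame mapping sample to
#'   condition.
#' @param dir Output directory; writes `counts.tsv` and `design.tsv`.
#' @return Invisible character vector of the two paths.
#' @export
export_de_tables <- function(counts, design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- round(SummarizedExperiment::assay(counts, "sense"))
  cpath <- file.path(dir, "counts.tsv")
  fwrite(data.table(gene_id = rownames(m), as.data.table(m)), cpath, sep = "\t")
  if (!is.data.frame(design))
    design <- data.frame(sample_id = names(design), condition = unname(design))
  dpath <- file.path(dir, "design.tsv")
  fwrite(as.data.table(design), dpath, sep = "\t")
  invisible(c(cpath, dpath))
}
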