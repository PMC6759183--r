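# Expression preprocessing: CPM filtering, TMM normalisation, and
# between-line variance ranking.

#' Filter and normalise a count matrix
#'
#' Retains genes with more than `cpm_min` counts per million in at least
#' `min_samples` samples (the reference rule: > 2 CPM in >= 44 RILs),
#' normalises libraries by trimmed mean of M-values (TMM), and returns
#' log2(CPM + 0.5) on effective library sizes.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param cpm_min CPM cutoff (exceeded strictly).
#' @param min_samples Minimum number of samples exceeding the cutoff.
#' @return Object of class `expr_matrix`: list with `log2cpm` (genes x
#'   samples), `norm_factors`, `lib_size`.
#' @export
preprocess_counts <- function(counts, cpm_min = 2, min_samples = 44) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    abort(paste("libraries with zero total counts:",
                paste(colnames(counts)[lib == 0], collapse = ", ")))
  }
  cpm_raw <- sweep(counts, 2, lib, `/`) * 1e6
  keep <- rowSums(cpm_raw > cpm_min) >= min_samples
  counts <- counts[keep, , drop = FALSE]
  dge <- edgeR::DGEList(counts = counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  eff <- dge$samples$lib.size * dge$samples$norm.factors
  log2cpm <- log2(sweep(counts, 2, eff, `/`) * 1e6 + 0.5)
  structure(list(log2cpm = log2cpm,
                 norm_factors = setNames(dge$samples$norm.factors,
                                         colnames(counts)),
                 lib_size = setNames(dge$samples$lib.size, colnames(counts))),
            class = "expr_matrix")
}

#' Keep the most variable genes between lines
#'
#' Ranks genes by the variance of their per-line mean expression (for one
#' sample per line this is the plain between-sample variance) and keeps the
#' top `k`. Ties break by gene id so the selection is deterministic.
#'
#' @param expr An `expr_matrix` or a plain genes x samples matrix.
#' @param k Number of genes to keep (default 10,000).
#' @param line Optional factor/character mapping samples to lines, for
#'   replicated designs.
#' @return A matrix (genes x samples or genes x lines when `line` is
#'   given), ordered by decreasing variance.
#' @export
top_variable <- function(expr, k = 10000, line = NULL) {
  if (k < 1) abort("k must be >= 1")
  m <- if (inherits(expr, "expr_matrix")) expr$log2cpm else as.matrix(expr)
  if (!is.null(line)) {
    m <- t(apply(m, 1, function(v) tapply(v, line, mean)))
  }
  v <- apply(m, 1, var)
  ord <- order(-v, rownames(m))
  m[ord[seq_len(min(k, nrow(m)))], , drop = FALSE]
}
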