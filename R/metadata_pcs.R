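## Sequencing-metadata principal components: batch-effect covariates built
## from per-sample sequencing QC metrics (depth, contamination, and other
## depth-correlated metrics).

#' Compute sequencing-metadata principal components
#'
#' Metrics are median-imputed (rare missing values), z-standardized per
#' column and decomposed by PCA. Constant columns are dropped with a
#' warning. The first `k` score vectors (default 4, which in practice
#' capture essentially all metric variance when the metrics are
#' depth-driven) are returned with the cumulative variance-explained
#' fraction. Signs are fixed so each component's largest-magnitude score is
#' positive.
#'
#' @param metrics samples x metrics numeric matrix or data.frame.
#' @param k number of components (default 4).
#' @return list(scores: samples x k, variance_explained: per-component
#'   fractions, cumulative: cumulative fractions, dropped: names of
#'   constant metrics removed).
#' @export
compute_metadata_pcs <- function(metrics, k = 4) {
  x <- as.matrix(metrics)
  if (!is.numeric(x)) stopf("metrics must be numeric")
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- median(x[, j], na.rm = TRUE)
  }
  if (any(!is.finite(x))) stopf("metrics contain non-finite values")
  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped) > 0) {
    warnf("dropping constant metric column(s): %s",
          paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (ncol(x) < k)
    stopf("need at least k=%d non-constant metrics, have %d", k, ncol(x))
  z <- scale(x)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  k_eff <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k_eff), drop = FALSE]
  for (j in seq_len(k_eff)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("mPC", seq_len(k_eff))
  rownames(scores) <- rownames(metrics)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, variance_explained = ve[seq_len(k_eff)],
       cumulative = cumsum(ve)[seq_len(k_eff)], dropped = dropped)
}

#' Extract the metric matrix from a sample table
#' @param samples sample table carrying the QC metric columns.
#' @param names metric column names (default: the generator's metric set).
#' @export
metric_matrix <- function(samples, names = metric_names()) {
  present <- intersect(names, colnames(samples))
  if (length(present) == 0) stopf("no metric columns found")
  m <- as.matrix(samples[, present, drop = FALSE])
  rownames(m) <- samples$sample_id
  m
}
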