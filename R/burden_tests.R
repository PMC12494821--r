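## Category-level logistic burden tests (annotation states, repeat classes,
## genes, gene sets) and genomic-control lambda diagnostics.

#' Build the covariate matrix for burden and single-variant tests
#'
#' Base covariates are the first 10 genetic PCs, sex, sequencing batch
#' (indicator columns, first level dropped; only meaningful for
#' internal-only comparisons) and the per-sample total weighted burden of
#' the comparison's analyzed variant set. Adding the first 4 metadata PCs
#' gives the `base+metaPCs` model. Aliased columns are dropped
#' automatically at fit time.
#'
#' @param samples sample table for the comparison's samples.
#' @param genetic_pcs samples x k score matrix (or NULL).
#' @param total_burden per-sample total weighted burden (or NULL).
#' @param metadata_pcs samples x 4 metadata PC scores (or NULL).
#' @param include_batch add batch indicator columns.
#' @return numeric design block (no intercept column; the fitters add one).
#' @export
build_covariates <- function(samples, genetic_pcs = NULL, total_burden = NULL,
                             metadata_pcs = NULL, include_batch = FALSE) {
  n <- nrow(samples)
  blocks <- list(sex = as.numeric(samples$sex == "XY"))
  if (!is.null(genetic_pcs)) blocks$gpc <- as.matrix(genetic_pcs)
  if (include_batch) {
    b <- factor(samples$batch)
    if (nlevels(b) > 1) {
      mm <- stats::model.matrix(~b)[, -1, drop = FALSE]
      colnames(mm) <- paste0("batch_", levels(b)[-1])
      blocks$batch <- mm
    }
  }
  if (!is.null(total_burden)) blocks$total_burden <- as.numeric(total_burden)
  if (!is.null(metadata_pcs)) blocks$mpc <- as.matrix(metadata_pcs)
  out <- do.call(cbind, blocks)
  rownames(out) <- samples$sample_id
  out
}

#' Logistic burden test for one category
#'
#' Maximum-likelihood logistic regression of the binary outcome on the
#' (optionally standardized) burden score plus covariates; two-sided Wald
#' p-value on the burden coefficient. Non-convergence or separation falls
#' back to a Firth-penalized fit (flagged `"firth"`). A constant burden
#' yields a flagged degenerate result with `p = 1`.
#'
#' @param burden per-sample burden vector.
#' @param outcome binary outcome (0/1, logical, or a 2-level factor whose
#'   second level is the "case" level).
#' @param covariates covariate matrix from [build_covariates()] (or NULL).
#' @param unit,kind,model labels copied into the result row.
#' @param n_variants number of variants in the category (bookkeeping).
#' @param standardize divide the burden by its SD so the reported log-odds
#'   / OR is per SD of burden (default TRUE; set FALSE for per-allele
#'   effects as in PTV count tests).
#' @param null_fit optional covariate-only fit for warm starts (internal).
#' @return one-row AssocResult data.frame.
#' @export
burden_logistic_test <- function(burden, outcome, covariates = NULL,
                                 unit = "burden", kind = "category",
                                 model = "base", n_variants = NA_integer_,
                                 standardize = TRUE, null_fit = NULL) {
  y <- as_binary_outcome(outcome)
  if (length(unique(y)) < 2) stopf("outcome must contain both classes")
  if (sd(burden) == 0) {
    return(assoc_result(unit, kind, model, estimate = 0, se = NA_real_,
                        p = 1, n_variants = n_variants, flag = "degenerate"))
  }
  x <- if (standardize) burden / sd(burden) else burden
  X0 <- design_with_intercept(covariates, length(y))
  if (is.null(null_fit)) null_fit <- logit_irls(X0, y)
  wt <- wald_logistic(x, y, X0, null_fit = null_fit)
  assoc_result(unit, kind, model, estimate = wt$estimate, se = wt$se,
               p = wt$p, n_variants = n_variants, flag = wt$flag)
}

as_binary_outcome <- function(outcome) {
  if (is.factor(outcome)) return(as.numeric(outcome == levels(outcome)[2]))
  if (is.logical(outcome)) return(as.numeric(outcome))
  if (is.character(outcome)) {
    lv <- sort(unique(outcome))
    if (length(lv) > 2) stopf("outcome has >2 levels")
    return(as.numeric(outcome == lv[2]))
  }
  as.numeric(outcome)
}

design_with_intercept <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  keep <- full_rank_columns(X)
  X[, keep, drop = FALSE]
}

#' Scan all categories of a burden matrix
#'
#' One logistic burden test per category plus family-wise significance
#' flags at `0.05 / n_categories` and at the stricter
#' `0.05 / (n_categories * n_comparisons)`, and the genomic-control lambda
#' over the category p-values.
#'
#' @param burden_mat result of [build_burden_matrix()] (or a plain matrix).
#' @param outcome binary outcome.
#' @param covariates covariate matrix.
#' @param kind label (e.g. "state", "repeat").
#' @param model "base" or "base+metaPCs".
#' @param n_comparisons number of analysis groups for the stricter tier
#'   (default 7).
#' @return list(results, lambda_gc, threshold, strict_threshold).
#' @export
run_category_scan <- function(burden_mat, outcome, covariates = NULL,
                              kind = "state", model = "base",
                              n_comparisons = 7) {
  B <- if (is.list(burden_mat)) burden_mat$burden else burden_mat
  nv <- if (is.list(burden_mat)) burden_mat$n_variants else
    rep(NA_integer_, ncol(B))
  if (ncol(B) < 2) stopf("need >= 2 categories")
  y <- as_binary_outcome(outcome)
  X0 <- design_with_intercept(covariates, length(y))
  null_fit <- logit_irls(X0, y)
  rows <- lapply(seq_len(ncol(B)), function(j) {
    burden_logistic_test(B[, j], y, covariates, unit = colnames(B)[j],
                         kind = kind, model = model, n_variants = nv[j],
                         null_fit = null_fit)
  })
  res <- do.call(rbind, rows)
  thr <- 0.05 / ncol(B)
  strict <- 0.05 / (ncol(B) * n_comparisons)
  res$significant <- res$p < thr
  res$significant_strict <- res$p < strict
  ok <- res$flag != "degenerate" & !is.na(res$p)
  list(results = res, lambda_gc = lambda_gc(res$p[ok]),
       threshold = thr, strict_threshold = strict)
}

#' Genomic-control lambda
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`: the median of the
#' inverse-chi-square(1df) transformed p-values divided by the null median
#' 0.4549. Values near 1 indicate a well-calibrated test family; values
#' above 1, inflation. Zero p-values are clipped to the smallest positive
#' double with a warning.
#'
#' @param pvalues numeric p-values in (0, 1].
#' @return lambda (scalar).
#' @export
lambda_gc <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (length(p) == 0) stopf("lambda_gc: no p-values")
  if (any(p < 0 | p > 1)) stopf("lambda_gc: p-values outside [0,1]")
  if (any(p == 0)) {
    warnf("lambda_gc: %d zero p-value(s) clipped", sum(p == 0))
    p[p == 0] <- .Machine$double.xmin
  }
  median(qchisq(1 - p, df = 1, lower.tail = TRUE)) / qchisq(0.5, 1)
}

#' Gene-level singleton PTV burden tests
#'
#' Per-gene logistic regression of case status on the per-sample count of
#' singleton PTV alleles in the gene (unweighted), restricted by default to
#' genes with more than `min_singletons` PTV singletons. Covariates should
#' include the genetic PCs, sex, and the individual's total number of
#' singleton alleles (the `total` component of the burden matrix). In
#' sensitivity mode (PTVs to 1% MAF) pass `min_singletons = 0` to test all
#' genes.
#'
#' @param gene_burden result of [build_burden_matrix()] grouped by gene
#'   with `weights = NULL`.
#' @param outcome binary outcome.
#' @param covariates covariate matrix (include `gene_burden$total`).
#' @param min_singletons genes with `<= min_singletons` variants are
#'   skipped and recorded (default 10, i.e. strict "> 10" inclusion).
#' @return list(results, skipped, threshold, lambda_gc).
#' @export
gene_ptv_burden <- function(gene_burden, outcome, covariates = NULL,
                            min_singletons = 10) {
  nv <- gene_burden$n_variants
  test_genes <- names(nv)[nv > min_singletons]
  skipped <- setdiff(colnames(gene_burden$burden), test_genes)
  if (length(test_genes) == 0)
    return(list(results = assoc_result(character(0), character(0),
                                       character(0), numeric(0), numeric(0),
                                       numeric(0), integer(0))[0, ],
                skipped = skipped, threshold = NA_real_, lambda_gc = NA_real_))
  y <- as_binary_outcome(outcome)
  X0 <- design_with_intercept(covariates, length(y))
  null_fit <- logit_irls(X0, y)
  rows <- lapply(test_genes, function(gn) {
    burden_logistic_test(gene_burden$burden[, gn], y, covariates, unit = gn,
                         kind = "gene_ptv", model = "base",
                         n_variants = nv[[gn]], standardize = FALSE,
                         null_fit = null_fit)
  })
  res <- do.call(rbind, rows)
  thr <- 0.05 / length(test_genes)
  res$significant <- res$p < thr
  ok <- res$flag != "degenerate" & !is.na(res$p)
  list(results = res, skipped = skipped, threshold = thr,
       lambda_gc = if (any(ok)) lambda_gc(res$p[ok]) else NA_real_)
}

#' Gene-set singleton PTV burden tests
#'
#' For each gene set, per-person PTV counts are summed over the set's genes
#' and tested as a single burden. Two significance tiers are flagged:
#' `0.05 / n_sets` and `0.05 / (n_sets * n_comparisons)`.
#'
#' @param gene_sets named list of character vectors of gene ids.
#' @param gene_burden per-gene burden matrix ([build_burden_matrix()]).
#' @param outcome binary outcome.
#' @param covariates covariate matrix.
#' @param n_comparisons comparisons for the stricter tier (default 2).
#' @return list(results, threshold, strict_threshold).
#' @export
gene_set_burden <- function(gene_sets, gene_burden, outcome,
                            covariates = NULL, n_comparisons = 2) {
  if (length(gene_sets) == 0) stopf("no gene sets supplied")
  y <- as_binary_outcome(outcome)
  X0 <- design_with_intercept(covariates, length(y))
  null_fit <- logit_irls(X0, y)
  rows <- lapply(names(gene_sets), function(nm) {
    genes <- intersect(gene_sets[[nm]], colnames(gene_burden$burden))
    if (length(genes) == 0) stopf("gene set '%s' is empty", nm)
    b <- rowSums(gene_burden$burden[, genes, drop = FALSE])
    burden_logistic_test(b, y, covariates, unit = nm, kind = "gene_set",
                         model = "base",
                         n_variants = sum(gene_burden$n_variants[genes]),
                         standardize = FALSE, null_fit = null_fit)
  })
  res <- do.call(rbind, rows)
  thr <- 0.05 / length(gene_sets)
  strict <- thr / n_comparisons
  res$significant <- res$p < thr
  res$significant_strict <- res$p < strict
  list(results = res, threshold = thr, strict_threshold = strict)
}
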