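## Genome-wide sliding-window weighted burden scan, permutation-calibrated
## effective number of tests, and the repeat-masked secondary analysis.

window_sizes_default <- c(5000, 10000, 15000, 20000, 25000, 50000)

#' Enumerate sliding windows
#'
#' For each size, windows start at multiples of `size * step_fraction`
#' (half-overlapping by default) and are clipped at the chromosome end.
#' Spans are 1-based inclusive.
#'
#' @param genome named vector of chromosome lengths.
#' @param sizes window sizes in bp (default 5/10/15/20/25/50 kb).
#' @param step_fraction step as a fraction of the window size (default 0.5).
#' @return data.frame(chrom, start, end, size).
#' @export
enumerate_windows <- function(genome, sizes = window_sizes_default,
                              step_fraction = 0.5) {
  stopifnot(all(sizes > 0), step_fraction > 0)
  out <- list()
  for (size in sizes) {
    step <- max(1, round(size * step_fraction))
    for (ch in names(genome)) {
      L <- genome[[ch]]
      if (size >= L) {   # whole chromosome: a single clipped window
        out[[length(out) + 1]] <- data.frame(chrom = ch, start = 1,
                                             end = L, size = size)
        next
      }
      starts <- seq(1, max(1, L), by = step)
      ends <- pmin(starts + size - 1, L)
      out[[length(out) + 1]] <- data.frame(chrom = ch, start = starts,
                                           end = ends, size = size)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Sparse membership of analyzed variants in windows.
window_membership <- function(variants, variant_idx, windows) {
  vr <- GenomicRanges::GRanges(variants$chrom[variant_idx],
                               IRanges::IRanges(variants$pos[variant_idx],
                                                variants$pos[variant_idx]))
  wr <- GenomicRanges::GRanges(windows$chrom,
                               IRanges::IRanges(windows$start, windows$end))
  ov <- GenomicRanges::findOverlaps(vr, wr)
  Matrix::sparseMatrix(i = S4Vectors::queryHits(ov),
                       j = S4Vectors::subjectHits(ov), x = 1,
                       dims = c(length(variant_idx), nrow(windows)))
}

#' Sliding-window weighted burden scan
#'
#' Per-window beta(1,25)-weighted burden logistic test on the same variant
#' set and covariates as the annotation-state tests. Windows containing no
#' analyzed variant are dropped.
#'
#' @param genotypes samples x variants matrix (comparison samples).
#' @param variants variant table.
#' @param windows window table from [enumerate_windows()].
#' @param outcome binary outcome.
#' @param covariates covariate matrix (should already include the total
#'   weighted burden).
#' @param variant_idx analyzed variant set; default
#'   `select_analysis_variants(kind = "window")`.
#' @param weights per-variant weights over `variant_idx`; default
#'   beta(1,25) at the recomputed MAF.
#' @param chunk_size windows fitted per block (memory control).
#' @param max_windows optional cap: a seeded random subset of this many
#'   non-empty windows is fitted (the genomic-control lambda is invariant
#'   to such thinning; used by large synthetic diagnostics).
#' @param thin_seed seed for the thinning draw.
#' @return list(results: WindowResult data.frame, lambda_gc).
#' @export
window_burden_scan <- function(genotypes, variants, windows, outcome,
                               covariates = NULL, variant_idx = NULL,
                               weights = NULL, chunk_size = 2000L,
                               max_windows = Inf, thin_seed = 1) {
  if (is.null(variant_idx)) {
    variant_idx <- select_analysis_variants(variants, genotypes, "window")
    maf <- attr(variant_idx, "maf")
    weights <- beta_weight(pmax(maf[variant_idx], 1e-12))
  } else if (is.null(weights)) {
    maf <- allele_counts(genotypes)$maf
    weights <- beta_weight(pmax(maf[variant_idx], 1e-12))
  }
  y <- as_binary_outcome(outcome)
  X0 <- design_with_intercept(covariates, length(y))
  null_fit <- logit_irls(X0, y)
  member <- window_membership(variants, variant_idx, windows)
  n_var <- Matrix::colSums(member != 0)
  tested <- which(n_var >= 1)
  if (length(tested) > max_windows) {
    set.seed(thin_seed)
    tested <- sort(sample(tested, max_windows))
  }
  g <- genotypes[, variant_idx, drop = FALSE]
  rows <- vector("list", length(tested))
  pos <- 0L
  for (idx in chunk_indices(length(tested), chunk_size)) {
    wcols <- tested[idx]
    B <- as.matrix(g %*% (member[, wcols, drop = FALSE] * weights))
    for (k in seq_along(wcols)) {
      b <- B[, k]
      if (sd(b) == 0) {
        wt <- list(estimate = 0, se = NA_real_, p = NA_real_, flag = "degenerate")
      } else {
        wt <- wald_logistic(b / sd(b), y, X0, null_fit = null_fit)
      }
      pos <- pos + 1L
      rows[[pos]] <- c(wcols[k], wt$estimate, wt$se, wt$p,
                       as.numeric(wt$flag == "firth"),
                       as.numeric(wt$flag == "degenerate"))
    }
  }
  mat <- do.call(rbind, rows)
  wi <- mat[, 1]
  res <- data.frame(chrom = windows$chrom[wi], start = windows$start[wi],
                    end = windows$end[wi], size = windows$size[wi],
                    n_variants = n_var[wi], estimate = mat[, 2],
                    se = mat[, 3], p = mat[, 4],
                    direction = sign(mat[, 2]),
                    flag = ifelse(mat[, 6] > 0, "degenerate",
                                  ifelse(mat[, 5] > 0, "firth", "ok")),
                    stringsAsFactors = FALSE)
  ok <- res$flag != "degenerate" & !is.na(res$p)
  list(results = res, lambda_gc = lambda_gc(res$p[ok]))
}

#' Permutation estimate of the effective number of tests
#'
#' Outcome labels are permuted within deciles of the covariate-only fitted
#' linear predictor (so the permutation null preserves covariate
#' structure); each permutation re-runs the window scan and records the
#' minimum p-value. Treating the minimum of the scan as the minimum of
#' `n_eff` independent uniforms, `min p ~ Beta(1, n_eff)`, the ML estimate
#' is `n_eff = -n_perm / sum(log(1 - p_min))`, and the scan-wide
#' significance threshold is `0.05 / n_eff`.
#'
#' @param genotypes,variants,windows,outcome,covariates,variant_idx,weights
#'   as in [window_burden_scan()].
#' @param n_perm number of permutation replicates (>= 100; default 5000).
#' @param seed RNG seed for the permutations.
#' @return list(n_eff, threshold, min_p: the permuted minima).
#' @export
estimate_effective_tests <- function(genotypes, variants, windows, outcome,
                                     covariates = NULL, variant_idx = NULL,
                                     weights = NULL, n_perm = 5000, seed = 1) {
  if (n_perm < 100) stopf("n_perm < 100 gives an unstable Beta fit")
  set.seed(seed)
  y <- as_binary_outcome(outcome)
  X0 <- design_with_intercept(covariates, length(y))
  null_fit <- logit_irls(X0, y)
  eta <- drop(X0 %*% null_fit$coef)
  strata <- if (ncol(X0) > 1 && length(unique(eta)) > 10) {
    cut(eta, breaks = unique(quantile(eta, 0:10 / 10)), include.lowest = TRUE)
  } else factor(rep(1, length(y)))
  min_p <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    yp <- y
    for (s in levels(strata)) {
      i <- which(strata == s)
      yp[i] <- y[sample(i)]
    }
    scan <- window_burden_scan(genotypes, variants, windows, yp, covariates,
                               variant_idx = variant_idx, weights = weights)
    min_p[r] <- min(scan$results$p, na.rm = TRUE)
  }
  mp <- pmin(min_p, 1 - 1e-12)
  n_eff <- -n_perm / sum(log(1 - mp))
  list(n_eff = n_eff, threshold = 0.05 / n_eff, min_p = min_p)
}

#' Secondary analysis of one window
#'
#' For a target window: (1) burden test restricted to variants outside
#' repeat regions; (2) per-variant two-sided Fisher exact tests on allele
#' counts; (3) the window's variants partitioned at nominal Fisher p < 0.05
#' (strict), with the burden test re-run on each partition. All component
#' p-values are reported.
#'
#' @param window list or one-row data.frame with chrom, start, end
#'   (1-based inclusive).
#' @param genotypes,variants as elsewhere (comparison samples).
#' @param repeat_track repeat `interval_track` (multi-label) or NULL.
#' @param outcome binary outcome.
#' @param covariates covariate matrix.
#' @return list(full, nonrepeat, significant_subset, nonsignificant_subset:
#'   AssocResult rows (or NULL when a partition is empty, flagged in
#'   `notes`), fisher: per-variant Fisher table, notes).
#' @export
secondary_window_analysis <- function(window, genotypes, variants,
                                      repeat_track, outcome,
                                      covariates = NULL) {
  y <- as_binary_outcome(outcome)
  variant_idx <- select_analysis_variants(variants, genotypes, "window")
  maf <- attr(variant_idx, "maf")
  in_win <- variant_idx[variants$chrom[variant_idx] == window$chrom &
                          variants$pos[variant_idx] >= window$start &
                          variants$pos[variant_idx] <= window$end]
  if (length(in_win) == 0) stopf("no analyzed variants in window")
  w_all <- beta_weight(pmax(maf[in_win], 1e-12))
  X0 <- design_with_intercept(covariates, length(y))
  null_fit <- logit_irls(X0, y)
  notes <- character(0)
  btest <- function(idx, w, unit) {
    if (length(idx) == 0) return(NULL)
    b <- as.numeric(genotypes[, idx, drop = FALSE] %*% w)
    burden_logistic_test(b, y, covariates, unit = unit, kind = "window",
                         n_variants = length(idx), null_fit = null_fit)
  }
  full <- btest(in_win, w_all, "full_window")
  in_repeat <- rep(FALSE, length(in_win))
  if (!is.null(repeat_track) && nrow(repeat_track$intervals) > 0) {
    vr <- GenomicRanges::GRanges(variants$chrom[in_win],
                                 IRanges::IRanges(variants$pos[in_win],
                                                  variants$pos[in_win]))
    in_repeat <- IRanges::overlapsAny(vr, track_to_granges(repeat_track))
  }
  nonrep <- btest(in_win[!in_repeat], w_all[!in_repeat], "nonrepeat_window")
  if (is.null(nonrep)) notes <- c(notes, "no non-repeat variants")
  ## per-variant allele-count Fisher tests
  y1 <- y == 1
  fisher_p <- vapply(seq_along(in_win), function(k) {
    g <- as.numeric(genotypes[, in_win[k]])
    a <- sum(g[y1]); b <- 2 * sum(y1) - a
    cc <- sum(g[!y1]); d <- 2 * sum(!y1) - cc
    fisher_exact_2x2(a, b, cc, d)
  }, numeric(1))
  sig <- fisher_p < 0.05   # strict: p == 0.05 goes to the non-significant side
  sig_res <- btest(in_win[sig], w_all[sig], "fisher_significant_subset")
  if (is.null(sig_res)) notes <- c(notes, "significant partition empty")
  nonsig_res <- btest(in_win[!sig], w_all[!sig], "fisher_nonsignificant_subset")
  if (is.null(nonsig_res)) notes <- c(notes, "non-significant partition empty")
  list(full = full, nonrepeat = nonrep, significant_subset = sig_res,
       nonsignificant_subset = nonsig_res,
       fisher = data.frame(chrom = variants$chrom[in_win],
                           pos = variants$pos[in_win], p = fisher_p,
                           in_repeat = in_repeat),
       notes = notes)
}
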