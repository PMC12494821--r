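## Sample-level QC: hard filters, KING-robust kinship, relatedness pruning,
## LD pruning and genetic principal components.

#' Apply sample-level hard filters
#'
#' Excludes samples with estimated DNA contamination above 5%, with fewer
#' than 98% of sites at sequencing depth >= 10, or whose reported sex
#' disagrees with the genetic sex field. Reason codes are recorded per
#' excluded sample.
#'
#' @param samples sample table with `contamination`, `depth10_completeness`,
#'   `sex`, `reported_sex` columns.
#' @param max_contamination,min_depth10 filter thresholds.
#' @return list(kept, excluded) where excluded carries a `reason` column
#'   (comma-joined codes among contamination, coverage, sex_mismatch).
#' @export
filter_samples <- function(samples, max_contamination = 0.05,
                           min_depth10 = 0.98) {
  for (col in c("contamination", "depth10_completeness", "sex", "reported_sex")) {
    if (is.null(samples[[col]]))
      stopf("filter_samples: metric '%s' missing", col)
    bad <- which(is.na(samples[[col]]))
    if (length(bad) > 0)
      stopf("sample %s is missing metric '%s'", samples$sample_id[bad[1]], col)
  }
  reasons <- mapply(function(cont, d10, sx, rsx) {
    r <- character(0)
    if (cont > max_contamination) r <- c(r, "contamination")
    if (d10 < min_depth10) r <- c(r, "coverage")
    if (sx != rsx) r <- c(r, "sex_mismatch")
    paste(r, collapse = ",")
  }, samples$contamination, samples$depth10_completeness,
     samples$sex, samples$reported_sex)
  drop <- reasons != ""
  excluded <- samples[drop, , drop = FALSE]
  excluded$reason <- reasons[drop]
  list(kept = samples[!drop, , drop = FALSE], excluded = excluded)
}

#' KING-robust pairwise kinship
#'
#' Within-pair estimator
#' `phi = (N_Aa,Aa - 2 N_AA,aa) / (N_Aa,i + N_Aa,j)`, where `N_Aa,Aa`
#' counts sites at which both members are heterozygous, `N_AA,aa` counts
#' opposite homozygotes, and the denominator sums the two members'
#' heterozygote counts. Identical genomes give exactly 0.5; unrelated pairs
#' scatter around 0. Computed for all pairs via indicator-matrix
#' cross-products; restrict `genotypes` to common variants (MAF > 0.05)
#' before calling.
#'
#' @param genotypes samples x variants count matrix on common variants.
#' @param min_report if non-NULL, only pairs with `phi > min_report` are
#'   returned (keeps the table small at cohort scale).
#' @return data.frame(id1, id2, phi); pairs with zero heterozygotes in both
#'   members get `phi = NA`.
#' @export
estimate_kinship <- function(genotypes, min_report = NULL) {
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  if (m < 1) stopf("estimate_kinship: no variants")
  ids <- rownames(genotypes) %||% paste0("S", seq_len(n))
  ## accumulate the pair-count matrices over variant blocks so that only
  ## n x n accumulators and one n x block indicator live at a time
  n_hh <- matrix(0, n, n)
  n_opp <- matrix(0, n, n)
  het_count <- numeric(n)
  for (idx in chunk_indices(m, 2000L)) {
    g <- as.matrix(genotypes[, idx, drop = FALSE])
    het <- (g == 1) * 1
    n_hh <- n_hh + tcrossprod(het)
    n_opp <- n_opp + tcrossprod((g == 0) * 1, (g == 2) * 1)
    het_count <- het_count + rowSums(het)
    rm(g, het)
  }
  n_opp <- n_opp + t(n_opp)
  denom <- outer(het_count, het_count, "+")
  phi <- (n_hh - 2 * n_opp) / denom
  rm(n_hh, n_opp)
  phi[denom == 0] <- NA
  rm(denom); gc(FALSE)
  ## select pairs on the numeric matrix before materializing the table
  pick <- upper.tri(phi)
  if (!is.null(min_report)) pick <- pick & !is.na(phi) & phi > min_report
  ut <- which(pick, arr.ind = TRUE)
  rm(pick)
  out <- data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
                    phi = phi[ut], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Prune related samples to an unrelated set
#'
#' Removes one member of every pair with kinship above the threshold
#' (default 0.0409, third-degree or closer). Duplicate-level pairs
#' (`phi > dup_threshold`) are resolved first with cohort priority: an
#' internal sample is retained over an external one. Remaining related
#' groups are resolved by seeded-random greedy removal of the
#' highest-degree node until no edge remains, which also handles chains and
#' groups larger than two.
#'
#' @param kinship data.frame(id1, id2, phi) (complete over the samples).
#' @param samples sample table (for cohort priority); NULL disables it.
#' @param threshold kinship above which a pair is "related".
#' @param dup_threshold kinship above which a pair is a duplicate/MZ pair.
#' @param seed seed for the random tie-breaking.
#' @return character vector of excluded sample ids; the retained set is
#'   everything else.
#' @export
prune_related <- function(kinship, samples = NULL, threshold = 0.0409,
                          dup_threshold = 0.354, seed = 1) {
  set.seed(seed)
  edges <- kinship[!is.na(kinship$phi) & kinship$phi > threshold, , drop = FALSE]
  removed <- character(0)
  is_external <- function(id) {
    if (is.null(samples)) return(rep(FALSE, length(id)))
    samples$cohort[match(id, samples$sample_id)] == "external_control"
  }
  ## duplicates first, external member dropped preferentially
  dup <- edges[edges$phi > dup_threshold, , drop = FALSE]
  for (k in seq_len(nrow(dup))) {
    a <- dup$id1[k]; b <- dup$id2[k]
    if (a %in% removed || b %in% removed) next
    ext <- c(is_external(a), is_external(b))
    drop_id <- if (xor(ext[1], ext[2])) c(a, b)[ext] else sample(c(a, b), 1)
    removed <- c(removed, drop_id)
  }
  repeat {
    live <- !(edges$id1 %in% removed) & !(edges$id2 %in% removed)
    e <- edges[live, , drop = FALSE]
    if (nrow(e) == 0) break
    deg <- table(c(e$id1, e$id2))
    top <- names(deg)[deg == max(deg)]
    removed <- c(removed, if (length(top) == 1) top else sample(top, 1))
  }
  removed
}

#' Greedy LD pruning
#'
#' PLINK-style `--indep-pairwise` pruning: only variants with MAF above
#' `maf_min` are considered; scanning left to right, the later variant of
#' any pair within `window_bp` whose squared genotype correlation exceeds
#' `r2_max` is dropped. The retained set has no within-window pair above
#' the threshold.
#'
#' @param genotypes samples x variants matrix.
#' @param variants variant table (chrom, pos) aligned to columns.
#' @param window_bp physical window size in bp (default 500000).
#' @param step advance in variants between window evaluations (kept for
#'   interface compatibility; the incremental scan is equivalent to the
#'   smallest step).
#' @param r2_max squared-correlation threshold (default 0.2).
#' @param maf_min MAF floor for eligibility (default 0.05).
#' @return integer indices (into the original columns) of retained variants.
#' @export
ld_prune <- function(genotypes, variants, window_bp = 500000, step = 5,
                     r2_max = 0.2, maf_min = 0.05) {
  ac <- allele_counts(genotypes)
  cand <- which(ac$maf > maf_min)
  if (length(cand) == 0) return(integer(0))
  ord <- cand[order(variants$chrom[cand], variants$pos[cand])]
  n <- nrow(genotypes)
  x <- as.matrix(genotypes[, ord, drop = FALSE])
  sds <- apply(x, 2, sd)
  ord <- ord[sds > 0]; x <- x[, sds > 0, drop = FALSE]
  m <- length(ord)
  if (m == 0) return(integer(0))
  x <- scale(x)
  chrom <- variants$chrom[ord]; pos <- variants$pos[ord]
  ## precompute, blockwise (BLAS), the within-window pairs with r^2 above
  ## threshold; the greedy scan then drops the later member of each such
  ## pair whose earlier member is still kept
  edge_from <- list(); edge_to <- list(); ne <- 0L
  blocks <- chunk_indices(m, 512L)
  for (bi in seq_along(blocks)) {
    b1 <- blocks[[bi]]
    for (bj in bi:length(blocks)) {
      b2 <- blocks[[bj]]
      ## skip block pairs entirely out of physical reach
      if (chrom[b2[1]] == chrom[b1[length(b1)]] &&
          pos[b2[1]] - pos[b1[length(b1)]] > window_bp) break
      r <- crossprod(x[, b1, drop = FALSE], x[, b2, drop = FALSE]) / (n - 1)
      hits <- which(r^2 > r2_max, arr.ind = TRUE)
      if (nrow(hits) > 0) {
        i1 <- b1[hits[, 1]]; i2 <- b2[hits[, 2]]
        keep_pair <- i1 < i2 & chrom[i1] == chrom[i2] &
          (pos[i2] - pos[i1]) <= window_bp
        if (any(keep_pair)) {
          ne <- ne + 1L
          edge_from[[ne]] <- i1[keep_pair]
          edge_to[[ne]] <- i2[keep_pair]
        }
      }
    }
  }
  kept_flag <- rep(TRUE, m)
  if (ne > 0) {
    ef <- unlist(edge_from); et <- unlist(edge_to)
    o <- order(et, ef)
    ef <- ef[o]; et <- et[o]
    for (k in seq_along(et)) {
      if (kept_flag[ef[k]] && kept_flag[et[k]]) kept_flag[et[k]] <- FALSE
    }
  }
  sort(ord[kept_flag])
}

#' Genetic principal components
#'
#' PCs of the centered, variance-standardized genotype matrix on the pruned
#' variant set. Signs follow a fixed convention (the largest-magnitude
#' loading of each component is positive). The exact eigendecomposition is
#' used at moderate sample counts; for larger inputs a randomized subspace
#' solver (two power iterations) is used and flagged in the result.
#'
#' @param genotypes samples x variants matrix restricted to pruned variants.
#' @param k number of components (default 10).
#' @param method "auto", "exact" or "randomized".
#' @param seed seed for the randomized solver.
#' @return list(scores: samples x k matrix, sdev, method).
#' @export
compute_genetic_pcs <- function(genotypes, k = 10, method = "auto", seed = 1) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  if (m == 0) stopf("compute_genetic_pcs: empty variant set")
  p_hat <- Matrix::colMeans(genotypes) / 2
  keep <- which(p_hat > 0 & p_hat < 1)
  g <- genotypes[, keep, drop = FALSE]
  p_hat <- p_hat[keep]
  if (method == "auto") method <- if (n <= 2500) "exact" else "randomized"
  k_eff <- min(k, n - 1, length(keep))
  if (k_eff < k) warnf("rank supports only %d PCs (requested %d)", k_eff, k)
  center <- 2 * p_hat
  scale_ <- sqrt(pmax(2 * p_hat * (1 - p_hat), 1e-12))
  if (method == "exact") {
    x <- sweep(sweep(as.matrix(g), 2, center), 2, scale_, "/")
    pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = k_eff)
    scores <- pc$x[, seq_len(k_eff), drop = FALSE]
    sdev <- pc$sdev[seq_len(k_eff)]
  } else {
    rs <- randomized_pca(g, center, scale_, k_eff, seed)
    scores <- rs$scores; sdev <- rs$sdev
  }
  ## fixed sign convention: largest-|score| entry positive
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- rownames(genotypes)
  list(scores = scores, sdev = sdev, method = method)
}

## Randomized range-finder PCA on the implicitly standardized genotype
## matrix; never forms the dense standardized matrix.
randomized_pca <- function(g, center, scale_, k, seed, oversample = 10L,
                           power_iter = 2L) {
  set.seed(seed)
  n <- nrow(g); m <- ncol(g)
  l <- min(m, k + oversample)
  std_mult <- function(mat) {            # X %*% mat with X = (g - center)/scale
    gm <- as.matrix(g %*% (mat / scale_))
    sweep(gm, 2, drop(crossprod(center / scale_, mat)))
  }
  std_tmult <- function(mat) {           # t(X) %*% mat
    (as.matrix(Matrix::crossprod(g, mat)) - outer(center, colSums(mat))) / scale_
  }
  q <- qr.Q(qr(std_mult(matrix(rnorm(m * l), m, l))))
  for (i in seq_len(power_iter))
    q <- qr.Q(qr(std_mult(std_tmult(q))))
  ## project: B = t(Q) X, computed as t( t(X) Q )
  b <- t(std_tmult(q))
  sv <- svd(b, nu = k, nv = 0)
  scores <- (q %*% sv$u) %*% diag(sv$d[seq_len(k)], k, k)
  list(scores = scores, sdev = sv$d[seq_len(k)] / sqrt(max(1, n - 1)))
}
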