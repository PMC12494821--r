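## Variant annotation joining, beta(MAF,1,25) weighting, variant selection
## and per-sample category burden construction.

#' Beta(1,25) rarity weight
#'
#' The Beta(1, 25) density evaluated at the minor allele frequency:
#' `w = 25 (1 - maf)^24`, strictly decreasing in MAF, approaching 25 as
#' MAF approaches 0. This is the standard rare-variant upweighting used by
#' whole-genome sliding-window burden frameworks.
#'
#' @param maf minor allele frequency, strictly inside (0, 1).
#' @return numeric weight vector.
#' @export
beta_weight <- function(maf) {
  if (any(maf <= 0 | maf >= 1)) stopf("beta_weight: maf must lie in (0,1)")
  stats::dbeta(maf, 1, 25)
}

#' Join interval-track annotations onto variants
#'
#' Assigns each variant its annotation state (single-label point lookup at
#' the 1-based position; indels are assigned by their VCF pos), the set of
#' repeat classes it overlaps (multi-label), an excluded-region flag, and a
#' gene id (first overlapping gene).
#'
#' @param variants variant table (chrom, pos).
#' @param tracks list with `state`, `repeats`, `excluded`, `gene`
#'   interval tracks (any may be NULL).
#' @return list(variants, repeat_membership): variants gains `state`,
#'   `repeat_classes` (list column), `excluded`, `gene` columns;
#'   `repeat_membership` is a sparse logical variants x classes matrix with
#'   an `overall` column flagging any-repeat overlap.
#' @export
annotate_variants <- function(variants, tracks) {
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  m <- nrow(variants)
  if (!is.null(tracks$state)) {
    gr <- track_to_granges(tracks$state)
    hit <- GenomicRanges::findOverlaps(vr, gr, select = "first")
    variants$state <- ifelse(is.na(hit), NA_character_,
                             gr$label[ifelse(is.na(hit), 1L, hit)])
  }
  repeat_membership <- NULL
  if (!is.null(tracks$repeats)) {
    gr <- track_to_granges(tracks$repeats)
    ov <- GenomicRanges::findOverlaps(vr, gr)
    classes <- sort(unique(tracks$repeats$intervals$label))
    cls_idx <- match(gr$label[S4Vectors::subjectHits(ov)], classes)
    pairs <- unique(cbind(S4Vectors::queryHits(ov), cls_idx))
    repeat_membership <- Matrix::sparseMatrix(
      i = pairs[, 1], j = pairs[, 2], x = TRUE,
      dims = c(m, length(classes) + 1L),
      dimnames = list(NULL, c(classes, "overall")))
    any_rep <- unique(pairs[, 1])
    if (length(any_rep) > 0)
      repeat_membership[any_rep, length(classes) + 1L] <- TRUE
    variants$repeat_classes <- unname(split(classes[cls_idx],
                                            factor(S4Vectors::queryHits(ov),
                                                   levels = seq_len(m))))
    variants$repeat_classes <- lapply(variants$repeat_classes, unique)
  }
  if (!is.null(tracks$excluded)) {
    gr <- track_to_granges(tracks$excluded)
    variants$excluded <- IRanges::overlapsAny(vr, gr)
  } else if (is.null(variants$excluded)) variants$excluded <- FALSE
  if (!is.null(tracks$gene)) {
    gr <- track_to_granges(tracks$gene)
    hit <- GenomicRanges::findOverlaps(vr, gr, select = "first")
    variants$gene <- ifelse(is.na(hit), NA_character_,
                            gr$label[ifelse(is.na(hit), 1L, hit)])
  }
  list(variants = variants, repeat_membership = repeat_membership)
}

#' Select the analysis variant set for a given test family
#'
#' * `kind = "state"` (also used for repeat and window tests): SNVs only,
#'   MAF strictly below 0.05 (computed on the analysis sample set), MAC > 0,
#'   not overlapping the exclusion list.
#' * `kind = "singleton_ptv"`: PTVs whose minor allele count is exactly 1
#'   among the supplied (unrelated) analysis samples.
#' * `kind = "ptv_1pct"`: PTVs with MAF <= 0.01 (sensitivity mode).
#'
#' MAF/MAC are recomputed on `genotypes` (the comparison's sample subset),
#' not taken from a frozen genome-wide table.
#'
#' @param variants annotated variant table.
#' @param genotypes genotype matrix restricted to the analysis samples.
#' @param kind one of "state", "repeat", "window", "singleton_ptv",
#'   "ptv_1pct".
#' @return integer vector of selected variant column indices; the recomputed
#'   `maf` is attached as attribute `"maf"` (aligned to all variants).
#' @export
select_analysis_variants <- function(variants, genotypes,
                                     kind = c("state", "repeat", "window",
                                              "singleton_ptv", "ptv_1pct")) {
  kind <- match.arg(kind)
  ac <- allele_counts(genotypes)
  excluded <- variants$excluded %||% rep(FALSE, nrow(variants))
  sel <- switch(kind,
    state = , "repeat" = , window =
      which(variants$is_snv & ac$maf < 0.05 & ac$mac > 0 & !excluded),
    singleton_ptv =
      which((variants$is_ptv %||% rep(FALSE, nrow(variants))) & ac$mac == 1),
    ptv_1pct =
      which((variants$is_ptv %||% rep(FALSE, nrow(variants))) &
              ac$maf <= 0.01 & ac$mac > 0))
  attr(sel, "maf") <- ac$maf
  attr(sel, "mac") <- ac$mac
  sel
}

#' Build a samples-by-categories weighted burden matrix
#'
#' `B[s, c] = sum over variants v in category c of w(v) * g[s, v]`, where
#' `g` is the non-reference allele count. The weight argument is the minor
#' allele frequency density weight even when the minor allele is the
#' reference allele; the summed count stays the non-reference count (a
#' documented asymmetry matching the predictor definition). A per-sample
#' total over all analyzed variants is attached for use as the burden-test
#' covariate.
#'
#' @param genotypes samples x variants matrix (all variants).
#' @param variant_idx columns making up the analyzed set.
#' @param grouping either a character/factor vector over `variant_idx`
#'   (single-label categories; NA drops the variant) or a logical/numeric
#'   membership matrix with rows aligned to `variant_idx` (multi-label).
#' @param weights per-variant weights aligned to `variant_idx`; `NULL`
#'   means unweighted (weight 1, as in PTV count tests).
#' @return list(burden: dense samples x categories matrix, total: per-sample
#'   total weighted burden over the analyzed set, n_variants: per-category
#'   variant counts).
#' @export
build_burden_matrix <- function(genotypes, variant_idx, grouping,
                                weights = NULL) {
  g <- genotypes[, variant_idx, drop = FALSE]
  k <- length(variant_idx)
  w <- weights %||% rep(1, k)
  stopifnot(length(w) == k)
  if (is.matrix(grouping) || methods::is(grouping, "Matrix")) {
    stopifnot(nrow(grouping) == k)
    member <- methods::as(grouping, "CsparseMatrix") * 1
    cats <- colnames(member) %||% paste0("cat", seq_len(ncol(member)))
  } else {
    stopifnot(length(grouping) == k)
    grouping <- as.character(grouping)
    cats <- sort(unique(grouping[!is.na(grouping)]))
    keep <- which(!is.na(grouping))
    member <- Matrix::sparseMatrix(i = keep, j = match(grouping[keep], cats),
                                   x = 1, dims = c(k, length(cats)),
                                   dimnames = list(NULL, cats))
  }
  wm <- member * w
  burden <- as.matrix(g %*% wm)
  colnames(burden) <- cats
  rownames(burden) <- rownames(genotypes)
  n_var <- Matrix::colSums(member != 0)
  list(burden = burden,
       total = as.numeric(g %*% w),
       n_variants = setNames(as.numeric(n_var), cats))
}
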