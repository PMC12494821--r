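## End-to-end orchestration of the seven comparison groups:
## three case groups (BD, SZ, BD+SZ) against internal controls and against
## internal+external controls, plus the internal-vs-external control
## comparison used as the batch-effect diagnostic.

comparison_defs <- function() {
  list(
    cc_ext   = list(case = "external_control",
                    control = "internal_control", internal_only = FALSE),
    BD_int   = list(case = "internal_case_BD",
                    control = "internal_control", internal_only = TRUE),
    SZ_int   = list(case = "internal_case_SZ",
                    control = "internal_control", internal_only = TRUE),
    BDSZ_int = list(case = c("internal_case_BD", "internal_case_SZ"),
                    control = "internal_control", internal_only = TRUE),
    BD_all   = list(case = "internal_case_BD",
                    control = c("internal_control", "external_control"),
                    internal_only = FALSE),
    SZ_all   = list(case = "internal_case_SZ",
                    control = c("internal_control", "external_control"),
                    internal_only = FALSE),
    BDSZ_all = list(case = c("internal_case_BD", "internal_case_SZ"),
                    control = c("internal_control", "external_control"),
                    internal_only = FALSE))
}

#' Sample QC, relatedness pruning and covariate construction
#'
#' Runs the hard sample filters, KING kinship on a (thinned) common-variant
#' set with relatedness pruning at 0.0409, LD pruning and genetic PCs, and
#' metadata PCs. Returns everything [run_comparisons()] needs.
#'
#' @param cohort a [generate_cohort()] result (or equivalently structured
#'   real data).
#' @param k_genetic_pcs,k_metadata_pcs numbers of components.
#' @param max_kinship_variants,max_pc_variants caps on the common-variant
#'   subsets used for kinship and PCs (seeded thinning; caps keep the
#'   all-pairs kinship and PCA tractable at cohort scale).
#' @param seed RNG seed for thinning/pruning tie-breaks.
#' @return list(samples, unrelated_ids, excluded, kinship, genetic_pcs,
#'   metadata_pcs, counts).
#' @export
run_sample_qc <- function(cohort, k_genetic_pcs = 10, k_metadata_pcs = 4,
                          max_kinship_variants = 10000, max_pc_variants = 8000,
                          seed = 1) {
  flt <- filter_samples(cohort$samples)
  kept <- flt$kept
  g <- cohort$genotypes[kept$sample_id, , drop = FALSE]
  ac <- allele_counts(g)
  common <- which(ac$maf > 0.05)
  set.seed(derive_seed(seed, 21))
  kin_set <- if (length(common) > max_kinship_variants)
    sort(sample(common, max_kinship_variants)) else common
  kinship <- estimate_kinship(g[, kin_set, drop = FALSE], min_report = 0.02)
  gc(FALSE)
  removed <- prune_related(kinship, samples = kept,
                           seed = derive_seed(seed, 22))
  unrelated <- setdiff(kept$sample_id, removed)
  pc_cand <- if (length(common) > max_pc_variants)
    sort(sample(common, max_pc_variants)) else common
  pruned <- pc_cand[ld_prune(g[, pc_cand, drop = FALSE],
                             cohort$variants[pc_cand, , drop = FALSE])]
  gpc <- compute_genetic_pcs(g[unrelated, pruned, drop = FALSE],
                             k = k_genetic_pcs,
                             seed = derive_seed(seed, 23))
  mpc <- compute_metadata_pcs(metric_matrix(kept), k = k_metadata_pcs)
  counts <- list(n_input = nrow(cohort$samples), n_filtered = nrow(kept),
                 n_related_removed = length(removed),
                 n_unrelated = length(unrelated),
                 n_common = length(common), n_pruned = length(pruned))
  list(samples = kept, unrelated_ids = unrelated, excluded = flt$excluded,
       kinship = kinship, genetic_pcs = gpc$scores,
       metadata_pcs = mpc$scores, counts = counts)
}

#' Run the comparison groups end to end
#'
#' For each requested comparison, recomputes the analysis variant set
#' (SNVs, MAF < 0.05 in the comparison's samples, exclusion list applied),
#' builds beta(1,25)-weighted burden matrices, and runs the requested
#' analyses (annotation-state scan, repeat-class scan, sliding-window scan,
#' single-variant GWAS) under the base and/or base+metadata-PC covariate
#' models. Emits a lambda_GC matrix in the style of an analysis-by-
#' comparison diagnostic table.
#'
#' @param cohort a [generate_cohort()] result.
#' @param qc result of [run_sample_qc()] (computed if NULL).
#' @param comparisons subset of the seven group names (see package docs):
#'   cc_ext, BD_int, SZ_int, BDSZ_int, BD_all, SZ_all, BDSZ_all.
#' @param analyses subset of c("state", "repeat", "window", "gwas").
#' @param models subset of c("base", "base+metaPCs"); GWAS always runs the
#'   base model only, matching its use as a covariate-light diagnostic.
#' @param window_sizes sliding-window sizes (bp).
#' @param max_windows optional cap on fitted windows per scan (seeded
#'   thinning; lambda-invariant).
#' @param mac_min GWAS minor-allele-count filter (strict >).
#' @param gwas_max_tests optional cap on tested GWAS variants (seeded
#'   thinning; lambda-invariant).
#' @param seed RNG seed (QC thinning).
#' @return list(qc, comparisons = per-comparison results, lambda_table).
#' @export
run_comparisons <- function(cohort, qc = NULL,
                            comparisons = names(comparison_defs()),
                            analyses = c("state", "repeat", "window", "gwas"),
                            models = c("base", "base+metaPCs"),
                            window_sizes = window_sizes_default,
                            max_windows = Inf,
                            mac_min = 20, gwas_max_tests = Inf, seed = 1) {
  defs <- comparison_defs()
  bad <- setdiff(comparisons, names(defs))
  if (length(bad) > 0) stopf("unknown comparison(s): %s", paste(bad, collapse = ", "))
  if (is.null(qc)) qc <- run_sample_qc(cohort, seed = seed)
  windows <- if ("window" %in% analyses)
    enumerate_windows(cohort$truth$config$genome %||%
                        infer_genome(cohort$variants), sizes = window_sizes)
  lambda_rows <- list()
  out <- list()
  for (cmp in comparisons) {
    def <- defs[[cmp]]
    samples <- qc$samples[qc$samples$sample_id %in% qc$unrelated_ids &
                            qc$samples$cohort %in% c(def$case, def$control), ,
                          drop = FALSE]
    if (length(unique(samples$cohort %in% def$case)) < 2) {
      stopf("comparison %s: missing a group after QC", cmp)
    }
    y <- as.numeric(samples$cohort %in% def$case)
    g <- cohort$genotypes[samples$sample_id, , drop = FALSE]
    sel <- select_analysis_variants(cohort$variants, g, "state")
    maf <- attr(sel, "maf")
    w <- beta_weight(pmax(maf[sel], 1e-12))
    total <- as.numeric(g[, sel, drop = FALSE] %*% w)
    gpcs <- qc$genetic_pcs[samples$sample_id, , drop = FALSE]
    mpcs <- qc$metadata_pcs[samples$sample_id, , drop = FALSE]
    covs <- list(
      "base" = build_covariates(samples, gpcs, total,
                                include_batch = def$internal_only),
      "base+metaPCs" = build_covariates(samples, gpcs, total, mpcs,
                                        include_batch = def$internal_only))
    res <- list(n_case = sum(y), n_control = sum(1 - y),
                n_variants_analyzed = length(sel))
    add_lambda <- function(analysis, model, lam) {
      lambda_rows[[length(lambda_rows) + 1]] <<-
        data.frame(comparison = cmp, analysis = analysis, model = model,
                   lambda = lam)
    }
    if ("state" %in% analyses) {
      bm <- build_burden_matrix(g, sel, cohort$variants$state[sel], w)
      for (mdl in models) {
        scan <- run_category_scan(bm, y, covs[[mdl]], kind = "state",
                                  model = mdl)
        res[[paste0("state_", mdl)]] <- scan
        add_lambda("state", mdl, scan$lambda_gc)
      }
    }
    if ("repeat" %in% analyses && !is.null(cohort$repeat_membership)) {
      bm <- build_burden_matrix(g, sel,
                                cohort$repeat_membership[sel, , drop = FALSE], w)
      for (mdl in models) {
        scan <- run_category_scan(bm, y, covs[[mdl]], kind = "repeat",
                                  model = mdl)
        res[[paste0("repeat_", mdl)]] <- scan
        add_lambda("repeat", mdl, scan$lambda_gc)
      }
    }
    if ("window" %in% analyses) {
      for (mdl in models) {
        scan <- window_burden_scan(g, cohort$variants, windows, y,
                                   covs[[mdl]], variant_idx = sel, weights = w,
                                   max_windows = max_windows, thin_seed = seed)
        res[[paste0("window_", mdl)]] <- scan
        add_lambda("window", mdl, scan$lambda_gc)
      }
    }
    if ("gwas" %in% analyses) {
      gw <- run_gwas(g, cohort$variants, y, covs[["base"]], mac_min = mac_min,
                     max_tests = gwas_max_tests, seed = seed)
      res$gwas <- gw
      add_lambda("gwas", "base", gw$lambda_gc)
    }
    out[[cmp]] <- res
  }
  list(qc = qc, comparisons = out,
       lambda_table = do.call(rbind, lambda_rows))
}

infer_genome <- function(variants) {
  tapply(variants$pos, variants$chrom, max) * 1.02
}

#' One batch-effect diagnostic replicate
#'
#' Generates a synthetic cohort at the given seed, runs sample QC and the
#' requested comparisons/analyses, and returns the lambda table plus the
#' per-comparison scan results. This is the driver behind the
#' inflation-diagnostic experiments: run it over several seeds and average
#' the lambdas (a single 200-test genomic-control lambda has sampling SD
#' of roughly 0.17 even under perfect calibration).
#'
#' @param seed generator seed (QC derives its own streams from it).
#' @param config cohort configuration; defaults to the study conditions.
#' The state scans run for every requested comparison; the heavier window
#' and GWAS scans run only for the comparisons named in
#' `window_comparisons` / `gwas_comparisons` (empty vectors skip them),
#' with lambda-invariant seeded thinning to bound runtime.
#'
#' @param comparisons,models passed to [run_comparisons()] for the state
#'   scans.
#' @param window_comparisons,gwas_comparisons comparisons for which the
#'   window scan / GWAS are also run.
#' @param max_windows,gwas_max_tests thinning caps for the heavy scans.
#' @return list(lambda_table, comparisons, qc_counts).
#' @export
batch_effect_diagnostic <- function(seed,
                                    config = cohort_config(seed = seed),
                                    comparisons = c("cc_ext", "BD_int",
                                                    "SZ_int", "BDSZ_int"),
                                    models = c("base", "base+metaPCs"),
                                    window_comparisons = character(0),
                                    gwas_comparisons = character(0),
                                    max_windows = 8000,
                                    gwas_max_tests = 6000) {
  config$seed <- seed
  cohort <- generate_cohort(config)
  qc <- run_sample_qc(cohort, seed = seed)
  gc(FALSE)
  rc <- run_comparisons(cohort, qc = qc, comparisons = comparisons,
                        analyses = "state", models = models, seed = seed)
  lambda_table <- rc$lambda_table
  out <- rc$comparisons
  if (length(window_comparisons) > 0) {
    rw <- run_comparisons(cohort, qc = qc, comparisons = window_comparisons,
                          analyses = "window", models = models,
                          max_windows = max_windows, seed = seed)
    lambda_table <- rbind(lambda_table, rw$lambda_table)
    for (nm in names(rw$comparisons))
      out[[nm]] <- utils::modifyList(out[[nm]] %||% list(),
                                     rw$comparisons[[nm]])
  }
  if (length(gwas_comparisons) > 0) {
    rg <- run_comparisons(cohort, qc = qc, comparisons = gwas_comparisons,
                          analyses = "gwas", gwas_max_tests = gwas_max_tests,
                          seed = seed)
    lambda_table <- rbind(lambda_table, rg$lambda_table)
    for (nm in names(rg$comparisons))
      out[[nm]] <- utils::modifyList(out[[nm]] %||% list(),
                                     rg$comparisons[[nm]])
  }
  list(lambda_table = lambda_table, comparisons = out,
       qc_counts = qc$counts)
}

#' One repeat-class artifact recovery replicate
#'
#' Generates a two-cohort control-only dataset with depth-differential
#' calling, scans the 22 repeat classes with and without metadata PCs, and
#' returns the SINE-class test under both models. Covariates (genetic PCs,
#' total weighted burden, metadata PCs) are built directly; no relatives
#' are spiked at this scale.
#'
#' @param seed replicate seed.
#' @param n_internal,n_external control-cohort sizes.
#' @param n_variants,genome generator scale.
#' @return list(or_base, p_base, or_meta, p_meta, lambda_base, results).
#' @export
sine_recovery_run <- function(seed, n_internal = 900, n_external = 1800,
                              n_variants = 8000,
                              genome = c(chr1 = 3e6, chr2 = 3e6)) {
  cfg <- cohort_config(
    n = c(internal_case_BD = 0, internal_case_SZ = 0,
          internal_control = n_internal, external_control = n_external),
    genome = genome, n_variants = n_variants,
    relatedness = list(n_dup = 0, n_po = 0), seed = seed)
  co <- generate_cohort(cfg)
  g <- co$genotypes
  samples <- co$samples
  y <- as.numeric(samples$cohort == "external_control")
  sel <- select_analysis_variants(co$variants, g, "repeat")
  maf <- attr(sel, "maf")
  w <- beta_weight(pmax(maf[sel], 1e-12))
  total <- as.numeric(g[, sel, drop = FALSE] %*% w)
  ac <- allele_counts(g)
  common <- which(ac$maf > 0.05)
  set.seed(derive_seed(seed, 41))
  pc_cand <- sort(sample(common, min(3000, length(common))))
  gpc <- compute_genetic_pcs(g[, pc_cand, drop = FALSE], k = 10,
                             seed = derive_seed(seed, 42))
  mpc <- compute_metadata_pcs(metric_matrix(samples), k = 4)
  bm <- build_burden_matrix(g, sel, co$repeat_membership[sel, , drop = FALSE],
                            w)
  base <- run_category_scan(bm, y,
                            build_covariates(samples, gpc$scores, total),
                            kind = "repeat", model = "base")
  meta <- run_category_scan(bm, y,
                            build_covariates(samples, gpc$scores, total,
                                             mpc$scores),
                            kind = "repeat", model = "base+metaPCs")
  sb <- base$results[base$results$unit == "SINE", ]
  sm <- meta$results[meta$results$unit == "SINE", ]
  list(or_base = sb$or, p_base = sb$p, or_meta = sm$or, p_meta = sm$p,
       lambda_base = base$lambda_gc,
       results = list(base = base$results, meta = meta$results))
}
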