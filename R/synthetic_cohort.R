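## Synthetic cohort generator.
##
## Emulates the data structure the analysis assumes: an internally sequenced
## case-control cohort (shallower WGS, ~26.8 +/- 5.5x) plus an external
## unscreened control cohort (deeper, ~36.8 +/- 4.7x), a 200-state
## annotation partition of the genome, 21 repeat classes plus an "overall"
## class, genes carrying singleton protein-truncating variants, related and
## duplicate samples, and depth-dependent differential variant calling
## concentrated in repeat-like regions and in the ultra-rare frequency tail.
## Every latent quantity is kept in a truth record so that recovery tests
## never peek at generator internals.

repeat_class_names <- c(
  "SINE", "LINE", "LTR", "DNA", "DNA_unclassified", "Simple_repeat",
  "Low_complexity", "Satellite", "Retroposon", "RC", "rRNA", "tRNA",
  "snRNA", "scRNA", "srpRNA", "misc_RNA", "Unknown", "SINE_unclassified",
  "LINE_unclassified", "LTR_unclassified", "Microsatellite")

#' Configuration for the synthetic cohort generator
#'
#' Defaults are the generator's study conditions: group sizes proportioned
#' like a two-cohort psychiatric WGS study scaled to run on one CPU, depth
#' distributions 26.8 +/- 5.5 (internal) vs 36.8 +/- 4.7 (external), 200
#' annotation states, 22 repeat categories (21 specific + overall), a
#' rare-skewed Beta(0.2, 6) allele-frequency spectrum, and disease
#' prevalences of 1% (BD), 1% (SZ) and 2% (BD+SZ).
#'
#' @param n named integer vector of group sizes (internal_case_BD,
#'   internal_case_SZ, internal_control, external_control).
#' @param genome named numeric vector of chromosome lengths in bp.
#' @param n_variants number of bi-allelic variant sites.
#' @param maf_spectrum list(shape1, shape2) of the Beta spectrum for
#'   population minor-allele frequencies, truncated to `[1/(2N), 0.5]`.
#' @param n_states number of annotation states partitioning the genome.
#' @param state_segment_mean mean annotation-segment length (bp).
#' @param repeat_fraction target fraction of the genome covered by repeats.
#' @param n_genes,gene_length,ptv_fraction gene model: number of genes,
#'   their length, and the probability that an in-gene variant is a PTV.
#' @param excluded_fraction fraction of the genome in the exclusion list.
#' @param disease list: prevalence (named: BD, SZ, BD_SZ), sex_log_or, and
#'   optional window_effect = list(chrom, start, end, log_or, phenotype)
#'   giving a shared per-variant log-odds ratio for rare variants in a
#'   window (negative = protective).
#' @param batch list of depth/differential-calling parameters; see
#'   [inject_batch_effect()]. Set `enabled = FALSE` for a clean null.
#' @param female_fraction named vector (internal, external).
#' @param n_batches_internal number of internal sequencing batches.
#' @param relatedness list(n_dup, n_po) pairs to spike.
#' @param ancestry list(theta_shape1, theta_shape2, freq_sd): 2-way
#'   admixture proportions and the SD of the per-variant logit
#'   allele-frequency gradient between the two ancestral components.
#' @param seed master RNG seed; all generator randomness derives from it.
#' @return a config list (class `cohort_config`).
#' @export
cohort_config <- function(
    n = c(internal_case_BD = 500, internal_case_SZ = 1000,
          internal_control = 1500, external_control = 3000),
    genome = c(chr1 = 1e7, chr2 = 1e7),
    n_variants = 50000,
    maf_spectrum = list(shape1 = 0.2, shape2 = 6),
    n_states = 200,
    state_segment_mean = 800,
    repeat_fraction = 0.5,
    n_genes = 100,
    gene_length = 20000,
    ptv_fraction = 0.15,
    excluded_fraction = 0.01,
    disease = list(prevalence = c(BD = 0.01, SZ = 0.01, BD_SZ = 0.02),
                   sex_log_or = 0.3, window_effect = NULL),
    batch = list(enabled = TRUE,
                 depth_mean = c(internal = 26.8, external = 36.8),
                 depth_sd = c(internal = 5.5, external = 4.7),
                 dropout_max = 0.05, spurious_base = 2e-3,
                 depth_center = 31, depth_scale = 2,
                 class_multipliers = c(SINE = 3, Simple_repeat = 2.5),
                 repeat_multiplier = 2, nonrepeat_multiplier = 0.05,
                 batch_maf_max = 0.05),
    female_fraction = c(internal = 0.42, external = 0.62),
    n_batches_internal = 4,
    relatedness = list(n_dup = 3, n_po = 3),
    ancestry = list(theta_shape1 = 8, theta_shape2 = 2, freq_sd = 0.3),
    seed = 1) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$n >= 0), cfg$n_variants > 0, all(cfg$genome > 0))
  prev <- cfg$disease$prevalence
  if (any(prev <= 0 | prev >= 1)) stopf("prevalences must lie in (0,1)")
  if (cfg$repeat_fraction + cfg$excluded_fraction > 1)
    stopf("repeat + excluded genome fractions exceed 1")
  class(cfg) <- "cohort_config"
  cfg
}

## Random interval set with approximately `fraction` coverage of the genome.
random_intervals <- function(genome, fraction, mean_len, labels, label_weights,
                             allow_overlap = TRUE) {
  total <- sum(genome)
  ## with independent placement, coverage = 1 - exp(-L/G)
  target_len <- if (allow_overlap) -log(1 - fraction) * total else fraction * total
  n_int <- max(1L, round(target_len / mean_len))
  chrom <- sample(names(genome), n_int, replace = TRUE,
                  prob = genome / total)
  len <- pmax(20L, round(stats::rexp(n_int, 1 / mean_len)))
  start <- floor(runif(n_int) * (genome[chrom] - len))
  data.frame(chrom = chrom,
             start = as.integer(start),
             end = as.integer(start + len),
             label = sample(labels, n_int, replace = TRUE, prob = label_weights),
             stringsAsFactors = FALSE)
}

## Tile each chromosome with contiguous segments carrying state labels.
## State labels are assigned conditionally on each segment's repeat
## coverage: every state has a repeat-affinity anchor in [0, 1] and
## segments preferentially receive states whose anchor matches their
## coverage. This reproduces the strong, state-specific enrichment and
## depletion of genomic repeat classes that real chromatin/conservation
## state annotations show, which is what lets a repeat-concentrated
## calling artifact surface as state-level burden inflation.
state_partition <- function(genome, n_states, mean_len, repeat_intervals = NULL,
                            affinity_sd = 0.03) {
  pieces <- lapply(names(genome), function(ch) {
    L <- genome[[ch]]
    n_seg <- max(2L, ceiling(L / mean_len * 1.3))
    cuts <- sort(sample.int(L - 1L, min(n_seg, L - 1L)))
    start <- c(0L, cuts)
    end <- c(cuts, as.integer(L))
    data.frame(chrom = ch, start = start, end = end, stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, pieces)
  anchors <- stats::qbeta(seq(0.5, n_states - 0.5) / n_states, 0.8, 0.8)
  if (is.null(repeat_intervals) || nrow(repeat_intervals) == 0) {
    seg$label <- paste0("state", sample.int(n_states, nrow(seg), replace = TRUE))
    return(seg)
  }
  seg_gr <- GenomicRanges::GRanges(seg$chrom,
                                   IRanges::IRanges(seg$start + 1L, seg$end))
  rep_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    repeat_intervals$chrom,
    IRanges::IRanges(repeat_intervals$start + 1L, repeat_intervals$end)))
  ov <- GenomicRanges::findOverlaps(seg_gr, rep_gr)
  covered <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(seg_gr)[S4Vectors::queryHits(ov)],
    IRanges::ranges(rep_gr)[S4Vectors::subjectHits(ov)]))
  frac <- rep(0, nrow(seg))
  agg <- tapply(covered, S4Vectors::queryHits(ov), sum)
  frac[as.integer(names(agg))] <- agg / (seg$end - seg$start)[as.integer(names(agg))]
  lab <- integer(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    wts <- exp(-(frac[i] - anchors)^2 / (2 * affinity_sd^2))
    lab[i] <- sample.int(n_states, 1, prob = wts)
  }
  seg$label <- paste0("state", lab)
  seg
}

#' Generate a synthetic two-cohort case-control dataset
#'
#' Produces samples, variants, a sparse genotype matrix drawn under HWE from
#' ancestry-gradient allele frequencies, annotation tracks (states, repeat
#' classes, exclusion list, genes), spiked relatives, depth-dependent
#' differential calling, and a truth record with every latent parameter.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list(samples, variants, genotypes, tracks, repeat_membership,
#'   truth).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(config$seed, 1))
  genome <- config$genome
  n_total <- sum(config$n)

  ## ---- annotation tracks (repeats first: states condition on them) ----
  rw <- c(SINE = 0.33, LINE = 0.28, LTR = 0.12, DNA = 0.06,
          Simple_repeat = 0.022, Low_complexity = 0.03)
  other <- setdiff(repeat_class_names, names(rw))
  rw <- c(rw, setNames(rep((1 - sum(rw)) / length(other), length(other)), other))
  repeats <- interval_track("repeat",
                            random_intervals(genome, config$repeat_fraction, 400,
                                             repeat_class_names, rw[repeat_class_names]),
                            multi_label = TRUE)
  states <- interval_track("state",
                           state_partition(genome, config$n_states,
                                           config$state_segment_mean,
                                           repeats$intervals),
                           multi_label = FALSE)
  excluded <- interval_track("excluded",
                             random_intervals(genome, config$excluded_fraction,
                                              5000, "excluded", 1),
                             multi_label = TRUE)
  gene_ints <- random_intervals(genome, min(0.9, config$n_genes *
                                              config$gene_length / sum(genome)),
                                config$gene_length,
                                paste0("gene", seq_len(config$n_genes)),
                                rep(1, config$n_genes))
  genes <- interval_track("gene", gene_ints, multi_label = TRUE)
  tracks <- list(state = states, repeats = repeats, excluded = excluded,
                 gene = genes)

  ## ---- samples ----
  set.seed(derive_seed(config$seed, 2))
  n_int <- sum(config$n[c("internal_case_BD", "internal_case_SZ",
                          "internal_control")])
  n_ext <- config$n[["external_control"]]
  sample_id <- sprintf("S%05d", seq_len(n_total))
  is_external <- c(rep(FALSE, n_int), rep(TRUE, n_ext))
  sex <- ifelse(runif(n_total) < ifelse(is_external,
                                        config$female_fraction[["external"]],
                                        config$female_fraction[["internal"]]),
                "XX", "XY")
  batch <- ifelse(is_external, "ext_b1",
                  paste0("int_b", sample.int(config$n_batches_internal,
                                             n_total, replace = TRUE)))
  theta <- rbeta(n_total, config$ancestry$theta_shape1,
                 config$ancestry$theta_shape2)
  samples <- data.frame(sample_id = sample_id,
                        cohort = NA_character_,
                        phenotype = NA_character_,
                        sex = sex, reported_sex = sex, batch = batch,
                        stringsAsFactors = FALSE)

  ## ---- variants and population frequencies ----
  set.seed(derive_seed(config$seed, 3))
  m <- config$n_variants
  chrom <- sample(names(genome), m, replace = TRUE, prob = genome / sum(genome))
  pos <- floor(runif(m) * (genome[chrom] - 1)) + 1L
  ord <- order(match(chrom, names(genome)), pos)
  chrom <- chrom[ord]; pos <- as.integer(pos[ord])
  is_snv <- runif(m) < 0.95
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  alt[!is_snv] <- paste0(alt[!is_snv], "A")
  lo <- 1 / (2 * n_total)
  sp <- config$maf_spectrum
  u <- runif(m, pbeta(lo, sp$shape1, sp$shape2), pbeta(0.5, sp$shape1, sp$shape2))
  pop_maf <- stats::qbeta(u, sp$shape1, sp$shape2)
  grad <- rnorm(m, 0, config$ancestry$freq_sd)
  f_a <- plogis(stats::qlogis(pop_maf) - grad / 2)
  f_b <- plogis(stats::qlogis(pop_maf) + grad / 2)
  variants <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         is_snv = is_snv, stringsAsFactors = FALSE)

  ## ---- genotypes under HWE with per-sample admixture frequencies ----
  set.seed(derive_seed(config$seed, 4))
  genotypes <- hwe_genotypes(theta, f_a, f_b, sample_id)

  ## ---- annotation join ----
  ann <- annotate_variants(variants, tracks)
  variants <- ann$variants
  set.seed(derive_seed(config$seed, 5))
  variants$is_ptv <- !is.na(variants$gene) & runif(m) < config$ptv_fraction

  ## ---- phenotype / cohort assignment ----
  set.seed(derive_seed(config$seed, 6))
  asg <- assign_case_groups(samples, genotypes, variants, config)
  samples <- asg$samples

  ## ---- relatives ----
  set.seed(derive_seed(config$seed, 7))
  rel <- spike_relatives(samples, genotypes,
                         n_dup = config$relatedness$n_dup,
                         n_po = config$relatedness$n_po,
                         pop_freq = (f_a + f_b) / 2,
                         seed = derive_seed(config$seed, 8))
  genotypes <- rel$genotypes
  samples <- rel$samples

  ## ---- depth-driven differential calling and QC metrics ----
  batch_truth <- NULL
  if (isTRUE(config$batch$enabled)) {
    be <- inject_batch_effect(genotypes, variants, samples, config$batch,
                              seed = derive_seed(config$seed, 9))
    genotypes <- be$genotypes
    samples <- be$samples
    batch_truth <- be$truth
  } else {
    be <- regenerate_metrics(samples, depth = rnorm(n_total, 30, 5),
                             seed = derive_seed(config$seed, 9))
    samples <- be
  }

  ac <- allele_counts(genotypes)
  variants$ac <- ac$ac; variants$mac <- ac$mac; variants$maf <- ac$maf

  truth <- list(seed = config$seed, config = config,
                population_maf = pop_maf, freq_a = f_a, freq_b = f_b,
                admixture = theta,
                window_effect = config$disease$window_effect,
                effect_variants = asg$effect_variants,
                relative_pairs = rel$pairs,
                batch = batch_truth)
  list(samples = samples, variants = variants, genotypes = genotypes,
       tracks = tracks, repeat_membership = ann$repeat_membership,
       truth = truth)
}

## HWE genotype sampling in variant chunks; returns a sparse samples x
## variants matrix of 0/1/2 counts.
hwe_genotypes <- function(theta, f_a, f_b, sample_id) {
  n <- length(theta); m <- length(f_a)
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  acc_i <- list(); acc_j <- list(); acc_x <- list(); k <- 0L
  for (idx in chunk_indices(m, 1000L)) {
    p <- outer(1 - theta, f_a[idx]) + outer(theta, f_b[idx])
    g <- rbinom(length(p), 2L, p)
    nz <- which(g > 0L)
    k <- k + 1L
    acc_i[[k]] <- ((nz - 1L) %% n) + 1L
    acc_j[[k]] <- idx[((nz - 1L) %/% n) + 1L]
    acc_x[[k]] <- g[nz]
  }
  Matrix::sparseMatrix(i = unlist(acc_i), j = unlist(acc_j), x = unlist(acc_x),
                       dims = c(n, m),
                       dimnames = list(sample_id, NULL))
}

## Retrospective assignment of case groups within the internal pool:
## cases are drawn with probability proportional to exp(genetic + covariate
## log-odds), which preserves the configured per-variant odds ratios under
## case-control sampling.
assign_case_groups <- function(samples, genotypes, variants, config) {
  n <- config$n
  n_total <- nrow(samples)
  is_external <- seq_len(n_total) > (n_total - n[["external_control"]])
  internal_idx <- which(!is_external)
  we <- config$disease$window_effect
  lp <- numeric(n_total)
  effect_variants <- integer(0)
  if (!is.null(we)) {
    effect_variants <- which(variants$chrom == we$chrom &
                               variants$pos >= we$start &
                               variants$pos <= we$end)
    if (length(effect_variants) > 0)
      lp <- as.numeric(genotypes[, effect_variants, drop = FALSE] %*%
                         rep(we$log_or, length(effect_variants)))
  }
  lp <- lp + config$disease$sex_log_or * (samples$sex == "XY")
  target_pheno <- if (is.null(we) || is.null(we$phenotype)) "BD" else we$phenotype
  w <- exp(lp[internal_idx] - max(lp[internal_idx]))
  pool <- internal_idx
  pick <- function(k, use_weights) {
    if (k == 0) return(integer(0))
    probs <- if (use_weights) w[match(pool, internal_idx)] else rep(1, length(pool))
    chosen <- sample(pool, k, prob = probs)
    pool <<- setdiff(pool, chosen)
    chosen
  }
  bd <- pick(n[["internal_case_BD"]], target_pheno %in% c("BD", "BD_SZ"))
  sz <- pick(n[["internal_case_SZ"]], target_pheno %in% c("SZ", "BD_SZ"))
  ctrl <- pool
  samples$cohort[bd] <- "internal_case_BD"
  samples$cohort[sz] <- "internal_case_SZ"
  samples$cohort[ctrl] <- "internal_control"
  samples$cohort[is_external] <- "external_control"
  samples$phenotype <- ifelse(grepl("case", samples$cohort), "case", "control")
  list(samples = samples, effect_variants = effect_variants)
}

#' Assign phenotypes under a prevalence-calibrated logistic disease model
#'
#' Population-sampling mode: `logit P(case) = alpha + sex effect + sum of
#' per-variant effects`, with the intercept solved numerically so the
#' population prevalence matches the target. Used for prevalence-recovery
#' and null-calibration experiments; [generate_cohort()] uses retrospective
#' case sampling instead because its group sizes are fixed.
#'
#' @param samples sample table with a `sex` column.
#' @param genotypes samples x variants count matrix.
#' @param disease list(prevalence scalar, sex_log_or, variant_effects =
#'   optional numeric vector of per-variant log-ORs aligned to columns).
#' @param seed RNG seed.
#' @return `samples` with a `phenotype` column ("case"/"control") and the
#'   solved intercept as attribute `"intercept"`.
#' @export
assign_phenotypes <- function(samples, genotypes, disease, seed = 1) {
  set.seed(seed)
  prevalence <- disease$prevalence
  stopifnot(prevalence > 0, prevalence < 1)
  lp <- numeric(nrow(samples))
  if (!is.null(disease$variant_effects)) {
    eff <- disease$variant_effects
    nz <- which(eff != 0)
    if (length(nz) > 0)
      lp <- lp + as.numeric(genotypes[, nz, drop = FALSE] %*% eff[nz])
  }
  if (!is.null(disease$sex_log_or))
    lp <- lp + disease$sex_log_or * (samples$sex == "XY")
  f <- function(a) mean(plogis(a + lp)) - prevalence
  lo <- stats::qlogis(prevalence) - max(lp) - 1
  hi <- stats::qlogis(prevalence) - min(lp) + 1
  if (f(lo) > 0 || f(hi) < 0) stopf("prevalence %g unattainable", prevalence)
  alpha <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  samples$phenotype <- ifelse(runif(nrow(samples)) < plogis(alpha + lp),
                              "case", "control")
  attr(samples, "intercept") <- alpha
  samples
}

#' Spike duplicate and parent-offspring pairs into a cohort
#'
#' Duplicates copy the source genotype vector verbatim (downstream batch
#' noise is applied independently); parent-offspring pairs share exactly one
#' transmitted allele per variant, with the untransmitted allele drawn from
#' the population frequency.
#'
#' @param samples sample table.
#' @param genotypes samples x variants sparse count matrix.
#' @param n_dup,n_po numbers of duplicate and parent-offspring pairs.
#' @param pop_freq per-variant population allele frequency for the
#'   untransmitted allele.
#' @param seed RNG seed.
#' @return list(samples, genotypes, pairs): `pairs` records (id1, id2,
#'   relationship).
#' @export
spike_relatives <- function(samples, genotypes, n_dup, n_po, pop_freq,
                            seed = 1) {
  set.seed(seed)
  n_pairs <- n_dup + n_po
  if (n_pairs == 0)
    return(list(samples = samples, genotypes = genotypes,
                pairs = data.frame(id1 = character(), id2 = character(),
                                   relationship = character())))
  n <- nrow(genotypes)
  if (2 * n_pairs > n) stopf("not enough samples for %d relative pairs", n_pairs)
  chosen <- sample.int(n, 2 * n_pairs)
  src <- chosen[seq_len(n_pairs)]
  dst <- chosen[n_pairs + seq_len(n_pairs)]
  ## rebuild the sparse matrix once: drop the replaced rows' entries and
  ## append the new rows' entries as triplets
  tg <- as(genotypes, "TsparseMatrix")
  keep <- !((tg@i + 1L) %in% dst)
  add_i <- list(); add_j <- list(); add_x <- list()
  for (k in seq_len(n_pairs)) {
    if (k <= n_dup) {
      newrow <- as.numeric(genotypes[src[k], ])
    } else {
      gp <- as.numeric(genotypes[src[k], ])
      transmitted <- rbinom(length(gp), 1L, gp / 2)
      other <- rbinom(length(gp), 1L, pop_freq)
      newrow <- transmitted + other
    }
    nz <- which(newrow > 0)
    add_i[[k]] <- rep(dst[k], length(nz))
    add_j[[k]] <- nz
    add_x[[k]] <- newrow[nz]
  }
  genotypes <- Matrix::sparseMatrix(
    i = c(tg@i[keep] + 1L, unlist(add_i)),
    j = c(tg@j[keep] + 1L, unlist(add_j)),
    x = c(tg@x[keep], unlist(add_x)),
    dims = dim(genotypes), dimnames = dimnames(genotypes))
  pairs <- data.frame(
    id1 = samples$sample_id[src], id2 = samples$sample_id[dst],
    relationship = rep(c("duplicate", "parent_offspring"),
                       c(n_dup, n_po)), stringsAsFactors = FALSE)
  list(samples = samples, genotypes = genotypes, pairs = pairs)
}

## Depth-driven QC metrics: every metric is a smooth function of the latent
## per-sample depth plus noise, mirroring metadata whose principal
## components are almost entirely depth-driven.
regenerate_metrics <- function(samples, depth, seed) {
  set.seed(seed)
  n <- length(depth)
  samples$mean_depth <- depth + rnorm(n, 0, 0.1)
  samples$contamination <- rbeta(n, 1.5, 250)
  samples$depth10_completeness <-
    pmin(1, pmax(0, 1 - 0.012 * plogis((18 - depth) / 3) - abs(rnorm(n, 0, 0.001))))
  samples$q30_fraction <- pmin(1, plogis((depth - 8) / 9) + rnorm(n, 0, 0.004))
  samples$insert_size <- 350 + 2 * depth + rnorm(n, 0, 4)
  samples$gc_dropout <- pmax(0, plogis((20 - depth) / 6) + rnorm(n, 0, 0.004))
  samples$duplication_rate <- pmax(0, 0.2 * plogis((depth - 40) / 10) +
                                     rnorm(n, 0, 0.004))
  ## saturating depth metrics at staggered transition points: together
  ## their PCs span smooth nonlinear functions of depth, which is what
  ## lets metadata PCs absorb depth-dependent calling behaviour
  samples$soft_clip_rate <- pmax(0, 0.04 * plogis((depth - 31) / 2) +
                                   rnorm(n, 0, 0.0008))
  samples$q20_fraction <- pmin(1, plogis((depth - 25) / 3) +
                                 rnorm(n, 0, 0.002))
  samples$coverage_uniformity <- pmin(1, plogis((37 - depth) / 3) +
                                        rnorm(n, 0, 0.002))
  samples
}

metric_names <- function() {
  c("mean_depth", "contamination", "depth10_completeness", "q30_fraction",
    "insert_size", "gc_dropout", "duplication_rate", "soft_clip_rate",
    "q20_fraction", "coverage_uniformity")
}

#' Inject depth-dependent differential variant calling
#'
#' Each sample draws a latent sequencing depth from its cohort's depth
#' distribution. For ultra-rare variants (population MAF below
#' `batch$batch_maf_max`), non-reference calls drop out (1/2 -> 0) with a
#' probability that decreases with depth, and spurious non-reference calls
#' (0 -> 1) appear with a probability that increases with depth; both rates
#' are multiplied per variant by a repeat-class factor (largest over the
#' classes the variant overlaps; e.g. SINE and simple-repeat classes above
#' 1). Per-sample QC metrics are regenerated as depth-driven functions plus
#' noise. Restricting the artifact to the ultra-rare tail reflects
#' differential-calling artifacts that sit below a MAC>20 single-variant
#' filter while dominating beta(1,25)-weighted burden aggregates.
#'
#' @param genotypes samples x variants sparse count matrix.
#' @param variants variant table (needs pos/maf columns plus repeat labels
#'   from [annotate_variants()]).
#' @param samples sample table with a `cohort` column.
#' @param batch batch-model list; see [cohort_config()].
#' @param seed RNG seed.
#' @return list(genotypes, samples, truth) where truth records depths,
#'   per-variant multipliers and the eligible variant set.
#' @export
inject_batch_effect <- function(genotypes, variants, samples, batch, seed = 1) {
  set.seed(seed)
  n <- nrow(genotypes)
  if (any(unlist(batch[c("dropout_max", "spurious_base")]) < 0))
    stopf("negative batch-effect rates")
  is_ext <- samples$cohort == "external_control"
  depth <- rnorm(n,
                 ifelse(is_ext, batch$depth_mean[["external"]],
                        batch$depth_mean[["internal"]]),
                 ifelse(is_ext, batch$depth_sd[["external"]],
                        batch$depth_sd[["internal"]]))
  depth <- pmax(depth, 4)

  ac <- allele_counts(genotypes)
  eligible <- which(ac$maf < batch$batch_maf_max & ac$maf > 0)
  mult <- variant_class_multiplier(variants, batch)
  z <- (depth - batch$depth_center) / batch$depth_scale
  d_rate <- batch$dropout_max * plogis(-z)      # shallow samples lose calls
  s_rate <- batch$spurious_base * plogis(z)     # deep samples gain calls

  ## single triplet pass: drop out existing non-reference calls and add
  ## spurious het calls at eligible sites, then rebuild the matrix once
  if (length(eligible) > 0 &&
      (batch$dropout_max > 0 || batch$spurious_base > 0)) {
    is_eligible <- logical(ncol(genotypes))
    is_eligible[eligible] <- TRUE
    tg <- as(genotypes, "TsparseMatrix")
    ti <- tg@i + 1L; tj <- tg@j + 1L; tx <- tg@x
    keep <- rep(TRUE, length(tx))
    if (batch$dropout_max > 0) {
      el <- which(is_eligible[tj])
      p_drop <- pmin(1, d_rate[ti[el]] * mult[tj[el]])
      keep[el[runif(length(el)) < p_drop]] <- FALSE
    }
    add_i <- list(); add_j <- list(); k <- 0L
    if (batch$spurious_base > 0) {
      for (idx in chunk_indices(length(eligible), 1000L)) {
        cols <- eligible[idx]
        pmat <- outer(s_rate, mult[cols])
        hit <- which(matrix(runif(length(pmat)), n) < pmat)
        if (length(hit) > 0) {
          k <- k + 1L
          add_i[[k]] <- ((hit - 1L) %% n) + 1L
          add_j[[k]] <- cols[((hit - 1L) %/% n) + 1L]
        }
      }
    }
    si <- unlist(add_i); sj <- unlist(add_j)
    if (length(si) > 0) {
      ## spurious calls only flip entries that are currently reference
      occupied <- genotypes[cbind(si, sj)] != 0
      si <- si[!occupied]; sj <- sj[!occupied]
    }
    genotypes <- Matrix::sparseMatrix(
      i = c(ti[keep], si), j = c(tj[keep], sj),
      x = c(tx[keep], rep(1, length(si))),
      dims = dim(genotypes), dimnames = dimnames(genotypes))
  }
  samples <- regenerate_metrics(samples, depth, seed = derive_seed(seed, 11))
  list(genotypes = genotypes, samples = samples,
       truth = list(depth = depth, eligible_variants = eligible,
                    class_multiplier = mult,
                    dropout_rate = d_rate, spurious_rate = s_rate))
}

## Per-variant rate multiplier: max over overlapped repeat classes of the
## configured class multipliers, defaulting to `repeat_multiplier` inside
## any repeat and `nonrepeat_multiplier` outside.
variant_class_multiplier <- function(variants, batch) {
  mult <- rep(batch$nonrepeat_multiplier %||% 1, nrow(variants))
  rc <- variants$repeat_classes
  if (is.null(rc)) return(mult)
  cm <- batch$class_multipliers %||% numeric(0)
  base_rep <- batch$repeat_multiplier %||% 1
  in_rep <- !vapply(rc, is.null, logical(1)) & lengths(rc) > 0
  mult[in_rep] <- base_rep
  for (cls in names(cm)) {
    hit <- vapply(rc, function(x) cls %in% x, logical(1))
    mult[hit] <- pmax(mult[hit], cm[[cls]])
  }
  mult
}

#' Write a cohort to disk in standard formats
#'
#' VCF (genotypes), BED4 tracks, samples TSV and a truth JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort$variants, cohort$genotypes, file.path(dir, "genotypes.vcf"))
  for (nm in names(cohort$tracks))
    write_bed_track(cohort$tracks[[nm]], file.path(dir, paste0(nm, ".bed")))
  samples <- cohort$samples
  write.table(samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$config <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
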