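test_that("generation is fully reproducible from the seed", {
  cfg <- tiny_cohort_config(seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$variants, b$variants)
  expect_true(identical(as.matrix(a$genotypes), as.matrix(b$genotypes)))
  expect_identical(a$truth$relative_pairs, b$truth$relative_pairs)
  ## a different seed changes the data
  c_ <- generate_cohort(tiny_cohort_config(seed = 100))
  expect_false(identical(as.matrix(a$genotypes), as.matrix(c_$genotypes)))
})

test_that("cohort structure matches the configuration", {
  cfg <- tiny_cohort_config(seed = 7)
  co <- generate_cohort(cfg)
  expect_equal(unname(table(co$samples$cohort)[names(cfg$n)]),
               unname(cfg$n), ignore_attr = TRUE)
  expect_equal(ncol(co$genotypes), cfg$n_variants)
  expect_true(all(co$variants$maf <= 0.5 + 1e-12))
  expect_true(all(co$variants$mac == pmin(co$variants$ac,
                                          2 * nrow(co$samples) - co$variants$ac)))
  ## states partition: every variant gets a state
  expect_false(any(is.na(co$variants$state)))
  ## truth record exposes the latent structure
  expect_length(co$truth$population_maf, cfg$n_variants)
  expect_length(co$truth$admixture, sum(cfg$n))
  expect_equal(nrow(co$truth$relative_pairs), 2)
})

test_that("the population MAF spectrum follows the truncated Beta draw", {
  cfg <- tiny_cohort_config(seed = 13, n_variants = 50000,
                            n = c(internal_case_BD = 50, internal_case_SZ = 50,
                                  internal_control = 250,
                                  external_control = 250),
                            genome = c(chr1 = 5e6, chr2 = 5e6))
  co <- generate_cohort(cfg)
  m <- co$truth$population_maf
  lo <- 1 / (2 * sum(cfg$n))
  a <- cfg$maf_spectrum$shape1; b <- cfg$maf_spectrum$shape2
  trunc_cdf <- function(q) {
    (pbeta(q, a, b) - pbeta(lo, a, b)) /
      (pbeta(0.5, a, b) - pbeta(lo, a, b))
  }
  expect_true(all(m >= lo & m <= 0.5))
  expect_gt(suppressWarnings(stats::ks.test(m, trunc_cdf)$p.value), 0.01)
})

test_that("population-mode phenotypes match the target prevalence", {
  set.seed(55)
  n <- 50000
  samples <- data.frame(sample_id = sprintf("S%05d", 1:n),
                        sex = sample(c("XX", "XY"), n, replace = TRUE))
  g <- toy_genotypes(n, 10, maf = 0.1, seed = 55)
  disease <- list(prevalence = 0.02, sex_log_or = 0.3,
                  variant_effects = c(rep(0.2, 3), rep(0, 7)))
  out <- assign_phenotypes(samples, g, disease, seed = 56)
  achieved <- mean(out$phenotype == "case")
  expect_lt(abs(achieved - 0.02) / 0.02, 0.10)
  ## binomial 99% CI at n = 20,000 for the null model
  s2 <- samples[1:20000, ]
  out2 <- assign_phenotypes(s2, g[1:20000, ], list(prevalence = 0.01),
                            seed = 57)
  ci <- qnorm(0.995) * sqrt(0.01 * 0.99 / 20000)
  expect_lt(abs(mean(out2$phenotype == "case") - 0.01), ci)
  expect_error(assign_phenotypes(s2, g[1:20000, ], list(prevalence = 1.2)),
               "prevalence")
})

test_that("null phenotypes are independent of genotype", {
  set.seed(58)
  n <- 1500
  samples <- data.frame(sample_id = as.character(1:n),
                        sex = rep(c("XX", "XY"), n / 2))
  g <- toy_genotypes(n, 5, maf = 0.2, seed = 58)
  pvals <- vapply(1:150, function(r) {
    out <- assign_phenotypes(samples, g, list(prevalence = 0.3), seed = 100 + r)
    y <- out$phenotype == "case"
    suppressWarnings(stats::chisq.test(table(as.numeric(g[, 1]), y))$p.value)
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("a protective regional burden lowers case burden in that window", {
  lower <- 0
  n_rep <- 15
  for (r in seq_len(n_rep)) {
    cfg <- tiny_cohort_config(
      seed = 700 + r, n_variants = 2500,
      n = c(internal_case_BD = 120, internal_case_SZ = 60,
            internal_control = 220, external_control = 100),
      disease = list(prevalence = c(BD = 0.01, SZ = 0.01, BD_SZ = 0.02),
                     sex_log_or = 0,
                     window_effect = list(chrom = "chr1", start = 2e5,
                                          end = 4e5, log_or = -0.4,
                                          phenotype = "BD")),
      batch = list(enabled = FALSE))
    co <- generate_cohort(cfg)
    idx <- which(co$variants$chrom == "chr1" & co$variants$pos >= 2e5 &
                   co$variants$pos <= 4e5 & co$variants$maf > 0)
    w <- beta_weight(pmax(co$variants$maf[idx], 1e-9))
    burden <- as.numeric(co$genotypes[, idx, drop = FALSE] %*% w)
    grp <- co$samples$cohort
    if (mean(burden[grp == "internal_case_BD"]) <
          mean(burden[grp == "internal_control"])) lower <- lower + 1
  }
  expect_gte(lower, ceiling(0.8 * n_rep))
})

test_that("zero batch-effect rates leave genotypes untouched", {
  cfg <- tiny_cohort_config(seed = 31)
  co <- generate_cohort(cfg)
  batch <- cfg$batch
  batch$dropout_max <- 0; batch$spurious_base <- 0
  out <- inject_batch_effect(co$genotypes, co$variants, co$samples, batch,
                             seed = 5)
  expect_true(identical(as.matrix(out$genotypes), as.matrix(co$genotypes)))
  expect_error(inject_batch_effect(co$genotypes, co$variants, co$samples,
                                   modifyList(batch, list(dropout_max = -1)),
                                   seed = 5),
               "negative")
})

test_that("dropout alone couples rare burden to depth (shallow samples lose calls)", {
  cfg <- tiny_cohort_config(seed = 33, n_variants = 6000)
  cfg$batch$enabled <- FALSE
  co <- generate_cohort(cfg)
  batch <- cohort_config()$batch
  batch$spurious_base <- 0
  batch$dropout_max <- 0.5
  batch$depth_center <- 30; batch$depth_scale <- 5
  batch$batch_maf_max <- 0.05
  out <- inject_batch_effect(co$genotypes, co$variants, co$samples, batch,
                             seed = 6)
  rare <- which(co$variants$maf < 0.05 & co$variants$maf > 0)
  w <- beta_weight(co$variants$maf[rare])
  total <- as.numeric(out$genotypes[, rare, drop = FALSE] %*% w)
  ## shallow samples lose non-reference calls, so the per-sample rare
  ## burden rises with depth
  ct <- suppressWarnings(
    stats::cor.test(total, out$truth$depth, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("spiked duplicates and parent-offspring pairs have the right kinship", {
  set.seed(61)
  n <- 40; m <- 20000
  maf <- runif(m, 0.1, 0.5)
  g <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m,
              dimnames = list(sprintf("S%03d", 1:n), NULL))
  g <- methods::as(methods::as(g, "dMatrix"), "CsparseMatrix")
  samples <- data.frame(sample_id = rownames(g))
  out <- spike_relatives(samples, g, n_dup = 1, n_po = 1, pop_freq = maf,
                         seed = 62)
  kin <- estimate_kinship(out$genotypes)
  pair_phi <- function(p) {
    kin$phi[(kin$id1 == p[1] & kin$id2 == p[2]) |
              (kin$id1 == p[2] & kin$id2 == p[1])]
  }
  dup <- unlist(out$pairs[out$pairs$relationship == "duplicate", 1:2])
  po <- unlist(out$pairs[out$pairs$relationship == "parent_offspring", 1:2])
  expect_equal(pair_phi(dup), 0.5, tolerance = 1e-12)
  expect_gt(pair_phi(po), 0.23)
  expect_lt(pair_phi(po), 0.27)
})
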