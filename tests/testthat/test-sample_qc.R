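qc_samples <- function() {
  data.frame(sample_id = paste0("S", 1:5),
             cohort = "internal_control",
             contamination = c(0.01, 0.06, 0.02, 0.001, 0.03),
             depth10_completeness = c(0.99, 0.999, 0.97, 0.995, 0.985),
             sex = c("XX", "XY", "XX", "XY", "XX"),
             reported_sex = c("XX", "XY", "XX", "XX", "XX"),
             stringsAsFactors = FALSE)
}

test_that("sample filters apply the contamination, coverage and sex rules", {
  out <- filter_samples(qc_samples())
  expect_setequal(out$kept$sample_id, c("S1", "S5"))
  expect_equal(out$excluded$reason[out$excluded$sample_id == "S2"],
               "contamination")
  expect_equal(out$excluded$reason[out$excluded$sample_id == "S3"],
               "coverage")
  expect_equal(out$excluded$reason[out$excluded$sample_id == "S4"],
               "sex_mismatch")
  ## boundary: exactly 5% contamination and exactly 98% completeness pass
  edge <- qc_samples()[1, ]
  edge$contamination <- 0.05; edge$depth10_completeness <- 0.98
  expect_equal(nrow(filter_samples(edge)$kept), 1)
  bad <- qc_samples(); bad$contamination[2] <- NA
  expect_error(filter_samples(bad), "S2")
})

test_that("KING kinship equals a brute-force tally and is 0.5 for duplicates", {
  set.seed(71)
  ## toy pairs, 10 variants: brute-force the four genotype-pair counts
  for (r in 1:20) {
    g <- matrix(sample(0:2, 20, replace = TRUE), 2, 10)
    rownames(g) <- c("a", "b")
    kin <- estimate_kinship(methods::as(methods::as(g, "dMatrix"),
                                        "CsparseMatrix"))
    n_hh <- sum(g[1, ] == 1 & g[2, ] == 1)
    n_opp <- sum((g[1, ] == 0 & g[2, ] == 2) | (g[1, ] == 2 & g[2, ] == 0))
    denom <- sum(g[1, ] == 1) + sum(g[2, ] == 1)
    expected <- if (denom == 0) NA_real_ else (n_hh - 2 * n_opp) / denom
    expect_equal(kin$phi, expected, tolerance = 1e-12)
  }
  ## identical genomes: no opposite homozygotes, all het sites shared
  g <- matrix(rbinom(2000, 2, 0.3), 1, 2000)
  g2 <- rbind(g, g)
  rownames(g2) <- c("a", "b")
  kin <- estimate_kinship(methods::as(methods::as(g2, "dMatrix"),
                                      "CsparseMatrix"))
  expect_identical(kin$phi, 0.5)
})

test_that("unrelated pairs have near-zero kinship at 20,000 variants", {
  set.seed(72)
  m <- 20000
  maf <- runif(m, 0.1, 0.5)
  g <- matrix(rbinom(6 * m, 2, rep(maf, each = 6)), 6, m,
              dimnames = list(paste0("S", 1:6), NULL))
  kin <- estimate_kinship(methods::as(methods::as(g, "dMatrix"),
                                      "CsparseMatrix"))
  expect_true(all(abs(kin$phi) < 0.02))
})

test_that("null kinship produces no spurious related pairs at scale", {
  set.seed(73)
  n <- 400; m <- 20000
  maf <- runif(m, 0.1, 0.5)
  g <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m,
              dimnames = list(sprintf("S%04d", 1:n), NULL))
  kin <- estimate_kinship(methods::as(methods::as(g, "dMatrix"),
                                      "CsparseMatrix"), min_report = 0.0409)
  expect_lte(nrow(kin), 1)   # < 1 pair expected by chance
})

test_that("relatedness pruning removes the right members", {
  ## one related pair: exactly one removed
  kin1 <- data.frame(id1 = "A", id2 = "B", phi = 0.05)
  expect_length(prune_related(kin1), 1)
  ## chain A-B, B-C with A-C unrelated: B removed, A and C retained
  kin2 <- data.frame(id1 = c("A", "B"), id2 = c("B", "C"),
                     phi = c(0.06, 0.06))
  expect_identical(prune_related(kin2), "B")
  ## internal/external duplicate: the internal sample is retained
  samples <- data.frame(sample_id = c("I1", "E1"),
                        cohort = c("internal_control", "external_control"))
  kin3 <- data.frame(id1 = "I1", id2 = "E1", phi = 0.5)
  for (s in 1:5) expect_identical(prune_related(kin3, samples, seed = s), "E1")
})

test_that("pruning output never retains a pair above threshold (all-pairs check)", {
  set.seed(74)
  for (r in 1:10) {
    ids <- paste0("S", 1:30)
    pairs <- t(utils::combn(ids, 2))
    phi <- ifelse(runif(nrow(pairs)) < 0.08, runif(nrow(pairs), 0.05, 0.3),
                  runif(nrow(pairs), -0.02, 0.02))
    kin <- data.frame(id1 = pairs[, 1], id2 = pairs[, 2], phi = phi)
    removed <- prune_related(kin, seed = r)
    kept <- setdiff(ids, removed)
    live <- kin[kin$id1 %in% kept & kin$id2 %in% kept, ]
    expect_true(all(live$phi <= 0.0409))
    ## maximality on chains is guaranteed by highest-degree-first removal;
    ## at minimum the removal set is not everything
    expect_lt(length(removed), length(ids))
  }
})

test_that("LD pruning drops duplicated columns and sub-threshold MAFs", {
  set.seed(75)
  n <- 300
  g <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  g[, 3] <- g[, 2]                       # r^2 = 1 duplicate
  g[, 5] <- rbinom(n, 2, 0.04)           # MAF below the 5% floor
  variants <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 500L))
  kept <- ld_prune(methods::as(methods::as(g, "dMatrix"), "CsparseMatrix"),
                   variants)
  expect_false(3L %in% kept)
  expect_true(2L %in% kept)
  expect_false(5L %in% kept)   # ineligible, not considered
  ## retained set has no high-r^2 pair
  r2 <- cor(g[, kept])^2
  expect_true(all(r2[upper.tri(r2)] <= 0.2 + 1e-9))
})

test_that("independent variants survive LD pruning almost entirely", {
  set.seed(76)
  n <- 2000; m <- 300
  maf <- runif(m, 0.1, 0.5)
  g <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m)
  variants <- data.frame(chrom = "chr1", pos = sort(sample.int(5e5, m)))
  kept <- ld_prune(methods::as(methods::as(g, "dMatrix"), "CsparseMatrix"),
                   variants)
  expect_gte(length(kept), 0.95 * m)
})

test_that("genetic PCs separate subpopulations and are orthonormal-sane", {
  set.seed(77)
  n <- 200; m <- 800
  pop <- rep(c(0, 1), each = n / 2)
  f1 <- runif(m, 0.05, 0.5)
  f2 <- plogis(qlogis(f1) + rnorm(m, 0, 0.8))
  p <- outer(1 - pop, f1) + outer(pop, f2)
  g <- matrix(rbinom(n * m, 2, p), n, m,
              dimnames = list(sprintf("S%03d", 1:n), NULL))
  gs <- methods::as(methods::as(g, "dMatrix"), "CsparseMatrix")
  pcs <- compute_genetic_pcs(gs, k = 10, method = "exact")
  r <- cor(pcs$scores[, 1], pop)
  expect_gt(abs(r), 0.9)
  ## scores mutually orthogonal
  cp <- crossprod(pcs$scores)
  off <- cp[upper.tri(cp)] / sqrt(diag(cp)[1] * diag(cp)[2])
  expect_true(all(abs(off) < 1e-8))
  ## permuting samples permutes scores identically
  perm <- sample(n)
  pcs_p <- compute_genetic_pcs(gs[perm, ], k = 10, method = "exact")
  expect_equal(unname(pcs_p$scores), unname(pcs$scores[perm, ]),
               tolerance = 1e-8)
  ## the randomized solver agrees with the exact one on the structured
  ## leading component (later components are pure noise directions)
  pcs_r <- compute_genetic_pcs(gs, k = 4, method = "randomized", seed = 2)
  expect_gt(abs(cor(pcs_r$scores[, 1], pcs$scores[, 1])), 0.99)
  expect_warning(compute_genetic_pcs(gs[1:5, 1:10], k = 10), "PCs")
})
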