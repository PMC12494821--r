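test_that("lambda_gc is exact at p = 0.5, monotone, and calibrated on uniforms", {
  expect_identical(lambda_gc(rep(0.5, 7)), 1)
  set.seed(4)
  p <- runif(10000)
  lam <- lambda_gc(p)
  expect_gt(lam, 0.95)
  expect_lt(lam, 1.05)
  ## halving all p-values strictly increases lambda
  expect_gt(lambda_gc(p / 2), lam)
  expect_warning(l0 <- lambda_gc(c(0, 0.5, 0.5)), "clipped")
  expect_true(is.finite(l0))
  expect_error(lambda_gc(numeric(0)), "no p-values")
})

test_that("burden test is calibrated under permuted outcomes", {
  set.seed(14)
  n <- 400
  burden <- rpois(n, 5) + runif(n)
  covs <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  pvals <- replicate(400, {
    y <- sample(rep(c(0, 1), each = n / 2))
    burden_logistic_test(burden, y, covs)$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("burden effect sizes are recovered", {
  set.seed(15)
  n <- 3000
  hits <- 0
  for (r in 1:20) {
    burden <- rpois(n, 6)
    y <- rbinom(n, 1, plogis(-0.8 + 0.1 * burden))
    est <- burden_logistic_test(burden, y, standardize = FALSE)$estimate
    if (abs(est - 0.1) < 0.03) hits <- hits + 1
  }
  expect_gte(hits, 16)   # within +-30% in at least 80% of replicates
})

test_that("degenerate and separated burdens are flagged, not fatal", {
  set.seed(16)
  y <- rbinom(100, 1, 0.5)
  res <- burden_logistic_test(rep(0, 100), y)
  expect_equal(res$flag, "degenerate")
  expect_equal(res$p, 1)
  ## perfectly separating burden triggers the Firth fallback
  y2 <- c(rep(0, 50), rep(1, 50))
  b2 <- c(rep(0, 50), rep(3, 50))
  res2 <- burden_logistic_test(b2, y2)
  expect_equal(res2$flag, "firth")
  expect_true(is.finite(res2$p))
  expect_gt(res2$estimate, 0)
})

test_that("category scans report family thresholds and calibrated lambda", {
  set.seed(17)
  n <- 500; k <- 22
  B <- matrix(rpois(n * k, 8) + rnorm(n * k, 0, 0.3), n, k,
              dimnames = list(NULL, paste0("cat", 1:k)))
  y <- rbinom(n, 1, 0.5)
  scan <- run_category_scan(B, y, kind = "repeat")
  expect_equal(scan$threshold, 0.05 / 22)
  expect_equal(scan$strict_threshold, 0.05 / (22 * 7))
  expect_equal(nrow(scan$results), 22)
  ## per-run lambda over few categories is noisy; just bound it loosely
  expect_gt(scan$lambda_gc, 0.5)
  expect_lt(scan$lambda_gc, 1.8)
})

test_that("null category-scan lambda is centred at 1 over replicate scans", {
  set.seed(18)
  lams <- replicate(30, {
    n <- 300; k <- 100
    B <- matrix(rpois(n * k, 6), n, k,
                dimnames = list(NULL, paste0("c", 1:k)))
    y <- rbinom(n, 1, 0.5)
    run_category_scan(B, y)$lambda_gc
  })
  expect_gt(mean(lams), 0.93)
  expect_lt(mean(lams), 1.07)
})

test_that("gene PTV tests apply the strict >10 singleton rule", {
  set.seed(19)
  n <- 800
  counts <- cbind(geneA = rbinom(n, 1, 10 / n),    # ~10 singletons
                  geneB = rbinom(n, 1, 40 / n))
  ## force exact counts
  counts[, "geneA"] <- c(rep(1, 10), rep(0, n - 10))
  counts[, "geneB"] <- c(rep(0, 100), rep(1, 40), rep(0, n - 140))
  gb <- list(burden = counts, total = rowSums(counts),
             n_variants = c(geneA = 10, geneB = 40))
  y <- rbinom(n, 1, 0.4)
  res <- gene_ptv_burden(gb, y, covariates = cbind(total = gb$total))
  expect_identical(res$skipped, "geneA")
  expect_identical(res$results$unit, "geneB")
  expect_equal(res$threshold, 0.05)
  ## sensitivity mode tests every gene
  res2 <- gene_ptv_burden(gb, y, covariates = cbind(total = gb$total),
                          min_singletons = 0)
  expect_setequal(res2$results$unit, c("geneA", "geneB"))
})

test_that("an enriched risk gene is detected with good power", {
  set.seed(20)
  hits <- 0
  for (r in 1:20) {
    n <- 3000
    y <- rbinom(n, 1, 0.35)
    ## carriers enriched in cases, OR ~= 3; the total-singleton covariate
    ## is dominated by the rest of the exome, as in a genome-wide analysis
    p_carrier <- ifelse(y == 1, 0.030, 0.010)
    gene <- rbinom(n, 1, p_carrier)
    other <- rbinom(n, 1, 0.02)
    background <- rpois(n, 3)
    gb <- list(burden = cbind(risk = gene, null = other),
               total = gene + other + background,
               n_variants = c(risk = sum(gene), null = sum(other)))
    res <- gene_ptv_burden(gb, y, covariates = cbind(total = gb$total))
    row <- res$results[res$results$unit == "risk", ]
    if (nrow(row) == 1 && row$p < 0.05 && row$estimate > 0) hits <- hits + 1
  }
  expect_gte(hits, 16)
})

test_that("gene-set burdens are additive and recover enrichment direction", {
  set.seed(22)
  n <- 1500
  genes <- paste0("g", 1:30)
  counts <- matrix(rbinom(n * 30, 2, 0.02), n, 30,
                   dimnames = list(NULL, genes))
  gb <- list(burden = counts, total = rowSums(counts),
             n_variants = setNames(colSums(counts), genes))
  y <- rbinom(n, 1, 0.4)
  sets <- list(s1 = genes[1:10], s2 = genes[11:20],
               union = genes[1:20])
  res <- gene_set_burden(sets, gb, y, n_comparisons = 2)
  ## linearity: the union burden is the sum of the two member-set burdens
  b1 <- rowSums(counts[, sets$s1]); b2 <- rowSums(counts[, sets$s2])
  bu <- rowSums(counts[, sets$union])
  expect_equal(bu, b1 + b2)
  expect_equal(res$threshold, 0.05 / 3)
  expect_equal(res$strict_threshold, 0.05 / 6)
  ## direction recovery: cases' singleton rate scaled by 1.13
  pos <- 0
  for (r in 1:20) {
    rate <- ifelse(y == 1, 0.02 * 1.13, 0.02)
    cnt <- matrix(rbinom(n * 10, 2, rate), n, 10,
                  dimnames = list(NULL, genes[1:10]))
    gb2 <- list(burden = cnt, total = rowSums(cnt),
                n_variants = setNames(colSums(cnt), genes[1:10]))
    r2 <- gene_set_burden(list(s = genes[1:10]), gb2, y, n_comparisons = 2)
    if (r2$results$estimate > 0) pos <- pos + 1
  }
  expect_gte(pos, 15)
  expect_error(gene_set_burden(list(bad = "nope"), gb, y), "empty")
})
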