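test_that("window enumeration matches the arithmetic of sizes and steps", {
  w <- enumerate_windows(c(chrA = 1e5), sizes = 5000, step_fraction = 0.5)
  full <- w[w$end - w$start + 1 == 5000, ]
  expect_equal(nrow(full), 39)
  expect_equal(nrow(w), 40)                        # 39 full + clipped tail
  expect_equal(w$start, seq(1, 97501, by = 2500))
  expect_true(all(w$end <= 1e5))
  ## window larger than the chromosome: single clipped window
  w2 <- enumerate_windows(c(chrB = 3000), sizes = 5000)
  expect_equal(nrow(w2), 1)
  expect_equal(w2$end - w2$start + 1, 3000)
  ## two sizes: disjoint by size class, union of the single-size lists
  w3 <- enumerate_windows(c(chrA = 1e5), sizes = c(5000, 10000))
  expect_setequal(unique(w3$size), c(5000, 10000))
  expect_equal(nrow(w3[w3$size == 5000, ]), 40)
  expect_equal(nrow(w3),
               nrow(enumerate_windows(c(chrA = 1e5), sizes = 5000)) +
                 nrow(enumerate_windows(c(chrA = 1e5), sizes = 10000)))
})

scan_fixture <- function(n = 500, m = 240, n_win = 12, seed = 91,
                         protect = NULL) {
  set.seed(seed)
  ## n_win non-overlapping 5-kb windows, m/n_win rare variants in each
  per <- m / n_win
  pos <- as.integer(unlist(lapply(seq_len(n_win), function(k) {
    5000 * (k - 1) + sort(sample(4000, per))
  })) + 1L)
  maf <- runif(m, 0.005, 0.04)
  g <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m,
              dimnames = list(sprintf("S%04d", 1:n), NULL))
  lp <- rep(-0.3, n)
  if (!is.null(protect)) {
    idx <- which(pos >= protect$start & pos <= protect$end)
    lp <- lp + drop(g[, idx, drop = FALSE] %*% rep(protect$log_or,
                                                   length(idx)))
  }
  y <- rbinom(n, 1, plogis(lp))
  variants <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                         is_snv = TRUE, excluded = FALSE)
  windows <- data.frame(chrom = "chr1",
                        start = seq(1, by = 5000, length.out = n_win),
                        end = seq(5000, by = 5000, length.out = n_win),
                        size = 5000)
  list(genotypes = methods::as(methods::as(g, "dMatrix"), "CsparseMatrix"),
       variants = variants, windows = windows, y = y)
}

test_that("a single all-encompassing window reproduces the plain burden test", {
  fx <- scan_fixture(n = 300, m = 60, n_win = 12, seed = 92)
  big <- data.frame(chrom = "chr1", start = 1, end = 60000, size = 60000)
  scan <- window_burden_scan(fx$genotypes, fx$variants, big, fx$y)
  sel <- select_analysis_variants(fx$variants, fx$genotypes, "window")
  maf <- attr(sel, "maf")
  w <- beta_weight(pmax(maf[sel], 1e-12))
  burden <- as.numeric(fx$genotypes[, sel, drop = FALSE] %*% w)
  direct <- burden_logistic_test(burden, fx$y)
  expect_equal(scan$results$p, direct$p, tolerance = 1e-9)
})

test_that("null window scans are calibrated and protective windows rank first", {
  fx <- scan_fixture(seed = 93)
  scan <- window_burden_scan(fx$genotypes, fx$variants, fx$windows, fx$y)
  expect_gt(min(scan$results$p), 1e-4)   # nothing extreme under the null
  ## inject a strongly protective window
  fx2 <- scan_fixture(n = 900, seed = 94,
                      protect = list(start = 20001, end = 25000,
                                     log_or = -0.5))
  scan2 <- window_burden_scan(fx2$genotypes, fx2$variants, fx2$windows,
                              fx2$y)
  top <- which.min(scan2$results$p)
  expect_equal(scan2$results$start[top], 20001)
  expect_lt(scan2$results$direction[top], 0)
})

test_that("the effective-number-of-tests estimator recovers independence structure", {
  fx <- scan_fixture(n = 400, m = 500, n_win = 50, seed = 95)
  est <- estimate_effective_tests(fx$genotypes, fx$variants, fx$windows,
                                  fx$y, n_perm = 400, seed = 7)
  expect_gt(est$n_eff, 0.7 * 50)
  expect_lt(est$n_eff, 1.3 * 50)
  expect_equal(est$threshold, 0.05 / est$n_eff)
  ## duplicating every window halves the effective fraction
  wdup <- rbind(fx$windows, fx$windows)
  est2 <- estimate_effective_tests(fx$genotypes, fx$variants, wdup, fx$y,
                                   n_perm = 400, seed = 8)
  ratio <- est2$n_eff / nrow(wdup)
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.65)
  expect_error(estimate_effective_tests(fx$genotypes, fx$variants,
                                        fx$windows, fx$y, n_perm = 50),
               "n_perm")
})

test_that("a single window behaves like one test", {
  fx <- scan_fixture(n = 300, m = 20, n_win = 1, seed = 96)
  est <- estimate_effective_tests(fx$genotypes, fx$variants, fx$windows,
                                  fx$y, n_perm = 400, seed = 9)
  expect_gt(est$n_eff, 0.8)
  expect_lt(est$n_eff, 1.25)
})

test_that("permutation minima behave like scan minima under the null", {
  fx <- scan_fixture(n = 300, m = 200, n_win = 20, seed = 97)
  est <- estimate_effective_tests(fx$genotypes, fx$variants, fx$windows,
                                  fx$y, n_perm = 150, seed = 10)
  ## pooled permutation minima transformed by Beta(1, n_eff) are uniform
  u <- pbeta(est$min_p, 1, est$n_eff)
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("secondary analysis partitions at strict p < 0.05 and masks repeats", {
  fx <- scan_fixture(n = 400, m = 60, n_win = 12, seed = 98)
  win <- list(chrom = "chr1", start = 1, end = 60000)
  ## no repeat track: masked test equals the full-window test
  out <- secondary_window_analysis(win, fx$genotypes, fx$variants,
                                   repeat_track = NULL, fx$y)
  expect_equal(out$nonrepeat$p, out$full$p, tolerance = 1e-9)
  expect_true(all(out$fisher$p >= 0 & out$fisher$p <= 1))
  ## variants at exactly p = 0.05 go to the non-significant side
  expect_true(all(out$fisher$p[out$fisher$p == 0.05] >= 0.05))
  sig_n <- if (is.null(out$significant_subset)) 0 else
    out$significant_subset$n_variants
  nonsig_n <- if (is.null(out$nonsignificant_subset)) 0 else
    out$nonsignificant_subset$n_variants
  expect_equal(sig_n + nonsig_n, out$full$n_variants)
  ## with a repeat track covering part of the window, fewer variants remain
  rep_track <- interval_track("repeat",
                              data.frame(chrom = "chr1", start = 0,
                                         end = 30000, label = "SINE"),
                              multi_label = TRUE)
  out2 <- secondary_window_analysis(win, fx$genotypes, fx$variants,
                                    rep_track, fx$y)
  expect_lt(out2$nonrepeat$n_variants, out2$full$n_variants)
})

test_that("selecting the nominally significant subset is winner's-curse enriched", {
  better <- 0
  n_rep <- 15
  for (r in seq_len(n_rep)) {
    fx <- scan_fixture(n = 250, m = 40, n_win = 8, seed = 1200 + r)
    win <- list(chrom = "chr1", start = 1, end = 40000)
    out <- secondary_window_analysis(win, fx$genotypes, fx$variants, NULL,
                                     fx$y)
    if (!is.null(out$significant_subset)) {
      if (out$significant_subset$p <= out$full$p + 1e-12) better <- better + 1
    } else {
      better <- better + 1   # nothing nominal: no subset to capitalize on
    }
  }
  expect_gte(better, ceiling(0.75 * n_rep))
})
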