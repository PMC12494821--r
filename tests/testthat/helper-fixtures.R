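# Shared fixture builders; everything is generated in code at test time.

tiny_cohort_config <- function(seed = 42, ...) {
  args <- list(
    n = c(internal_case_BD = 60, internal_case_SZ = 90,
          internal_control = 150, external_control = 200),
    genome = c(chr1 = 1e6, chr2 = 1e6),
    n_variants = 3000,
    n_states = 40,
    n_genes = 30, gene_length = 15000,
    relatedness = list(n_dup = 1, n_po = 1),
    seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}

# deterministic toy genotype matrix (samples x variants)
toy_genotypes <- function(n = 50, m = 20, maf = 0.3, seed = 1) {
  set.seed(seed)
  g <- matrix(rbinom(n * m, 2, maf), n, m,
              dimnames = list(sprintf("S%03d", seq_len(n)), NULL))
  methods::as(methods::as(g, "dMatrix"), "CsparseMatrix")
}

# minimal sample table for covariate building
toy_samples <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             cohort = rep(c("internal_control", "external_control"),
                          length.out = n),
             sex = sample(c("XX", "XY"), n, replace = TRUE),
             reported_sex = NA, batch = "b1", stringsAsFactors = FALSE)
}

# independent brute-force two-sided Fisher p from ratios of choose()
brute_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- vapply(ks, function(k) {
    lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  }, numeric(1))
  p <- exp(logp)
  sum(p[p <= p[ks == a] * (1 + 1e-7)])
}
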