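#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix sparseMatrix drop0 colSums rowSums colMeans crossprod
#' @importFrom methods as is
#' @importFrom stats binomial coef glm median pchisq plogis pnorm prcomp
#'   qchisq quantile rbeta rbinom rnorm runif sd setNames uniroot var dhyper
#'   rpois complete.cases
#' @importFrom utils head read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a child RNG seed from a master seed and a stream offset, staying
## within the 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * offset) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Split 1:n into chunks of at most `size` consecutive indices.
chunk_indices <- function(n, size) {
  if (n == 0L) return(list())
  starts <- seq(1L, n, by = size)
  lapply(starts, function(s) s:min(s + size - 1L, n))
}

## Minor allele count/frequency from non-reference allele counts.
## `an` is the total number of counted alleles (2 * n_samples at full
## genotyping). Returns a list with ac (non-ref count), mac, maf.
allele_counts <- function(genotypes) {
  ac <- Matrix::colSums(genotypes)
  an <- 2 * nrow(genotypes)
  mac <- pmin(ac, an - ac)
  list(ac = as.numeric(ac), an = an, mac = as.numeric(mac),
       maf = as.numeric(mac) / an)
}
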