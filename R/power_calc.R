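## Analytic case-control single-variant power under a multiplicative
## odds-ratio disease model, and the detectable-OR solver.

#' Power specification for a single-variant case-control design
#'
#' @param raf risk allele frequency in the population.
#' @param or_per_allele per-allele odds ratio (multiplicative on the OR
#'   scale: heterozygote OR, homozygote OR^2).
#' @param prevalence disease prevalence K.
#' @param n_case,n_control sample sizes.
#' @param alpha significance level.
#' @param control_mode "screened" (controls are unaffected individuals,
#'   the default) or "population" (controls are an unscreened population
#'   sample). Unscreened external controls are closer to "population", but
#'   at the prevalences involved the two differ by at most a few percent
#'   power.
#' @param test "trend" (1-df allele-dosage trend, the default) or
#'   "allelic" (2x2 allele-count chi-square) non-centrality.
#' @export
power_spec <- function(raf, or_per_allele, prevalence, n_case, n_control,
                       alpha, control_mode = c("screened", "population"),
                       test = c("trend", "allelic")) {
  stopifnot(raf > 0, raf < 1, prevalence > 0, prevalence < 1,
            alpha > 0, alpha < 1, n_case > 0, n_control > 0,
            or_per_allele > 0)
  list(raf = raf, or = or_per_allele, K = prevalence, n_case = n_case,
       n_control = n_control, alpha = alpha,
       control_mode = match.arg(control_mode), test = match.arg(test))
}

#' Expected genotype frequencies under the multiplicative OR disease model
#'
#' Genotype frequencies are HWE in `raf`; per-genotype odds are
#' `odds0 * OR^g`, with the baseline odds solved by bisection (tolerance
#' 1e-12) so the population prevalence equals K. Case frequencies are
#' proportional to `P(g) * penetrance(g)`; control frequencies are the
#' population frequencies ("population" mode) or
#' `P(g) * (1 - penetrance(g)) / (1 - K)` ("screened" mode).
#'
#' @param spec a [power_spec()].
#' @return list(case, control: genotype frequency vectors over g = 0,1,2;
#'   penetrance; baseline_odds).
#' @export
disease_model_frequencies <- function(spec) {
  g <- 0:2
  p <- c((1 - spec$raf)^2, 2 * spec$raf * (1 - spec$raf), spec$raf^2)
  prev <- function(o0) sum(p * plogis(log(o0) + g * log(spec$or)))
  lo <- 1e-15; hi <- 1e15
  if (prev(lo) > spec$K || prev(hi) < spec$K)
    stopf("no baseline odds attains prevalence %g", spec$K)
  for (i in 1:200) {   # bisection to 1e-12 relative
    mid <- sqrt(lo * hi)
    if (prev(mid) < spec$K) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-12 * hi) break
  }
  o0 <- sqrt(lo * hi)
  pen <- plogis(log(o0) + g * log(spec$or))
  case <- p * pen / sum(p * pen)
  control <- if (spec$control_mode == "screened") {
    p * (1 - pen) / sum(p * (1 - pen))
  } else p
  list(case = case, control = control, penetrance = pen, baseline_odds = o0)
}

ncp_trend <- function(case, control, n1, n2) {
  x <- 0:2
  r <- case * n1; n <- n1 + n2; N <- r + control * n2
  n * (n * sum(x * r) - n1 * sum(x * N))^2 /
    (n1 * n2 * (n * sum(x^2 * N) - sum(x * N)^2))
}

ncp_allelic <- function(case, control, n1, n2) {
  p1 <- (case[2] + 2 * case[3]) / 2
  p2 <- (control[2] + 2 * control[3]) / 2
  pb <- (n1 * p1 + n2 * p2) / (n1 + n2)
  (p1 - p2)^2 / (pb * (1 - pb) * (1 / (2 * n1) + 1 / (2 * n2)))
}

#' Analytic power for a single-variant case-control test
#'
#' Non-centrality of the 1-df genotype trend (allele dosage) chi-square at
#' the expected case/control genotype frequencies and sample sizes; power
#' is the upper tail of the non-central chi-square(1, ncp) beyond the
#' central `1 - alpha` quantile. At OR = 1 the power equals alpha exactly.
#'
#' @param spec a [power_spec()].
#' @return power in (0, 1).
#' @export
power_cc <- function(spec) {
  m <- disease_model_frequencies(spec)
  ncp <- switch(spec$test,
                trend = ncp_trend(m$case, m$control, spec$n_case, spec$n_control),
                allelic = ncp_allelic(m$case, m$control, spec$n_case,
                                      spec$n_control))
  pchisq(qchisq(1 - spec$alpha, 1), df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Odds ratio detectable at a target power
#'
#' Bracketed bisection of [power_cc()] over OR in (1, 100) to tolerance
#' 1e-6.
#'
#' @param spec a [power_spec()] (its `or_per_allele` is ignored).
#' @param target target power (default 0.80).
#' @return the solved per-allele OR.
#' @export
or_for_power <- function(spec, target = 0.80) {
  stopifnot(target > 0, target < 1)
  f <- function(or) {
    s <- spec; s$or <- or
    power_cc(s) - target
  }
  if (f(1 + 1e-4) > 0 || f(100) < 0)
    stopf("target power %g not bracketed by OR in (1, 100)", target)
  uniroot(f, c(1 + 1e-4, 100), tol = 1e-6)$root
}

#' Bonferroni threshold table
#'
#' The multiple-testing constants used across the analysis families, as
#' one audited table: the exact fraction and the value to the precision at
#' which it is conventionally printed. The two-tier gene-set threshold
#' halves the printed single-tier value (0.017 -> 0.0085).
#'
#' @return data.frame(name, numerator, denominator, exact, printed).
#' @export
bonferroni_thresholds <- function() {
  rows <- list(
    list("state",              0.05,  200,      signif(0.05 / 200, 2)),
    list("repeat",             0.05,  22,       signif(0.05 / 22, 2)),
    list("gene_ptv",           0.05,  1045,     signif(0.05 / 1045, 2)),
    list("gene_ptv_1pct",      0.05,  22178,    signif(0.05 / 22178, 2)),
    list("gwas",               5e-9,  1,        5e-9),
    list("gwas_multi",         5e-9,  7,        signif(5e-9 / 7, 2)),
    list("gene_set",           0.05,  3,        signif(0.05 / 3, 2)),
    list("gene_set_multi",     0.05,  6,        signif(0.05 / 3, 2) / 2),
    list("state_multi",        0.05,  200 * 7,  signif(0.05 / 1400, 2)),
    list("repeat_multi",       0.05,  22 * 7,   signif(0.05 / 154, 2)))
  out <- data.frame(
    name = vapply(rows, `[[`, character(1), 1),
    numerator = vapply(rows, `[[`, numeric(1), 2),
    denominator = vapply(rows, `[[`, numeric(1), 3),
    stringsAsFactors = FALSE)
  out$exact <- out$numerator / out$denominator
  out$printed <- vapply(rows, `[[`, numeric(1), 4)
  out
}
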