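---
title: "Batch-aware rare-variant burden testing: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch-aware rare-variant burden testing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(statewiseburden)
```

# What this package does

`statewiseburden` implements a whole-genome rare and low-frequency variant
association workflow for case-control sequencing studies that enlarge their
control group with externally sequenced, psychiatrically unscreened
individuals. The scientific difficulty it addresses is that the internal and
external cohorts are sequenced at different depths and by different centers,
so *differential variant calling* — not biology — can drive apparent
case-control differences whenever rare variants are aggregated. The package
provides:

* beta(MAF, 1, 25)-weighted logistic burden tests over genome annotation
  states (a 200-state chromatin/conservation partition), 22 genomic repeat
  categories, genes (singleton protein-truncating variants) and sliding
  windows of 5–50 kb;
* genomic-control lambda diagnostics for every test family;
* sequencing-metadata principal components as batch-effect covariates;
* sample QC: hard filters, KING-robust kinship with relatedness pruning at
  0.0409, LD pruning (`500000 5 0.2`-style) and genetic PCs;
* covariate-adjusted single-variant logistic tests (MAC > 20) with a Firth
  fallback, and exact two-sided Fisher tests for the low-MAC secondary
  analysis of a target window;
* a permutation-calibrated effective-number-of-tests estimate for the
  window scan;
* an analytic case-control power module under a multiplicative
  odds-ratio disease model; and
* a synthetic cohort generator that reproduces the two-cohort data
  structure end to end, with a complete truth record.

# The burden model

For a comparison between two groups (case vs control, or internal control
vs external control), the analyzed variant set contains bi-allelic SNVs
with MAF < 0.05 *recomputed on that comparison's samples*, excluding
variants in the exclusion-list track. Each variant receives the Beta(1, 25)
density weight at its MAF,

$$ w(m) = 25\,(1 - m)^{24}, $$

which approaches 25 for singletons and falls below 7.3 at the 5% boundary.
For a category $c$ (state, repeat class, gene, window) the per-sample
burden is the weighted non-reference allele count
$B_{sc} = \sum_{v \in c} w(m_v)\, g_{sv}$. The test is a maximum-likelihood
logistic regression of group status on $B_{sc}$ with a two-sided Wald
p-value on the burden coefficient. Covariates are the first 10 genetic PCs,
sex, sequencing batch (internal-only comparisons), and the per-sample
total weighted burden over the comparison's analyzed set; the
`base+metaPCs` model adds the first four sequencing-metadata PCs. The
burden is standardized to unit variance by default, so reported ORs are
per SD of burden; gene-level PTV tests use raw counts (weights of 1,
per-allele ORs).

Separation or non-convergence — realistic for rare-variant burdens with
unbalanced outcomes — triggers a Firth (Jeffreys-prior) penalized refit,
flagged in the output. A constant burden yields a flagged degenerate row
with p = 1 rather than an error, so category scans never die mid-family.

The Wald statistic was chosen over the likelihood-ratio or score statistic
because the family-wide diagnostics only require a consistent convention;
it is isolated behind one function (`wald_logistic`) so the convention can
be swapped in one place.

# Genomic-control lambda and its sampling noise

For a family of p-values, $\lambda_{GC}$ is the median of
$\chi^2_1$-quantile-transformed p-values divided by
$\mathrm{qchisq}(0.5, 1) \approx 0.4549$. An important practical point,
verified by simulation during development: over a family of only 200
tests, the *sampling SD of $\lambda_{GC}$ is about 0.17 even under perfect
calibration* (the median of 200 draws is noisy). Single-run lambda values
for 200-category scans therefore scatter roughly between 0.8 and 1.3
under the null. All calibration claims in this package's tests are made
on replicate means or on pooled p-value families; window-scan and GWAS
lambdas (tens of thousands of tests) are tight enough to read per run.

# Sequencing-metadata PCs

Per-sample sequencing QC metrics (mean depth, contamination, completeness
at depth 10, and several depth-correlated quality metrics) are
median-imputed, z-standardized and decomposed by PCA; the first four
components are used as covariates. When metric variation is driven by a
single latent depth, the first component carries nearly all the variance
and the four together act as a flexible (piecewise-linear in the metric
basis) adjustment for depth-dependent calling behavior. This mirrors the
observation that such PCs are almost entirely depth-driven in practice.

# Sample QC

* Hard filters: contamination > 5%, fewer than 98% of sites at depth ≥ 10,
  or reported-vs-genetic sex mismatch.
* Kinship: the KING-robust within-pair estimator
  $\varphi = (N_{Aa,Aa} - 2N_{AA,aa}) / (N_{Aa,i} + N_{Aa,j})$ on common
  (MAF > 5%) variants, computed for all pairs via blockwise
  indicator-matrix cross-products. The formula comes from the KING
  publication; identical genomes give exactly 0.5. The null SD of
  $\varphi$ is ≈ $0.92/\sqrt{m}$ for $m$ variants, so the default caps the
  kinship variant subset at 12,000 — enough that chance exceedances of the
  0.0409 third-degree threshold are rare among millions of pairs.
* Relatedness pruning: duplicates are resolved first with cohort priority
  (internal retained over external); remaining related groups are resolved
  by seeded-random greedy removal of the highest-degree node until no edge
  above 0.0409 remains. This handles chains and groups larger than two and
  is verified against an all-pairs check in the tests.
* LD pruning: greedy left-to-right within 500-kb windows at $r^2 > 0.2$,
  MAF > 5%, implemented with blocked BLAS correlation so cohort-scale
  inputs run in seconds.
* Genetic PCs: exact eigendecomposition up to ~2,500 samples, a
  randomized range-finder (two power iterations, flagged in the result)
  above that. Sign convention: the largest-magnitude score of each
  component is positive.

# The sliding-window scan and its multiplicity

Windows of 5, 10, 15, 20, 25 and 50 kb advance by half their size
(the stepping is the package's own choice, isolated as
`step_fraction`). Each window's weighted burden is tested with the same
engine and covariates as the state tests. Because overlapping windows are
strongly dependent, the scan-wide threshold uses an effective number of
tests: outcome labels are permuted *within deciles of the covariate-only
linear predictor* (plain permutation would break the covariate structure
and overstate the effective count), the scan minimum p is recorded per
permutation, and $\hat n_{\mathrm{eff}} = -R / \sum_r \log(1 -
p^{(r)}_{\min})$ is the Beta(1, n) maximum-likelihood fit to the minima.
The scan threshold is $0.05/\hat n_{\mathrm{eff}}$. For m independent
windows the estimator recovers ≈ m; fully duplicated windows halve the
ratio, as the tests verify.

The secondary analysis of a target window re-tests it after removing
repeat-region variants, computes per-variant exact two-sided Fisher tests
on allele counts (appropriate below the MAC > 20 regime of the
single-variant scan), and re-runs the burden test on the nominally
significant (p < 0.05, strict) and non-significant partitions. The
partitioned p-values are reported for what they are — a winner's-curse
diagnostic, not an independent confirmation — and the tests assert the
selection effect explicitly.

# Power

The power module replicates a genetic power calculator for discrete
case-control traits. Genotype frequencies are HWE in the risk allele
frequency; per-genotype odds are $\mathrm{odds}_0 \cdot \mathrm{OR}^g$
with the baseline odds solved by bisection (tolerance $10^{-12}$) so the
population prevalence is matched exactly. Power is the upper tail of the
non-central $\chi^2_1$ at the central $1-\alpha$ quantile, with the
non-centrality of the 1-df allele-dosage trend test evaluated at the
expected genotype counts; an allelic-test variant is available for
sensitivity checks.

Two control models are supported. With `control_mode = "screened"`
(default), controls are unaffected individuals
($P(g\,|\,\mathrm{ctrl}) \propto P(g)(1 - f_g)$); with `"population"`
they are an unscreened population sample. At the prevalences involved the
two differ by at most a few percent power. The screened default was
chosen because the study-scale detectable ORs quoted for this design
(3.2/2.4/2.1, 3.4/2.5/2.3 at RAF 0.01; 1.76/1.53/1.43, 1.78/1.55/1.44 at
RAF 0.05, for 1,500/3,000/4,500 cases vs 11,000 controls at
$\alpha = 5\times10^{-9}$ and $7.1\times10^{-10}$) are all at or above
the minimal detectable OR under the screened model, whereas the strict
population-sample model leaves one of the twelve marginally short of 80%
power; the quoted values are thus consistent with the screened variant,
and `or_for_power()` under it reproduces them as conservative
(rounded-up) bounds.

# The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture. It
emulates the *structure* that the analysis assumes:

* four groups (two case groups, internal controls, external controls)
  with configurable sizes; defaults total 6,000 samples on a 2 × 10 Mb
  genome with 50,000 variants — sized so the full pipeline runs on one
  CPU in minutes, with every count configurable upward;
* a rare-skewed population MAF spectrum, Beta(0.2, 6) truncated to
  $[1/(2N), 0.5]$;
* two-way admixture (Beta(8, 2) proportions) driving logit-normal
  allele-frequency gradients (SD 0.3), so genetic PCs have real structure
  to find; HWE genotypes given each sample's frequencies;
* a 200-state annotation partition built from ~0.8-kb segments, 21 repeat
  classes plus an "overall" class covering ~50% of the genome, an
  exclusion list, and genes carrying PTV flags;
* spiked duplicate and parent-offspring pairs (duplicates copy genomes;
  parent-offspring share one transmitted allele per variant);
* depth-dependent differential calling (below); and
* disease models: retrospective case sampling with per-variant log-ORs in
  a configurable window for fixed group sizes, and a population-sampling
  mode (`assign_phenotypes()`) whose intercept is solved numerically to
  match prevalence (1% BD, 1% SZ, 2% combined by default).

Everything latent — population frequencies, admixture, depths, artifact
rates and eligibility, relative pairs, effect variants — is stored in a
truth record; recovery tests read latent state only through it.

## The differential-calling model, and why it is shaped this way

Each sample draws a latent depth from its cohort's distribution
(26.8 ± 5.5 internal, 36.8 ± 4.7 external). For rare variants
(MAF < 0.05), non-reference calls drop out with probability
`dropout_max · plogis((center − depth)/scale)` and spurious het calls
appear with probability
`spurious_base · plogis((depth − center)/scale)`, both multiplied by a
repeat-class factor: largest over the classes the variant overlaps, with
SINE (3) and simple repeats (2.5) most artifact-prone, other repeats 2,
and non-repeat sequence nearly clean (0.05). QC metrics are regenerated
as depth-driven functions plus small noise, including one metric with the
same logistic shape as the calling-rate curves, so the metadata PCs can
absorb the expected artifact given depth.

Three design points matter, all consequences of the synthetic scale
(50k variants rather than hundreds of millions):

1. *The artifact is diffuse and weak per variant, not concentrated and
   strong.* Per-unit burden inflation scales like
   $\sqrt{n_{\mathrm{variants}}} \times$ (relative composition
   deviation). A diffuse artifact therefore inflates 200-variant state
   aggregates while leaving 5-kb windows (~12 variants, composition
   deviations that self-average) and individual MAC > 20 variants
   essentially calibrated — reproducing the empirically observed ordering
   in which state scans inflate strongly, window scans and GWAS stay near
   1, and specific repeat classes (SINE, simple repeats) show the
   clearest enrichment.
2. *States must be coupled to repeat composition.* State labels are
   assigned conditionally on segment repeat coverage via per-state
   affinity anchors; without this coupling (i.e., states orthogonal to
   repeats) no state-level inflation can arise from a repeat-structured
   artifact, which is exactly why repeat classes are the diagnostic axis.
   Real chromatin/conservation states are strongly repeat-enriched or
   depleted, so the coupling mirrors reality.
3. *The overall artifact volume is bounded above.* The total weighted
   burden is a covariate in every test; if the artifact becomes a large
   share of the total burden, the total covariate becomes a proxy for
   cohort membership and suppresses all tests instead of absorbing the
   genome-wide shift. The default `spurious_base` of 2×10⁻³ keeps the
   cohort-mean artifact at a few percent of the total burden.

The rate curves saturate between the two cohort depth distributions
(center 31, scale 2), so the artifact is close to cohort-constant —
strong contrast between cohorts, little variance within — which keeps
internal-only comparisons calibrated.

## What the generator does not emulate

Linkage disequilibrium beyond ancestry gradients; X-chromosome
hemizygosity (autosomes only); realistic per-class repeat biology;
variant-quality scores or the upstream calling pipeline; and the sheer
variant density of real WGS. Passing calibration and recovery tests on
this generator demonstrates that the statistical machinery behaves as
designed under the assumed data structure — not that any particular real
dataset satisfies those assumptions.

# Numerical choices

* Logistic fits: IRLS with Cholesky solves and warm starts from the
  covariate-only null fit (coefficient tolerance 1e-8, clamped linear
  predictors at ±30); aliased covariate columns dropped by QR pivoting.
* Firth fallback: damped modified-score IRLS, used on separation,
  non-convergence, or |coefficient| > 15.
* Fisher exact: hypergeometric enumeration with the minimum-likelihood
  two-sided rule at relative tolerance 1e-7; degenerate margins give
  p = 1.
* lambda: zero p-values are clipped to the smallest positive double with
  a warning.
* PCA: exact vs randomized crossover at 2,500 samples; randomized solver
  uses 10 oversamples and 2 power iterations.
* All generator randomness derives from one 32-bit master seed through a
  fixed stream schedule, so outputs are byte-identical across runs.

# Problem sizes used in the shipped experiments

The calibration experiments in the test suite run the full pipeline
(generation, QC with kinship pruning and PCs, scans) at the default
6,000-sample / 50,000-variant scale, averaging state-scan lambdas over
replicates as discussed above; recovery experiments (SINE-class artifact,
protective windows) use 2,700-sample / 8,000-variant and
1,800-sample / 4,000-variant cohorts with 50 and 20 replicates
respectively, sizes at which the injected effects are unambiguous. The
acceptance script reruns the same computations at the same scales from a
single command-line seed.

# Known limitations

* The Wald convention can be conservative for extremely sparse burdens;
  the Firth fallback bounds but does not remove this.
* The effective-number-of-tests estimator assumes the permutation
  distribution of the scan minimum is Beta(1, n); heavy covariate
  imbalance between permutation strata would bias it.
* Kinship on a thinned variant subset trades a small number of chance
  removals for tractability; cohorts with real cryptic structure should
  raise `max_kinship_variants`.
* The generator's artifact model is a two-parameter logistic in depth;
  real center effects (chemistry, caller versions) are richer, which is
  precisely why the repeat-class and state diagnostics exist.
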