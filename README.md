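# statewiseburden

Whole-genome rare and low-frequency variant association testing for
case-control sequencing studies that combine an internally sequenced
case-control cohort with externally sequenced, unscreened controls — and the
batch-effect diagnostics that such a design demands.

## The problem

Enlarging the control group with externally sequenced individuals raises
power, but the two cohorts differ in sequencing depth and center. Rare
variants are exactly where calling is depth-sensitive, and burden-style
tests aggregate thousands of them, so differential calling masquerades as
association — concentrated in genomic repeat regions (SINEs, simple
repeats) and visible as inflation of the genomic-control lambda in
annotation-state burden scans while single-variant tests stay clean. This
package implements the full workflow:

- **Burden tests**: logistic regression of group status on the
  beta(MAF, 1, 25)-weighted non-reference allele count per category —
  200 annotation states, 22 repeat classes, genes (singleton PTVs, strict
  \>10-singleton inclusion), gene sets, and 5–50-kb sliding windows —
  with covariates (10 genetic PCs, sex, batch, total weighted burden) and
  an optional 4 sequencing-metadata PCs; Wald p-values with a Firth
  fallback on separation.
- **Diagnostics**: genomic-control lambda
  (median inverse-χ²₁ / 0.4549) per test family; Bonferroni tiers
  (0.05/200, 0.05/22, two-tier gene-set thresholds, 5×10⁻⁹/7, ...) as one
  audited table.
- **Sample QC**: contamination / coverage / sex-mismatch filters,
  KING-robust kinship with relatedness pruning at 0.0409 (internal samples
  retained over external duplicates), PLINK-style LD pruning, genetic PCs.
- **Single-variant tests** (MAC \> 20) and exact two-sided Fisher tests
  for low-MAC secondary analyses of a target window, with repeat masking
  and nominal-significance partitioning.
- **Window-scan multiplicity** by a permutation-calibrated effective
  number of tests (Beta(1, n) fit to permuted scan minima; threshold
  0.05/n).
- **Analytic power** for single-variant case-control designs under a
  multiplicative odds-ratio model, with a detectable-OR solver.
- **A synthetic cohort generator** reproducing the two-cohort structure:
  depth distributions 26.8 ± 5.5 vs 36.8 ± 4.7, ancestry-gradient allele
  frequencies, annotation states coupled to repeat composition,
  depth-dependent differential calling concentrated in repeat classes,
  spiked relatives, and prevalence-consistent disease models — with a full
  truth record for recovery testing.

## Worked example

Generate a synthetic two-cohort study, run QC, and scan the annotation
states for the internal-vs-external control comparison under both
covariate models:

```r
library(statewiseburden)

cohort <- generate_cohort(cohort_config(seed = 301))
qc     <- run_sample_qc(cohort, seed = 301)
run    <- run_comparisons(cohort, qc = qc,
                          comparisons = c("cc_ext", "BDSZ_int"),
                          analyses = "state", seed = 301)
run$lambda_table
#>   comparison analysis        model   lambda
#> 1     cc_ext    state         base 1.952565
#> 2     cc_ext    state base+metaPCs 1.063907
#> 3   BDSZ_int    state         base 1.236758
#> 4   BDSZ_int    state base+metaPCs 1.251059
```

The control-control state scan is strongly inflated under the base model
(λ ≈ 1.95): the two cohorts really do carry different rare-variant calls,
concentrated in repeat-rich states. Adding the four sequencing-metadata
PCs as covariates absorbs the depth-driven component and returns λ to ≈ 1.
The internal-only case-control comparison — same sequencing for both
groups — has no systematic inflation; its values here (≈ 1.24) illustrate
that a single 200-test λ has sampling SD ≈ 0.17, which is why the shipped
calibration experiments average λ over replicates and pool comparisons
(see the vignette).

The repeat-class scan names the culprit classes:

```r
rec <- sine_recovery_run(seed = 42)
round(c(or = rec$or_base, p = rec$p_base, p_metaPCs = rec$p_meta), 4)
#>        or         p p_metaPCs
#>    2.3204    0.0000    0.6044      # p = 9.8e-32 before adjustment
```

The deeper cohort shows a strong apparent SINE-class enrichment
(OR per SD of burden ≈ 2.3, p ≈ 10⁻³¹) that collapses by some thirty
orders of magnitude once metadata PCs are included — the signature of a
depth artifact rather than biology.

Power at the study scale:

```r
power_cc(power_spec(raf = 0.01, or_per_allele = 3.2, prevalence = 0.01,
                    n_case = 1500, n_control = 11000, alpha = 5e-9))
#> [1] 0.9999437
```

## Layout

| Path | Contents |
| --- | --- |
| `R/io_formats.R` | VCF/BED/TSV contracts |
| `R/synthetic_cohort.R` | generator, disease models, differential calling |
| `R/sample_qc.R` | filters, KING kinship, pruning, genetic PCs |
| `R/metadata_pcs.R` | sequencing-metadata PCs |
| `R/weights_annotation.R` | annotation joins, beta weights, burden matrices |
| `R/burden_tests.R` | burden engine, category scans, lambda, gene/PTV tests |
| `R/single_variant.R` | GWAS scan, Fisher exact |
| `R/window_scan.R` | window enumeration/scan, effective tests, secondary analysis |
| `R/power_calc.R` | power model, detectable-OR solver, threshold table |
| `R/pipeline.R` | QC + seven-comparison orchestration, diagnostic drivers |
| `vignettes/` | methods vignette (models, assumptions, design decisions) |
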