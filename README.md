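# repdx — TCR repertoire diversity, sharing and diagnostic modelling

`repdx` is an R package for analysing bulk TCRβ CDR3 clonotype tables from
multi-compartment cancer studies: tumor tissue (T), adjacent non-tumor
tissue (N) and peripheral blood (B), with an optional healthy-control blood
cohort. It is aimed at immunogenomics analysts who receive AIRR-style
clonotype tables (one row per clonotype per sample: `v_call`, `j_call`,
`junction`, `junction_aa`, `duplicate_count`) and need the standard
repertoire statistics plus a blood-based diagnostic model, reproducibly and
offline.

## What it computes

- **Diversity** — per-sample clonotype richness, Shannon entropy
  `H = -Σ p_i log p_i` (nats by default), top-100 clonality, and the
  entropy-vs-clonality Pearson correlation.
- **Sharing & clonal expansion** — for each patient, abundance-weighted
  (`f_XY|X`: reads of shared clonotypes / total reads) and richness
  (`c_XY|X`) sharing fractions for every tissue pair and the three-way
  T∩N∩B set; expansion degrees `E_T = f_TNB|T / f_TNB|B` and
  `E_N = f_TNB|N / f_TNB|B`; within- vs between-patient sharing; public
  clonotypes; chi-square association with clinical covariates.
- **Gene usage** — V / J / VJ relative-abundance matrices over a frozen
  48 × 13 = 624 pairing grid, Kruskal–Wallis + paired-Wilcoxon differential
  usage, dominant pairings (mean > 1%, p < 0.01), PCA on scaled VJ usage.
- **Diagnostics** — a ROC marker screen (AUC > 0.7 and |log fold change| ≥
  0.25) and a repeated equal-sampling LASSO logistic model: per repeat, a
  balanced training set (80% of cases + an equal number of controls),
  `cv.glmnet` at `lambda.min`, evaluation on the held-out imbalanced test
  set; mean ± sd metrics and feature-selection frequencies over repeats.
- **Synthetic cohorts** — a deterministic generator of multi-tissue patient
  repertoires and two-cohort blood panels with recorded ground truth
  (planted expansion, sharing, public clones and VJ usage shifts), so the
  entire pipeline is testable without patient data.

See `vignettes/repertoire-analytics.Rmd` for the models, parameter
defaults and design choices.

## Worked example

Simulate a six-patient T/N/B cohort and reproduce the headline repertoire
statistics:

```r
library(repdx)

sim <- simulate_tissue_cohort(sim_config(n_patients = 6, seed = 42))
div <- diversity_table(sim$set, level = "aa", k = 100)
aggregate(cbind(entropy, top_k_abundance) ~ tissue, div,
          function(x) round(mean(x), 3))
#>   tissue entropy top_k_abundance
#> 1      B   7.031           0.276
#> 2      N   3.942           0.901
#> 3      T   4.213           0.858

cc <- entropy_clonality_correlation(div)
sprintf("r = %.3f, p = %.2e", cc$r, cc$p)
#> "r = -0.969, p = 3.52e-11"

ov <- patient_overlap(sim$set)
round(colMeans(ov[, c("f_tnb_n", "f_tnb_t", "f_tnb_b")]), 4)
#>  f_tnb_n  f_tnb_t  f_tnb_b
#>   0.4860   0.3840   0.0379
```

Blood is far more diverse than tissue (entropy 7.03 vs ~4) and entropy
moves inversely with top-100 clonality (r = −0.97): both tissues are
dominated by expanded clones. The clones common to all three compartments
occupy ~49% of reads in adjacent tissue, ~38% in tumor, but only ~4% of
blood — the planted clonal-expansion structure.

Screen a case/control blood panel and fit the diagnostic model:

```r
sim2 <- simulate_cohorts(sim_config(n_case = 20, n_control = 60,
                                    effect_size = 8, n_diff_features = 20,
                                    seed = 42))
mat <- usage_matrix(sim2$set, "VJ")
lab <- sim2$set$meta$cohort[match(rownames(mat), sim2$set$meta$sample_id)]

mk <- roc_marker_test(mat, lab)
head(mk, 3)
#>            feature       auc      lfc  direction
#> 1  TRBV6-3_TRBJ1-3 1.0000000 2.019722 up_in_case
#> 2 TRBV12-4_TRBJ2-4 0.9958333 1.988600 up_in_case
#> 3 TRBV20-1_TRBJ2-6 0.9958333 1.995177 up_in_case

repeated_evaluation(mat, lab, n_repeats = 10, base_seed = 42)
#> classifier_report: 10/10 repeats completed
#>   auc          1.0000 +/- 0.0000
#>   accuracy     1.0000 +/- 0.0000
#>   sensitivity  1.0000 +/- 0.0000
#>   specificity  1.0000 +/- 0.0000
#>   precision    1.0000 +/- 0.0000
```

The screen recovers the planted 8-fold usage shifts (24 markers called, 20
planted) with correct directions, and the repeated LASSO separates the
cohorts perfectly at this effect size — the power analyses in
`tests/testthat/test-acceptance.R` track how recall and AUC fall toward
chance as the planted effect shrinks to 1.

## Pipeline / CLI

One YAML config drives the whole pipeline (simulate or read → validate →
diversity → overlap → usage → PCA → markers → classify), writing TSV/JSON
stage outputs and a manifest with file digests:

```r
run_pipeline(run_config("run.yaml"))
```

or from a shell: `Rscript inst/cli/repdx all --config run.yaml --out out/
--seed 1`.

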