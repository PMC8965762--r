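---
title: "TCR repertoire analytics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TCR repertoire analytics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(repdx)
```

## The analysis this package implements

`repdx` analyses bulk TCRβ CDR3 clonotype tables from a three-compartment
study design — tumor (T), adjacent non-tumor tissue (N) and peripheral blood
(B) — of the kind used to characterise hepatocellular carcinoma and to build
blood-based diagnostic classifiers. The input is one AIRR-style table per
sample (V call, J call, CDR3 nucleotide and amino-acid string, read count)
plus sample metadata. Five analyses sit on top:

1. **Diversity.** Per-sample clonotype richness, Shannon entropy
   $H = -\sum_i p_i \log p_i$ over clonotype frequencies, and top-$k$
   clonality (summed abundance of the $k$ most abundant clonotypes,
   $k = 100$ by default). Entropy and top-$k$ abundance are two views of the
   same expansion structure and are strongly negatively correlated.
2. **Sharing and expansion.** For each patient, the abundance-weighted
   fraction $f_{XY|X}$ (reads of shared clonotypes over total reads of the
   focal sample) and the richness fraction $c_{XY|X}$ (shared clonotypes
   over distinct clonotypes) for every tissue pair and for the three-way
   T∩N∩B set; the clonal-expansion degree
   $E_T = f_{TNB|T}/f_{TNB|B}$, $E_N = f_{TNB|N}/f_{TNB|B}$; within- vs
   between-patient sharing; public clonotypes (keys present in every blood
   sample); chi-square association of recurrent clonotypes with clinical
   covariates.
3. **Gene usage.** Samples × features relative-abundance matrices over a
   frozen gene grid (48 TRBV × 13 TRBJ = 624 VJ pairings), differential
   usage tests across tissues, dominant-pairing selection (mean abundance
   > 1% and omnibus p < 0.01), and PCA on z-scored VJ usage.
4. **Marker screen.** Per-VJ-pairing ROC AUC (rank statistic with midrank
   ties, identical to exhaustive pairwise win/tie counting) and log fold
   change with pseudocount; markers must satisfy $|\mathrm{lfc}| \ge 0.25$
   and $\max(\mathrm{AUC}, 1-\mathrm{AUC}) > 0.7$.
5. **Diagnostic harness.** Repeated equal-sampling LASSO logistic
   regression: per repeat, a balanced training set (80% of cases plus an
   equal number of controls), `cv.glmnet` with binomial deviance and
   10-fold stratified CV, evaluation on the held-out imbalanced test set;
   metrics aggregated as mean ± sd across repeats together with per-feature
   selection frequencies.

## Clonotype identity

Three keying schemes are supported: `aa` (CDR3 amino-acid string), `nt`
(nucleotide string) and the default `v_aa_j`
(`"<V gene>_<CDR3 aa>_<J gene>"`). The default matches the convention in
which public blood clonotypes are reported in the field; `aa`/`nt` are used
for diversity at the two CDR3 levels. Gene calls are always collapsed to
gene level (allele suffix truncated at `*`) because all usage analyses are
at gene resolution. Records lacking a field required by the active scheme
are excluded from that analysis but retained for others — this maximises
the information each analysis can use without imputation.

## Tunable parameters that matter

| parameter | default | unit / range | why this default |
|---|---|---|---|
| entropy base | $e$ (nats) | — | source analyses never state a base; log2 selectable |
| top-$k$ cut | 100 | clonotypes | the standard top-100 clonality statistic |
| key scheme | `v_aa_j` | — | matches reported public-clonotype strings |
| marker `lfc_min` | 0.25 | natural-log fold change | the screen's published threshold |
| marker `auc_min` | 0.7 | AUC | the screen's published threshold (strict >) |
| lfc pseudocount | 1e-4 | relative abundance | keeps lfc finite for absent features; order of one read in 10⁴ |
| `train_fraction` | 0.8 | of cases | reproduces the 35/8 split of a 43-case cohort (ceil rounding) |
| CV folds | 10 | — | `cv.glmnet` convention; stratified by class |
| decision threshold | 0.5 | probability | unstated upstream; configurable |
| prevalence window (clinical screen) | 47%–80% | of blood samples | keeps the "without" group large enough for a 2×k table |

## What the synthetic generator emulates — and what it does not

`simulate_tissue_cohort()` emulates the *statistical* structure the
analyses consume:

- **Blood** draws clone sizes from a shallow discrete power law
  (`rank^-0.55` over 1,500 clonotypes by default): high, even diversity.
- **T and N** draw from a 2.5× smaller clonotype pool with a steeper law.
  Each tissue clonotype has one intrinsic size weight shared between T and
  N — clone sizes of shared clones are correlated across adjacent tissues,
  which is what high T/N abundance-sharing means — and a planted expanded
  subset (20% of the T∩N-shared pool) is boosted multiplicatively:
  full `expansion_factor` (default 30) in N, half in T. The asymmetry makes
  the three-way shared set most abundant in N, less in T, and least in B,
  and is encoded structurally rather than left to sampling luck.
- **Recirculation**: 15% of tissue clonotypes (biased toward expanded ones)
  appear in blood at power-law tail frequencies, so tissue-blood sharing is
  low but non-zero and the expansion ratios $E_T, E_N \gg 1$.
- **Public clonotypes**: 3 keys injected into every blood sample at 0.5%
  each — the order of reported public-clone frequencies (≈0.17%–0.56%).
- **Two-cohort blood panels** (`simulate_cohorts()`): per-sample VJ usage is
  Dirichlet around a cohort base built from a power law over the 624
  pairings. The case base differs on exactly `n_diff_features` pairings
  (half up, half down, fold `effect_size`). The Dirichlet concentration
  (750) is calibrated to the coefficient of variation of published marker
  abundances (mean ± sd pairs such as 0.31% ± 0.20% imply a concentration
  near 750). Planted markers are restricted to pairings with baseline usage
  0.05%–0.5% — the range spanned by reported discriminative pairings —
  because a shift planted on an effectively absent pairing (Dirichlet
  α ≪ 1) is undetectable by any screen, which would test the generator
  rather than the method.

Not emulated: V(D)J junctional biology (no insertion/deletion model, no
back-translation consistency between nt and aa strings), sequencing error,
primer bias, and clinical covariate structure. A green recovery test
therefore establishes that the pipeline detects planted *statistical*
structure at the stated sizes and noise — not that it would behave
identically on any real cohort.

Determinism: one integer seed drives a run; per-patient substreams are
derived by a counter so individual patients are reproducible in isolation.
Identical seeds give byte-identical tables.

## Numerical and procedural choices

- **Entropy** uses the $0 \log 0 = 0$ convention and validates that
  frequencies sum to 1 within 1e-9.
- **Top-$k$ ties** at the cut are broken by key lexicographic order, making
  the statistic deterministic.
- **AUC** is computed from midranks, so it equals exhaustive pairwise
  win/tie counting including tied values.
- **Wilcoxon tests** use R's exact small-sample p-values when tie-free
  (verified against full permutation enumeration in the tests) and the
  normal approximation otherwise.
- **Chi-square** association uses no continuity correction: the statistic
  is exactly $\sum (O-E)^2/E$.
- **Bonferroni family** = the 3 pairwise tissue comparisons per feature,
  applied after the omnibus test; no cross-feature adjustment, mirroring
  the reporting convention of the source analyses.
- **"Paired Kruskal–Wallis"** is not a standard construct. The omnibus test
  is run as Kruskal–Wallis restricted to subjects contributing every
  compared group, with paired Wilcoxon signed-rank follow-ups on complete
  pairs. This keeps the omnibus rank test honest about its unpaired nature
  while honouring the pairing where a defined paired test exists.
- **PCA** is `prcomp` on centred, unit-variance features; zero-variance
  features are dropped with a warning; each component's sign is fixed so
  its largest-magnitude loading is positive, making scores reproducible.
- **LASSO** standardizes features internally; coefficients are reported on
  the standardized scale. λ is chosen at minimum mean cross-validated
  binomial deviance. Folds are stratified so no fold is single-class.
- **Split arithmetic** uses ceil for the training-case count
  (0.8 × 43 = 34.4 → 35), reproducing the 35/8, 70/412 sizes; sizes are a
  deterministic function of cohort sizes and the fraction, independent of
  seed. If the fraction would consume every case, one case is forced into
  the test set.
- **Expansion degree** is undefined when the three-way set has zero blood
  abundance; such patients are excluded and counted, never imputed. The
  cohort summary reports both the mean of per-patient ratios and the ratio
  of cohort means, because published values of this statistic cannot be
  attributed to a single convention.

## Degenerate inputs

Empty samples raise errors for fraction-valued statistics (0/0 has no
meaningful value); header-only input files are dropped with a warning;
records with unknown V/J genes or non-positive counts are rejected
(`strict`) or quarantined with reasons (`quarantine`); a constant feature
yields NA rather than a fabricated p-value; a single-class test set yields
NA AUC while threshold metrics remain defined.

## Known limitations

- Sharing is exact key identity; no sequence-similarity clustering.
- Only Shannon entropy and top-$k$ clonality are offered; no wider
  diversity-index family.
- The clinical-association screen tests 2×k tables marginally, with no
  multiplicity correction across clonotype–covariate pairs.
- The generator's realism claims are limited to the moments discussed
  above; in particular CDR3 strings are uniform random over 20 residues
  and carry no positional biology.
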