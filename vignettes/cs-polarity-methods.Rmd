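---
title: "Methods: CS polarity scoring, composition, survival and the RCSP model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CS polarity scoring, composition, survival and the RCSP model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspolar)
```

## The model

Tumor-associated macrophages (TAMs) polarize between a CXCL9-expressing,
immunostimulatory state and an SPP1-expressing, pro-tumor state, and the two
markers are rarely detected in the same cell. `cspolar` treats each patient
as the statistical unit and summarizes this axis as a single number, the CS
ratio.

**Adjusted mean counts.** For cell type $C$, patient $P$ and gene $G$, with
$m$ cells of type $C$:

$$\bar X_{P,C,G} = \frac{1}{m}\sum_{i=1}^{m} X^{(i)}_{P,C,G}$$

A patient-level scaling factor compares the patient's mean over the *full*
gene universe ($g$ genes) with the cohort average over the $N$ patients that
contribute cells of type $C$:

$$S_C(P) = \frac{\bar X_{P,C}}{\bar X_C},\qquad
  \bar X_{P,C} = \frac1g\sum_{j}\bar X_{P,C,j},\qquad
  \bar X_C = \frac1N\sum_{k}\bar X_{k,C}$$

and $\bar X^{adj}_{P,C,G} = \bar X_{P,C,G}\, S_C(P)$. The CS ratio is
$\bar X^{adj}_{P,TAM,CXCL9} / \bar X^{adj}_{P,TAM,SPP1}$.

Two properties are worth stating explicitly, because the test suite leans on
them:

* $S_C$ cancels exactly in the ratio, so the CS ratio equals the ratio of raw
  per-patient marker means. The scaling only matters when per-gene adjusted
  means are compared across patients (the association scan).
* $S_C$ *multiplies by* the patient's relative sequencing depth rather than
  dividing it out. We implement the formula as printed — it is the ratio that
  carries the biology — but users of per-gene adjusted means should be aware
  that deeper patients get larger adjusted values, not smaller.

All polarity statistics run on **raw counts**. The formula is defined on
counts; log-normalization is available (`lognorm_matrix()`) and is used where
the field normally uses it — signature scoring and marker correlations — but
is deliberately not applied before aggregation.

**Assumptions.** One latent polarity per patient that is stable across the
sampled regions; TAM identity correctly annotated upstream (clustering and
annotation are out of scope); enough TAM cells per patient for the marker
means to be informative (patients with zero TAM cells are excluded with a
warning, and the power helper below quantifies "enough").

## Parameters that matter

| Parameter | Default | Where | Why |
|---|---|---|---|
| `min_genes`, `max_genes` | 200, 5000 | `qc_filter` | detected-gene bounds per cell, inclusive; 199 detected genes is removed, 200 kept |
| `max_mito_frac` | 0.20 | `qc_filter` | mitochondrial count fraction on raw counts, prefix rule `MT-` (a curated list can be emulated by renaming) |
| `min_cells_per_gene` | 3 | `qc_filter` | genes detected in *three or fewer* cells are dropped (strictly more required) |
| `zero_policy` | `"exclude"` | `cs_ratio_*` | SPP1-zero patients have no defined ratio; a symmetric pseudocount (default 0.5) is the alternative |
| `rule` | `"median"` | `dichotomize` | high iff ratio > threshold; ties at the threshold go low; the immunotherapy-responder analysis uses a fixed 1.0 |
| `threshold` | 2.0 | `call_enrichment` | Ro/e strictly above 2 is "enriched" |
| `on_threshold` | 0 | `dichotomize_coexpression` | "on" means detected at all (count > 0); the cutoff is configurable because published analyses rarely print it |
| `r_min`, `q_max` | 0.3, 0.05 | `gene_polarity_correlation` | the convention for "associated": \|r\| > 0.3 and BH-FDR < 0.05 |
| `r_thresh`, `p_thresh` | 0.3, 0.05 | `pearson_filter` | both strict, p unadjusted as conventionally practiced for this screen |
| `cox_p_thresh` | 0.15 | `clinical_cox_filter` | permissive univariate screen |
| `nlambda`, `lambda_min_ratio` | 100, 1e-3 | `lasso_fit` | log-spaced grid from $\lambda_{max}$; LOOCV picks the MSE minimizer |

QC order is fixed: cells first (gene bounds, then mito), genes second, so a
gene's detection count refers to surviving cells. The filter is idempotent
and never reorders survivors.

## Composition and power

`compute_roe()` pools cells across patients within a tissue (the cohort-level
heat-table convention) and compares observed counts with the chi-squared
independence expectation $E_{ct} = \mathrm{row}_c\,\mathrm{col}_t/n$. Two
exact identities are tested: the marginals of $E$ equal those of $O$, and the
column-weighted row average of Ro/e is 1 for every cell type. A per-patient
stratified variant was considered and rejected as the default because the
published convention pools; pooling is also what the ratio's normalization
identity assumes.

`min_cells_required(freq, k, prob)` answers the design question "how many
cells must I capture so that a population at frequency `freq` yields at least
`k` cells with probability `prob`": the smallest $n$ with
$P(X \ge k) \ge prob$, $X \sim \mathrm{Binom}(n, freq)$, found by bracketing
plus binary search on the exact tail — no normal approximation. This is the
single-cluster binomial marginal of the multinomial capture problem; for one
target cluster it is exact.

## Exclusivity and signatures

The 2×2 mutual-exclusivity table dichotomizes both markers at `count > 0`
within TAMs. The odds ratio is the sample cross-ratio $(ad)/(bc)$ — 0 or
$\infty$ when an off-diagonal/diagonal product vanishes — not the conditional
MLE some software reports; the p-value is the standard two-sided Fisher exact
test. An odds ratio below 1 with small p is the mutual-exclusivity signature.

`signature_score()` reimplements the binned-control module score in
simplified form: 25 average-expression bins, 100 control genes per set gene,
sampled with replacement under a fixed seed. Exact parity with other
implementations is not claimed; the properties that are claimed (self-control
scores near zero, planted signatures separating planted states) are tested.

## Association scans

`gene_polarity_correlation()` correlates each gene's per-patient adjusted
mean with the CS ratio. Default is Spearman on the ratio — robust to the
ratio's heavy right tail; `method = "pearson"` uses the log ratio for the
conventional linear version. BH runs jointly across all (cell type, gene)
pairs; constant genes are skipped and counted as untested, and the summary
"fraction associated" divides by genes actually tested.

`preranked_enrichment()` is the weighted Kolmogorov–Smirnov running sum on
the correlation-ranked gene list. The null permutes gene labels, not samples:
expression is already aggregated per patient, so sample permutation has no
meaning here. At weight 0 the score is the classical KS statistic, bounded in
$[-1, 1]$, and reversing the ranking flips its sign exactly — both are
tested, as is agreement of the weighted score with an independent
implementation.

## Survival machinery

Kaplan–Meier, log-rank and Cox fits delegate to the `survival` package
behind small wrappers that enforce this package's contracts (positive times,
binary events, loud failures on constant covariates, too few events, or
monotone likelihoods). Ties use Efron's method by default — the common
default in survival software; the duplication identity (doubling the data
leaves $\hat\beta$ fixed and shrinks the SE by $\sqrt2$) holds exactly under
Breslow and is tested under that setting. Confidence intervals are Wald-type.
Each wrapper is checked against a hand-rolled oracle: the product-limit
estimator by explicit loop, the log-rank $\,(O-E)^2/V$ by direct summation,
and the vanishing partial-likelihood gradient at the estimate.

## The RCSP model

Stage 1 (RadScore): features are z-scored on the training cohort; those with
$|r| > 0.3$ and $p < 0.05$ against the continuous CS polarity survive;
LASSO with leave-one-out CV (one fold per training sample, MSE criterion,
100-point grid to $10^{-3}\lambda_{max}$) picks the final set; the RadScore
is the frozen linear combination, intercept included and unpenalized. The
LASSO target is the *continuous* polarity — the model is evaluated by
correlation with the measured ratio — with a logistic variant available via
`family = "binomial"` for the dichotomized group.

Stage 2 (RiskScore): clinical covariates passing a univariate Cox screen at
$p < 0.15$ join the RadScore in a multivariable Cox model;
$RiskScore = \hat\beta_{Rad}\,RadScore + \sum_j \hat\beta_j X_j$, and the
training-median threshold is frozen into the model. Ties at the threshold go
to the low-risk group.

Leakage discipline is structural: the model object stores training feature
means/sds, coefficients and the threshold; `apply_model()` only reads them.
A test fingerprints the model bytes before and after validation and permutes
validation rows to confirm nothing training-side moves.

## The synthetic generator

`generate_sc_cohort()` plants one latent polarity $z_P \sim N(0,
\sigma_z)$ per patient. A cell of type $C$ with coupling $k_C$ has CXCL9
rate $\mu e^{+k_C z_P}$ and SPP1 rate $\mu e^{-k_C z_P}$ in expectation.
TAM cells additionally carry an anti-correlated Bernoulli state $w = \pm 1$
entering both marker log-rates as $k(z_P + w)$, normalized by $\cosh(k)$ so
the patient-level means above hold exactly; this is what makes the two
markers mutually exclusive cell by cell, and it vanishes continuously as the
coupling goes to 0 — the property the null-calibration tests rely on. Counts
are negative binomial (variance $\mu + \phi\mu^2$, $\phi$ configurable,
default 0.5) because downstream statistics must tolerate overdispersion; a
Poisson generator would flatter them. Non-marker genes sit at the base rate,
a few with an `MT-` prefix so the QC path is exercisable. Bulk TPM, survival
(exponential hazards, $h_0\,HR^{-z_P}$, uniform censoring) and feature
tables (informative block $=$ weights $\times\ z_P$ + Gaussian noise, noise
block standard normal, column order shuffled) derive from the same planted
truth.

Defaults describe the study conditions: 24 patients (the single-cell cohort
scale this method targets), 300 cells each across normal/peritumor/core with
TAMs enriched toward the core, 200 genes, TAM coupling 1 with weaker (0.5)
coupling in T cells and fibroblasts for the cross-cell-type coordination,
polarity SD 1, 5 informative among 100 features, hazard ratio 3 per polarity
unit, 30% censoring. Feature noise SD is 0.3 by default; effect sizes for
the marker coupling in real tumors are unknown, so these values were chosen
once for testability, not realism, and are stated here rather than revisited.

What the generator does *not* emulate — and hence what green tests do not
demonstrate about real data: ambient RNA and doublets, per-gene baseline
heterogeneity and library-size gradients, spatial structure, batch effects
across studies, non-exponential hazards, and correlated (rather than
independent-noise) radiomics features. Passing tests show the estimators
recover the planted structure under overdispersed counts; they do not
validate the biology.

## Numerical choices and degenerate inputs

* Exact identities (scaling cancellation, Ro/e marginals) are asserted at
  1e-12 relative; oracle equivalences at 1e-8 where an iterative fit is
  involved.
* Zero-denominator patients: excluded by default, pseudocount optional;
  zero-numerator patients keep ratio 0.
* All ratios identical under the median rule is an error (no split exists),
  as is an all-zero cohort mean (degenerate cohort).
* `fisher_exact_or` on an all-diagonal table reports `NaN` odds ratio with a
  defined p-value.
* Cox fits stop with the offending covariate on non-convergence, aliasing,
  or monotone likelihood (|beta| > 15 or non-finite SE is treated as
  separation).
* Tie-breaks are all documented and deterministic: median ties low, risk
  ties low, patient ranking ties lexicographic.
* Seeds: every stochastic operation takes an explicit seed; the generator's
  sub-streams (cells, bulk, survival, features) use fixed offsets from the
  config seed so the four tables are individually reproducible.

## Problem sizes in the shipped checks

The test-suite and `scripts/acceptance.R` run at sizes chosen to make the
statistical claims decidable in seconds to a couple of minutes on one CPU:
recovery on a 40-patient × 300-cell cohort; exclusivity detection over 50
replicate 10×150 cohorts and its null over 200 replicates at the default
24×300 scale (smaller cohorts make the exact test visibly discrete); RCSP
over 50 replicates at 41 training / 65 validation samples with 5 informative
among 100 features; 400/200/1000 replicates for the Cox-screen, Pearson-
filter and log-rank calibrations. Oracle equivalences run on instances of at
most a few dozen cells, subjects or table entries, where brute-force
enumeration is feasible.

## Known limitations

The scaling factor amplifies depth differences by construction (see above).
Ro/e pools patients, so one heavily sampled patient can dominate a tissue
column. The signature score's control sampling is simplified relative to
other tools. The RCSP stage starts at the feature table: image conversion,
segmentation and texture-feature extraction are out of scope, and externally
extracted features are expected as a samples × features CSV with an `id`
column and stable feature names.
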