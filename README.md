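# cspolar

Tumor-associated macrophages (TAMs) in hepatocellular carcinoma polarize
along a CXCL9 (immunostimulatory, anti-tumor) versus SPP1 (matrix-remodeling,
pro-tumor) axis, and the two markers are mutually exclusive at the single-cell
level. `cspolar` turns that observation into a per-patient statistic — the
**CS ratio** — and provides the analysis stages built around it, for
computational biologists working with multi-patient single-cell cohorts,
matched bulk expression, survival data, and radiomics feature tables.

## The statistic

For a cell type *C* (TAMs) and patient *P*, the per-gene mean raw count over
that patient's cells of type *C* is

    X̄_{P,C,G} = (1/m) Σᵢ X⁽ⁱ⁾_{P,C,G}

A patient-level scaling factor compares the patient's all-gene mean with the
cohort's:

    S_C(P) = X̄_{P,C} / X̄_C ,   X̄_{P,C} = (1/g) Σⱼ X̄_{P,C,j} ,
    X̄_C = (1/N) Σₖ X̄_{k,C}

and the adjusted mean counts are `X̄ᵃᵈʲ_{P,C,G} = X̄_{P,C,G} · S_C(P)`.
The patient's polarity is

    CS_Ratio(P) = X̄ᵃᵈʲ_{P,TAM,CXCL9} / X̄ᵃᵈʲ_{P,TAM,SPP1}

(the scaling factor cancels in the ratio; it matters for per-gene
comparisons). Patients are split into CS-high / CS-low at the cohort median.

Around this core the package implements: QC filtering of single-cell counts;
tissue enrichment Ro/e = observed / chi-squared-expected cell counts (> 2
called enriched); the dichotomized CXCL9/SPP1 mutual-exclusivity odds ratio
with Fisher's exact test; binned-control signature scoring; gene–polarity
association scans with BH correction; preranked gene-set enrichment;
Kaplan–Meier / log-rank / Cox survival machinery; and the two-stage **RCSP**
radiogenomic model (Pearson filter |r| > 0.3 & p < 0.05 → LASSO with
leave-one-out CV → RadScore → univariate-Cox-screened clinical covariates →
Cox RiskScore, stratified at the frozen training median). A synthetic-cohort
generator plants a latent per-patient polarity so that every stage is
testable end to end without patient data.

## Worked example

```r
library(cspolar)

cfg <- synthetic_config(n_patients = 40, cells_per_patient = 300, seed = 7)
sc  <- generate_sc_cohort(cfg)
ds  <- qc_filter(sc$dataset, min_genes = 20, max_genes = 5000)

am <- compute_adjusted_means(ds)          # TAM adjusted mean counts
pt <- dichotomize(cs_ratio_sc(am))        # CS ratio + median split
cor(pt$cs_ratio, sc$truth$patient_polarity[pt$patient], method = "spearman")
#> [1] 0.979925

fisher_exact_or(dichotomize_coexpression(ds))
#>       B_on B_off
#> A_on   373  1070
#> A_off  783   521
#> odds ratio = 0.232, Fisher exact p = <2e-16

round(compute_roe(ds)$ratio["TAM", ], 2)
#>      core    normal peritumor
#>      1.45      0.43      1.12
```

The Spearman correlation of 0.98 says the estimated CS ratio recovers the
planted latent polarity ordering almost perfectly; the odds ratio of 0.23
(p < 1e-15) quantifies the planted cell-level mutual exclusivity of CXCL9 and
SPP1 in TAMs; the Ro/e row shows TAMs enriched toward the tumor core and
depleted in normal tissue, as simulated.

For the radiogenomic stage:

```r
tr  <- generate_feature_table(sc$truth, cfg)
sv  <- as_survival_table(generate_survival(sc$truth, cfg))
mod <- train_rcsp(tr$features, sc$truth$patient_polarity, sv)
mod$risk_threshold                        # frozen training-median RiskScore
res <- apply_model(mod, tr$features, sv)  # or a validation cohort
res$logrank$p
```

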