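# aesurv — autoencoder-based multi-omics survival subtyping

`aesurv` discovers survival-relevant tumour subtypes from paired bulk
RNA-seq and DNA-methylation profiles, the design used in glioma cohort
studies where molecular heterogeneity is not captured by histological
grade. It is aimed at computational biologists who have two feature-by-
sample matrices and a clinical table with right-censored survival, and who
want an integrated low-dimensional representation, prognostic patient
groups, a transferable classifier, and the methylation-driven genes that
characterise the groups.

## The method

The integration step is a five-layer autoencoder
`d → 500 → 100 → 500 → d` with tanh hidden layers, a sigmoid output layer,
and the cross-entropy reconstruction loss

    L(x, x') = −Σ_k [x_k log x'_k + (1 − x_k) log(1 − x'_k)]
               + Σ_i a_w ‖W_i‖₁ + Σ_i a_a ‖F_{1→i}(x)‖₂²

with L1 weight penalty `a_w = 1e-4` and L2 activity penalty `a_a = 1e-3`,
trained by minibatch SGD with 50% dropout. Inputs are MAD-filtered,
robust-scaled (median/IQR, training statistics reused on validation data)
and min–max squashed into the open unit interval per feature.

The 100 bottleneck features are screened with univariate Cox
proportional-hazards models (Wald p < 0.05); the surviving features are
clustered by K-means with the cluster number k ∈ 2..6 chosen by the
Calinski–Harabasz index (silhouette reported, used for ties). Clusters are
named G1..Gk by decreasing median survival, so the last group has the
worst prognosis. Labels transfer through a top-100-per-omic ANOVA-F
selection and an RBF SVM under 10× Monte-Carlo 60/40 cross-validation
(Harrell's C-index, Brier score, log-rank p), and to external cohorts by
refitting on the features both cohorts share. Methylation-driven genes are
genes with Spearman r < −0.3 between methylation and expression and
Wilcoxon p < 0.05 on methylation between subtypes; a hypergeometric
over-representation test against user-supplied GMT gene sets summarises
them. A PCA pipeline (top-100 components through the identical downstream
machinery) serves as the baseline, and a synthetic-cohort generator with
planted subtypes, proportional-hazards survival and methylation-expression
coupling makes every stage testable offline.

## Worked example

```r
library(aesurv)

cohort <- generate_cohort(synthetic_config(n_samples = 200,
                                           n_genes_expr = 400,
                                           n_cpg_meth = 400, seed = 42))
cohort
#> Synthetic multi-omics cohort: 200 samples, 400 genes, 400 methylation features
#>   subtypes: G1 = 120, G2 = 80; events = 148 (26% censored)
#>   planted driver genes: 50

pipe <- autoencoder_pipeline(cohort$expr, cohort$meth, cohort$clinical,
                             seed = 42, epochs = 15)
pipe
#> Subtype pipeline (autoencoder): 58 survival-associated features, chosen k = 2
#>  G1  G2
#> 120  80

glance(pipe$subtypes, cohort$clinical)
#> # A tibble: 2 × 4
#>   subtype     n events median_time
#> 1 G1        120     80        471.
#> 2 G2         80     68        227.

logrank_test(pipe$subtypes, cohort$clinical)
#> # A tibble: 1 × 3
#>   statistic    df  p_value
#> 1      39.0     1 4.29e-10
```

58 of 100 bottleneck features are survival-associated; K-means on them
picks k = 2 and recovers the planted groups exactly (the G1/G2 counts
match the simulation), with G2 the poor-prognosis group (median survival
227 vs 471 days, log-rank p ≈ 4e-10).

```r
cv <- crossvalidate(list(expr = cohort$expr, meth = cohort$meth),
                    cohort$clinical, pipe$subtypes, seed = 42)
glance(cv)
#> # A tibble: 1 × 6
#>   n_folds c_index_mean c_index_sd brier_mean brier_sd logrank_p_geomean
#> 1      10        0.619     0.0169      0.423   0.0555         0.0000129
```

The held-out C-index (0.62) sits at the ceiling this simulation permits: a
two-group cohort with hazard ratio 3 bounds Harrell's C near 0.62 for any
risk score built from the group label — the oracle risk using the true
planted labels measures the same value (see the methods vignette).

```r
drv <- find_driver_genes(cohort$expr, cohort$meth, pipe$subtypes)
dplyr::count(drv, direction)
#> # A tibble: 3 × 2
#>   direction      n
#> 1 hypo_up       75
#> 2 hyper_down    75
#> 3 none         250
```

150 genes pass the driver rule: the 50 planted driver genes plus the 100
subtype-informative genes, whose methylation and expression were generated
with opposite subtype shifts and therefore genuinely satisfy the
negative-correlation criterion.

Each result type has `autoplot()` (Kaplan–Meier curves by subtype,
cluster-selection scores, training trajectory, driver overview) and
broom-style `tidy()`/`glance()` methods. `run_pipeline("config.yaml")`
drives the whole chain from a single YAML file and writes a manifest with
per-stage seeds and output digests;
`Rscript inst/scripts/run_pipeline.R --config config.yaml` does the same
from a shell.

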