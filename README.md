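# painvlab

Virtual-patient simulation of pregabalin pain response in painful diabetic
peripheral neuropathy (pDPN).

Pregabalin response in pDPN is heterogeneous: six-week pain trajectories
differ systematically across patient subgroups defined by sex, age, BMI,
insulin use, depression history, prior gabapentin, treatment regimen,
baseline pain and pain-related sleep interference (PRSI, both on the 0–10
NRS). `painvlab` implements a cluster-then-simulate ("virtual lab")
pipeline for clinicians' and modellers' what-if questions — *given this
patient's baseline profile, what trajectory cloud should we expect, and
will they reach a 30% or 50% pain reduction by week 6?* — and for studying
how observational and randomized-trial data can be combined to answer
them.

The pipeline, stage by stage:

1. **Clustering** — hierarchical agglomeration (Ward-style) on the Gower
   distance over nine mixed-type baseline variables; semipartial *R²*
   merge diagnostics; six-cluster cut.
2. **Coarsened exact matching (CEM)** — RCT patients matched to each OS
   cluster on coarsened covariates; multivariate L1 imbalance
   ½ Σ\_s |f\_s − g\_s| reported before/after matching.
3. **Lagged regressions** — per cluster, weekly pain
   y(t) = β₁·pain(t−1) + β₂·PRSI(t) + β₃·PRSI(t−3) + β₄·dose(t−3) +
   β₅·1[age 75+] + β₆·calm₀ + β₇·energy₀ (no intercept), selected
   stepwise by maximum likelihood and re-estimated with LASSO /
   adaptive LASSO / elastic net (`glmnet`).
4. **Microsimulation** — a novel patient is assigned to a cluster by a
   kNN + fuzzy-c-means ensemble, then simulated as `n` virtual instances
   whose weekly PRSI and dose are drawn from k-nearest-neighbour
   empirical distributions (k = √cluster size) and whose pain advances by
   the cluster regression, clipped to [0, 10].
5. **Extrapolation** — responder status beyond week 6 predicted from the
   cloud's trajectory monotonicity, (1/T) Σ sign(Δp), classified at
   ±0.2, via kNN against long-duration (12/13-week) trial patients.

A synthetic-cohort generator (`generate_cohort()`) reproduces the
statistical structure the pipeline assumes — six covariate-profiled
subgroups, OS visits only at weeks {0, 1, 3, 6} (imputed by Lagrange
quadratic interpolation), trial arms of 6 vs 12/13 weeks — so the whole
pipeline is testable without proprietary study data.

## Worked example

```r
library(painvlab)

coh     <- generate_cohort(cohort_spec(n_os = 600, n_rct = 300, seed = 1))
coh     <- inject_selection_bias(coh, 0.3)
series  <- interpolate_weeks(coh$series)
os      <- dplyr::filter(coh$patients, source == "OS")

clusters <- cluster_patients(os, n_clusters = 6)
#> <vlab_clusters> 600 patients in 6 clusters (sizes 97, 62, 158, 120, 113, 50)

ms <- match_clusters(clusters, dplyr::filter(coh$patients, source == "RCT"))
glance(ms)[, c("n_matched_os", "pct_os_matched",
               "mean_imbalance_reduction_pct")]
#>   n_matched_os pct_os_matched mean_imbalance_reduction_pct
#> 1          215           35.8                         81.7

labs <- matched_labels(ms)
fits <- fit_cluster_models(coh$patients, series, labs,
                           predictors = predictor_dictionary()$term,
                           method = "lasso")
fits[["2"]]
#> <vlab_fit> cluster 2 (lasso): 15 terms, adj R² 0.865, RMSE 0.309

novel <- os[os$patient_id == "P00011", ]
sim <- simulate_patient(novel, clusters, fits, series, labels = labs,
                        n_instances = 200, seed = 42)
sim
#> <vlab_sim> cluster 4 (confidence 1.00); 200 instances
#>   median final pain 2.72; responders 50%/30%: 94.0% / 100.0%;
#>   cloud monotonicity -0.998

pool <- long_duration_pool(dplyr::filter(coh$patients, source == "RCT"),
                           series)
extrapolate_status(sim, pool)
#> <vlab_extrapolation> monotonicity -0.998 (below_negative) -> maintained
#>   neighbours: decreased_pain=1, maintained=14, increased_pain=0
```

Reading the output: this patient lands in cluster 4; 94% of their 200
simulated trajectories reach a ≥ 50% pain reduction by week 6 (100% reach
30%), with a median final pain of 2.7 NRS points; the near −1 cloud
monotonicity says the simulated trajectories fall almost every week, and
14 of the 15 most similar long-duration trial patients kept their week-6
responder status through weeks 12–13, so the prediction beyond week 6 is
"maintained".

`run_pipeline(pipeline_config(...))` chains all stages — generation, bias
injection, imputation, clustering, matching, fitting, holdout validation,
simulation of validation patients, extrapolation, Fisher cluster
contrasts and covariate-combination coverage — and returns a report whose
`summary` row carries the headline metrics; `autoplot()` methods draw the
semipartial-R² scree, the L1 before/after bars, the trajectory cloud and
the extrapolation histogram.

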