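# drugrec

Cluster-based collaborative filtering for diabetes drug recommendation.

`drugrec` turns hospital-encounter records of diabetes inpatients (the
130-US-hospitals CSV schema: demographics, admission metadata, labs, and 24
per-drug dose-change columns) into top-N drug recommendations, and evaluates
how well those recommendations recover held-out prescribing decisions. It is
aimed at clinical-informatics researchers who want a reproducible, fully
offline implementation of the classic *cluster-then-recommend* pipeline:

1. **Preprocess** — deduplicate patients, drop under-medicated patients,
   rule-based variable selection (missingness, imbalance, drug prevalence),
   and transformation to a numeric per-patient feature table (one-hot race
   and ICD-9 disease categories, age-bracket midpoints, ordinal readmission).
2. **Cluster** — z-score the features, project onto principal components
   (smallest count reaching a cumulative explained-variance target), then
   group patients with K-means or DBSCAN, selecting the model with the best
   mean silhouette coefficient.
3. **Recommend** — encode each drug's dose-change token as a rating
   (`No` → 0, `Down` → 1, `Steady` → 1, `Up` → 2), and predict a patient
   `u`'s unobserved rating for drug `d` as the similarity-weighted mean over
   the patients `v` in `u`'s cluster that received the drug:

   r̂(u, d) = Σ_v sim(u, v) · r(v, d) / Σ_v sim(u, v),
   sim(u, v) = u·v / (‖u‖‖v‖),

   with cluster-mean and global-mean fallbacks when no neighbour exists.
   The top-N drugs by completed score form the recommendation list.
4. **Evaluate** — an 80/20 patient split; held-out patients are assigned to
   their nearest centroid from their *features* (never their ratings), their
   administered drugs are predicted from training patients only, and the
   report carries the mean squared error of predicted dose values plus the
   precision of the top-N list (a drug is *relevant* when its held-out dose
   value exceeds 1, i.e. an increased dose).

A synthetic encounter generator with planted cluster structure
(per-cluster demographic profiles, diagnosis mixes and deterministic
drug-dose signatures, with tunable noise) makes every stage testable without
downloading anything.

## Worked example

The package ships the worked 5-patient × 4-medication rating matrix with
cluster labels `{1, 2, 1, 3, 2}`:

```r
library(drugrec)
m <- example_rating_matrix()
cosine_similarity(m$ratings["patient_1", ], m$ratings["patient_3", ])
#> [1] 0.5477226        # = 3 / sqrt(30), hand-derivable

recommend_top_n(m, "patient_3", n = 3)
#> $drugs       [1] "medication_1" "medication_3" "medication_2"
#> $scores      [1] 2.000000 2.000000 1.333333
#> $provenance  [1] "observed" "neighbors" "global_mean"
```

Patient 3 received medication 1 with an increased dose (observed score 2);
medication 3 is predicted at 2.0 from the only same-cluster neighbour who
received it (patient 1); medication 2 has no in-cluster evidence and falls
back to the global mean of its observed ratings (4/3).

End to end on synthetic encounters:

```r
gen    <- generate_encounters(synthetic_config(n_patients = 1000, seed = 42))
report <- run_evaluation(gen$encounters, seed = 42)
report
#> Held-out evaluation (800 train / 200 test)
#>   clustering: kmeans, 6 clusters, silhouette 0.7606
#>   PCA: 5 components, 67.7% variance
#>   MSE (968 cells): 0.05433
#>   precision@3 (199 patients): 0.9296
```

Silhouette-based selection recovers the six planted patient groups; the
held-out dose error and precision quantify how much of the planted
prescribing signal the cluster-restricted collaborative filter recovers at
the generator's default noise level.

A thin command-line front end (`inst/cli/drugrec.R`) exposes the same
stages as subcommands (`simulate`, `preprocess`, `cluster`, `recommend`,
`evaluate`, `run-all`) over YAML/JSON configs.

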