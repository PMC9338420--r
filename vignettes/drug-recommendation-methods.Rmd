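---
title: "Methods: cluster-based collaborative filtering for diabetes drug recommendation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-based collaborative filtering for diabetes drug recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugrec)
```

## The problem and the model

Hospital encounter databases for diabetes inpatients record, per encounter,
which of ~24 antidiabetic drugs were administered and whether each dose was
increased (`Up`), decreased (`Down`), unchanged (`Steady`) or not given
(`No`). `drugrec` treats drug recommendation as user-based collaborative
filtering on these dose-change codes: patients play the role of users, drugs
of items, and the encoded dose change of the rating. Because a new patient
has no prescribing history, neighbourhoods are restricted to a patient
*cluster* discovered from clinical features — demographics, admission
metadata, utilisation counts, lab flags and diagnosis categories — so that a
patient can be routed to a peer group before any drug has been prescribed
(the new-user cold-start strategy).

The pipeline is: preprocess → standardise → PCA → cluster (model selection
by silhouette) → rating matrix → cluster-restricted prediction → top-N
recommendation → held-out evaluation.

## Preprocessing rules

`build_feature_table()` applies, in a fixed order:

1. **Deduplication** — one row per patient, keeping the *first* encounter in
   file order. (The convention for this data set; the order matters only
   when a patient's encounters disagree.)
2. **Medication filter** — patients with fewer than `min_medications`
   (default 2) administered drugs (token ≠ `No`) are removed; a patient with
   no medication carries no rating signal at all.
3. **Variable selection** (`select_variables()`), with one reason recorded
   per dropped column:
   - *missingness*: missing fraction > 0.50 (e.g. weight at ~97%
     missing, medical specialty at ~53%);
   - *irrelevant*: an explicit a-priori list — identifiers, payer code, the
     secondary/tertiary diagnoses, and thirteen drugs administered to a
     negligible number of patients in the source data;
   - *imbalance*: a single value covering > 95% of rows. This rule is
     applied to **non-drug columns only**: almost every individual drug is
     `No` for well over 95% of patients, yet low-prevalence drugs are
     governed by the dedicated prevalence rule below, so letting the
     imbalance rule see drug columns would silently delete the entire
     rating signal;
   - *prevalence*: drug columns administered to fewer than 0.5% of the
     surviving patients. Prevalence is computed after the explicit drops and
     after the medication filter; the default explicit list already names
     the rare drugs, so results do not hinge on this ordering choice.
   Missingness is evaluated before the explicit list, so a column that is
   both listed and mostly missing reports the more informative reason.
4. **Transformation** — gender and yes/no flags to 0/1; lab results
   (serum glucose, haemoglobin A1C) to performed/not-performed flags;
   readmission to an ordered severity code (none 0, after 30 days 1, within
   30 days 2); age brackets `[L, L+10)` to midpoints (5, 15, …, 95 years);
   race to five one-hot columns (missing race joins `Other`); the first
   ICD-9 diagnosis to nine one-hot disease categories keyed on the
   three-digit prefix (circulatory 390–459 & 785, respiratory 460–519 & 786,
   digestive 520–579 & 787, diabetes 250.xx, genitourinary 580–629 & 788,
   injury 800–999, musculoskeletal 710–739, neoplasms 140–239, everything
   else including V/E codes → other). The mapping is total: any unparseable
   code falls into `other` rather than erroring.

Missing values are only ever dropped, never imputed; after transformation
the table is fully numeric with no missing entries.

## Dose encoding

`No` → 0, `Down` → 1, `Up` → 2 are fixed anchor points: 0 must mean "not
administered" so that the rating matrix's zeros mark missing preferences,
and 1/2 encode the direction of dose change. `Steady` is not pinned down by
those anchors; the default maps it to 1, keeping "administered without
change" distinguishable from "not administered" while staying inside the
0–2 range. It is configurable (`preprocess_config(dose_encoding = …)`), and
any admissible encoding must keep `No` at 0 and be monotone
`No ≤ Down ≤ Up`.

## Clustering

- **Standardisation** uses the population standard deviation (denominator
  `n`). The choice is arbitrary but must be fixed for reproducibility; the
  sample convention is available via `method = "sample"`. Constant columns
  are a hard error at this stage — callers (e.g. `run_evaluation()`) drop
  zero-variance features first, since a constant feature carries no
  clustering information.
- **PCA** retains the smallest number of components whose cumulative
  explained-variance ratio reaches `var_target` (default 0.62); a fixed
  component count can be forced with `n_components`. Component signs are
  made deterministic by forcing the largest-magnitude loading of each
  component positive.
- **K-means** uses k-means++ seeding with `n_init = 10` restarts and Lloyd
  iterations (`stats::kmeans`, `iter.max = 300`), keeping the restart with
  the lowest inertia. All restarts derive from one seed (default 42).
- **DBSCAN** is implemented as connected components of the core-point graph
  (a point is *core* when it has ≥ `min_samples` neighbours within `eps`,
  itself included). Border points — non-core points within `eps` of a
  core — join the cluster of their *nearest* core point, ties to the lower
  label. Classic DBSCAN leaves border assignment order-dependent; this rule
  makes the labelling a pure function of the input. Noise is labelled 0.
- **Silhouette**: per point, `(b − a) / max(a, b)` with `a` the mean
  distance to the point's own cluster (excluding itself) and `b` the
  smallest mean distance to another cluster; singletons score 0 (the
  standard convention), and DBSCAN noise points are excluded from both the
  mean and the neighbourhoods — a clustering should not be rewarded or
  punished for points it explicitly refused to cluster. Distances are
  Euclidean on the PCA scores. The computation is exact (O(n²)) up to
  `max_n = 20000` points; above that a seeded subsample is scored.
- **Model selection** (`select_model()`) fits every K-means `k` in the
  range (default 2–10) and every DBSCAN grid point (default
  eps ∈ {0.3, 0.5, 0.8, 1.2, 2.0} × min_samples ∈ {5, 10, 20}), scores each
  by mean silhouette, and returns the argmax with a full leaderboard. Ties
  break toward fewer clusters, then K-means over DBSCAN (centroids enable
  assigning new patients), then the lower `k`/`eps`. Candidates that
  collapse to fewer than two clusters are unscored.

New patients are assigned to the nearest K-means centroid after applying
the stored standardisation and PCA projection; a DBSCAN model has no
centroids and refuses assignment rather than inventing a rule.

## Prediction and recommendation

The rating matrix keeps dense rows (zeros included) and cosine similarity
is computed on the full vectors, matching the worked 5 × 4 example matrix
the package ships (`example_rating_matrix()`); an all-zero vector has
similarity 0 by convention. Prediction, by contrast, averages only over
same-cluster neighbours with a *nonzero* rating for the target drug and
positive similarity — a non-prescription is treated as missing, not as
evidence for a dose of zero. The prediction is a plain similarity-weighted
mean without user-mean centring: on a 3-level ordinal scale where 0 means
"not administered", subtracting a per-patient mean would conflate how many
drugs a patient received with the direction of their dose changes.

Fallbacks, in order, when no neighbour qualifies: mean nonzero rating of
the drug within the cluster, then the global mean nonzero rating, then 0;
each prediction carries a `provenance` flag (`neighbors`, `cluster_mean`,
`global_mean`, `none`) recording which branch fired.

Top-N ranking sorts drugs by completed score — observed value where one
exists, predicted otherwise — breaking ties first by provenance
(observed/neighbour evidence outranks cluster-mean outranks global-mean)
and then alphabetically. The provenance step exists because the global-mean
fallback can tie a drug *nobody in the cluster ever received* with drugs
backed by genuine in-cluster neighbours; a fallback guess should not
displace evidence on an alphabetical technicality. Drugs the patient
already received are *not* excluded by default (recommendation lists in
this setting deliberately include prevalent in-cluster drugs), but
`exclude_administered = TRUE` is available.

## Evaluation protocol

`run_evaluation()` splits *patients* (never rating cells) 80/20 with a
seeded draw taken in sorted-id order, so the selected patients do not
depend on row order. Standardisation, PCA and clustering are fitted on the
training patients only; test patients are assigned to their nearest
centroid from their features — their ratings never enter any neighbourhood,
so there is no information leak from the test set.

- **MSE** averages the squared error over test cells with an *observed
  nonzero* rating (cell-averaged, not patient-averaged). Predicting the
  zeros would mix "no prescription" with dose error.
- **Precision@N** (default N = 3): a held-out drug is *relevant* when its
  observed dose value is strictly greater than 1 — an increased dose under
  the default encoding. Each test patient with at least one relevant drug
  contributes `|top-N ∩ relevant| / N`; patients with no relevant drug have
  an undefined numerator, are excluded from the mean, and are counted
  separately in the report.

## The synthetic-data generator

`generate_encounters()` emulates the structure the pipeline assumes: six
planted patient groups with size proportions (875, 910, 412, 1369, 646,
965)/5177, per-cluster demographic profiles (modal age bracket in the
45–85 band, modal race — one group entirely African American, one
Hispanic — and gender ratio), a modal diagnosis category per group, and a
deterministic per-drug dose signature over the ten retained drugs, with
insulin prevalent in three groups and absent from the other three. Raw
files come out in the full encounter schema, including `"?"` missing
markers for weight (97%) and medical specialty (53%), always-`No` rare
drug columns, and duplicate encounters at a configurable rate, so every
cleaning rule is exercised.

Two noise knobs govern difficulty. `sigma` jitters the count variables
(sd = `sigma` × a per-variable scale) and resamples each categorical value
— including each retained drug's token — with probability `min(sigma, 0.9)`;
at `sigma = 0` every patient reproduces its cluster signature exactly, which
is the signal-recovery limit the tests rely on (held-out MSE → 0,
precision → 1). `epsilon` draws a patient's entire record from a random
*other* cluster while the ground-truth label keeps the original, degrading
any recovery metric. Categorical resampling draws from the pool of
categories the profiles actually use: after z-scoring, a one-hot column
with near-zero prevalence places its carriers at enormous distances, and
uniform resampling over the full vocabulary would plant spurious
micro-clusters that have nothing to do with the configured structure.

The discrete parts of each profile are deliberately *unimodal* (one modal
age bracket, race and diagnosis category per cluster). A generator whose
clusters are themselves mixtures of discrete modes plants real sub-cluster
structure, and a silhouette criterion then has every right to prefer a
finer partition than the nominal G — the benchmark would be testing the
wrong thing. Ground-truth labels live in a sidecar table and are never
written into the data file, so no pipeline stage can read them.

What the generator does **not** emulate: temporally ordered encounters,
correlated comorbidity patterns across the three diagnosis fields, realistic
marginal distributions of the utilisation counts, or rating sparsity driven
by prescribing practice rather than cluster membership. Passing tests on
synthetic data therefore demonstrate that the machinery recovers structure
of the kind it assumes — not that real encounter data contains such
structure, nor that the headline metrics transfer to the real extract.

## Numerical choices and degenerate inputs

- Population-sd standardisation; zero-variance columns are errors at the
  algorithm level and are filtered (and logged) by the orchestration level.
- PCA sign fixing via the largest-magnitude loading; ties take the first
  index.
- Nearest-centroid ties take the lowest label; top-N ties are resolved by
  provenance then drug name; the selection leaderboard breaks silhouette
  ties toward fewer clusters.
- `silhouette_score` is exact to 20 000 points, then subsamples with a
  fixed seed.
- An empty candidate space, a clustering with a single cluster, a test set
  with no observed nonzero cell, and an infeasible synthetic signature
  (fewer administered drugs than `min_medications`) are all immediate
  errors, not silent degradations.
- Problem sizes in the shipped tests were chosen to keep the full suite
  fast while leaving the statistics stable: parameter-recovery sweeps use
  2000 patients × 10 seeds, the evaluation tests 300–1000 patients, and
  oracle-equivalence checks 100+ random instances of 15–60 points each.

## Known limitations

- Only user-based collaborative filtering is implemented — no item-based
  variant, latent-factor model, or drug-metadata features; new *drugs*
  (never prescribed to anyone) remain unrecommendable (item cold start).
- The silhouette criterion inherits its known bias toward convex,
  similar-scale clusters; DBSCAN results with heavy noise are compared on
  their non-noise points only.
- Dose-change codes are a coarse 3-level ordinal signal; MSE on this scale
  compresses clinically distinct errors.
- The preprocessing defaults reproduce a specific published analysis table
  on the real extract; other extracts of the same registry (different
  year ranges, recoded identifiers) may need adjusted thresholds, and the
  drop report is the tool for auditing that.
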