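# oncosepsis

Sepsis is a leading cause of death among patients with cancer, whose
immunosuppression makes early warning signs easy to miss. `oncosepsis` is an
R package for analysing sepsis risk in cancer cohorts from longitudinal
electronic health records (EHRs): it labels emergency-room (ER) visits by the
Sepsis-3 criteria, mines the co-prescription and laboratory signatures that
separate septic from non-septic visits, and evaluates how much those
signatures add to a predictive model beyond common EHR features. Because
hospital EHR extracts cannot be redistributed, the package ships a synthetic
cohort generator that reproduces the statistical structure the analysis
assumes, so the entire pipeline is runnable and testable out of the box.

It is aimed at clinical data scientists and biostatisticians who want a
transparent, fully tested reference implementation of this analysis pattern
for their own EHR extracts.

## What it computes

**Sepsis-3 labelling.** SOFA organ-failure scores (respiration, coagulation,
liver, cardiovascular, CNS, renal; each 0–4) are recomputed at every
measurement with last observation carried forward per component; unmeasured
components score 0. A suspected-infection window is the ±24 h interval around
a bacterial culture containing an intravenous antibiotic. A visit is labelled
sepsis when the SOFA total rises by ≥ 2 points within any window, relative to
the last pre-window total (0 if never measured).

**Co-prescription mining.** Same-day prescription baskets are mined with
FP-growth; a drug pair (D_i, D_j) is selected when its support

    S(D_i → D_j) = N(D_i, D_j) / N(s)

(co-occurring baskets over total baskets) reaches 0.05, separately per group.
Selected drugs become nodes of a co-prescription graph ranked by degree and
average shortest path.

**Drug-pair vectorization.** For each unordered pair of selected drugs, the
per-patient prescription-day counts (x, y) are mapped to three features:
interaction `I = x·y`, harmonized average `H = 2xy/(x+y)`, and arctangent
`T = atan2(y, x)`; k drugs yield `3·k(k−1)/2` columns.

**Lab screening.** Each lab test is compared between groups with Welch's
t-test; tests with p below a per-test α (default .001) enter the feature set,
with significance tiers (`*` < .05 … `****` < .0001).

**Model evaluation.** Five classifier families (logistic regression, a
20-tree random forest, a feed-forward net, a residual CNN, an LSTM) are
evaluated by stratified 5-fold cross-validation over three nested feature
sets (`ehr_only`, `ehr_drug`, `ehr_drug_lab`) with accuracy, AUROC, AUPRC,
precision, recall and F1. Feature contributions of the tree ensemble are
ranked by exact path-dependent Tree Shapley values.

## Worked example

```r
library(oncosepsis)

cfg    <- cohort_config(n_control = 200, n_sepsis = 100, seed = 42)
cohort <- generate_cohort(cfg)
result <- run_sepsis_pipeline(cohort, cfg, families = "random_forest",
                              n_folds = 5, seed = 1)
result
#> <sepsis_pipeline>
#>   visits labelled: 300  (sepsis 100 / nonsepsis 200)
#>   ground-truth agreement: 100.0%
#>   selected drugs: sepsis 14 / control 13 / union 14
#>   selected labs: 4
#> # A tibble: 3 × 6
#>   family        feature_set  accuracy auroc auprc    f1
#>   <chr>         <chr>           <dbl> <dbl> <dbl> <dbl>
#> 1 random_forest ehr_only        0.63  0.625 0.419 0.160
#> 2 random_forest ehr_drug        0.993 1     1     0.990
#> 3 random_forest ehr_drug_lab    1     1     1     1
```

Reading the output: the Sepsis-3 labeler recovered the generator's
ground-truth groups for every visit; 14 drugs passed the 0.05 support
threshold in the sepsis-group mining run (13 in the control run); 4 lab
tests passed the Welch screen at α = .001 at this cohort size; and the
cross-validated random forest is near-chance on common EHR features alone
but separates the groups once drug-relationship and lab features are added —
the synthetic cohort's group contrasts are deliberately clean, so the
improvement is far larger than one should expect on real hospital data.

The screened labs and the top-ranked Shapley features point back at the
simulated biology — depressed albumin and A/G ratio, prolonged prothrombin
time, and narcotic-analgesic co-prescription:

```r
head(result$lab_comparison[c("lab_type", "mean_sepsis", "mean_control", "p_value", "tier")], 4)
#>   lab_type   mean_sepsis mean_control     p_value tier
#> 1 ag_ratio         0.666         1.13 0.000000243 ****
#> 2 albumin          2.39          3.28 0.00000567  ****
#> 3 pt_percent      38.0          15.2  0.00000833  ****
#> 4 pt_sec           7.30          3.24 0.000226    ***

full  <- select_feature_set(result$features, "ehr_drug_lab")
model <- fit_sepsis_model(full, full$group_label,
                          model_config("random_forest", seed = 1))
rank_feature_contributions(model, data = dplyr::slice(full, 1:60), top_k = 5)$top_k
#> [1] "opioid_alkaloids__synthetic_narcotics__I"
#> [2] "antipyretic_a__synthetic_narcotics__H"
#> [3] "opioid_alkaloids__saline_solution__I"
#> [4] "opioid_alkaloids__synthetic_narcotics__H"
#> [5] "opioid_alkaloids__saline_solution__T"
```

`autoplot()` methods exist for the lab comparison table, the co-prescription
graph, cross-validation reports and contribution rankings; `tidy()` and
`glance()` methods summarise evaluation and ranking objects.

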