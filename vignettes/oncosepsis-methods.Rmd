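---
title: "Methods: sepsis-risk analysis for cancer cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sepsis-risk analysis for cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncosepsis)
```

`oncosepsis` implements a complete sepsis-risk analysis for cancer cohorts
from longitudinal EHR events. This vignette is the package's account of the
science: the models and procedures, the parameters that matter, the design
choices that were genuinely open, and what the synthetic data do and do not
show.

## The Sepsis-3 labelling procedure

Sepsis is operationalized as *suspected infection plus acute organ
dysfunction*. Organ dysfunction is measured by the SOFA score: six organ
systems (respiration by PaO2/FiO2, coagulation by platelets, liver by
bilirubin, cardiovascular by mean arterial pressure and vasopressor use, CNS
by Glasgow Coma Scale, renal by creatinine), each mapped to an integer 0–4
and summed to 0–24. The thresholds ship as a versioned, unit-annotated YAML
file (`inst/extdata/sofa_thresholds.yaml`) so the clinical lookup is
auditable and overridable rather than buried in code:

```{r}
str(sofa_thresholds()[c("coagulation", "renal")])
```

Three scoring conventions deserve note:

* **Missing components score 0** and are flagged in `components_missing`.
  This is the guideline convention for unmeasured baselines; it also means a
  patient with no measurements has SOFA 0, so an in-window total of 2
  suffices for a sepsis label on a first ER visit.
* **Respiration subscores 3–4 require respiratory support.** Without an
  `on_ventilation` flag the subscore is capped at 2.
* **Vasopressor dose tiers are collapsed to presence/absence** (any
  vasopressor scores the cardiovascular system 2). Source EHR extracts
  rarely carry reliable dose tiers; this is a documented limitation, not a
  claim that dose information is irrelevant.

*Suspected infection* is a bacterial culture with at least one intravenous
antibiotic administered within 24 hours either side (boundary inclusive;
route string `"IV"` matched case-insensitively; antibiotics identified by an
`is_antibiotic` flag in the drug catalog, since no standard code list is
assumed). Within each window, the labeler compares the maximum in-window
SOFA total against the last total strictly before the window (0 when never
measured) and labels the visit sepsis when the rise is ≥ 2 in any window;
when several windows qualify, the earliest is reported as the trigger — the
clinically conservative choice for onset timing.

The cadence of SOFA recomputation is not fixed by the definition; the
implementation recomputes at every timestamp carrying any new component
value and carries the last observation of each component forward. This is an
assumption, flagged here rather than asserted: alternative conventions
(fixed cadence, no carry-forward) would shift borderline labels.

## Observation window and preprocessing

Predictive features come from events 2–7 days *before* the ER visit — recent
enough to reflect the pre-septic state, but excluding the final 48 hours so
the model predicts in advance rather than describing established deterioration.
Visits with no retained event are dropped.

* Diagnosis codes are stripped of punctuation, uppercased and truncated to
  three characters (`"C22.0"` → `"C22"`).
* A lab test is retained only when strictly more than 60% of patients have at
  least one non-missing measurement of it.
* Extreme values are removed by a robust z-score: entries beyond `k = 5`
  scaled median absolute deviations from the median become missing. The rule
  is applied literally when the MAD is zero, so a constant feature is
  untouched while a lone extreme among identical values is removed. The
  specific rule (and `k`) is this package's choice; only the *existence* of
  an extreme-outlier step is inherited from the analysis being implemented.
* Missing values are imputed with the mean of the same (cancer type, sex,
  age) stratum. Exact-age strata are nearly empty in realistic cohorts, so
  "same age" is a 5-year bin (configurable); empty strata fall back by
  dropping age, then sex, then to the global mean. Imputation never drops
  rows.
* Categorical features are one-hot encoded as 0/1 columns, and every column
  carries a manifest entry (`name`, `source_stage`, `encoding`) from which
  the nested feature sets are carved.

Lab tests known to be ordered only for specific disease groups can leak the
outcome; the package takes a user-supplied exclusion list (`lab_exclude`)
rather than hard-coding test names.

## Co-prescription mining and the drug graph

Prescriptions of one patient on one day form a basket; the support of a drug
pair is the fraction of baskets containing both. Frequent itemsets are mined
with FP-growth (implemented in-package: frequency-ordered prefix-tree
insertion and recursive conditional-pattern-base projection, no candidate
generation), and pairs at support ≥ 0.05 are selected, separately for the
sepsis and control groups — the group networks are the object of interest,
and their differences (narcotic analgesics central in the sepsis network)
are the qualitative signal. Itemsets larger than pairs are mined naturally
but only pairs are graphed and vectorized, matching their downstream use.
Selected drugs become nodes with two topological attributes: degree and
average shortest path over the node's connected component (unweighted
breadth-first distances; no edge weights are defined for path computation).
An isolated node has an infinite average path and ranks last.

## Drug-pair relationship vectors

For patient-level features, each selected drug's prescription frequency is
its count of distinct prescription days in the observation window. A pair
with frequencies (x, y) maps to three scalars:

* `I = x·y` — the level of joint use;
* `H = 2xy/(x+y)` — the overall intensity, dominated by the weaker member
  (0 when both absent);
* `T = atan2(y, x)` — the pair's geometric angle in [0, π/2] as a single
  scale-invariant scalar (0 when both absent).

These functional forms are this package's reconstruction of a verbally
described triple (interaction / harmonized average / arctangent); the exact
published algebra is not legible in the source material. They are therefore
injected through a strategy interface (`relationship_strategy()`) so an
alternative reconstruction can be swapped in without touching the pipeline,
and no claim is made that these forms equal the original authors'. Useful
identities: I and H are symmetric, `T(x,y) + T(y,x) = π/2` for positive
frequencies, I scales quadratically and H linearly under joint scaling while
T is scale-invariant. The drug set used for vectorization is the union of
the two groups' selections (k drugs give `3·k(k−1)/2` columns; 31 drugs give
1395).

## Lab screening

Each lab's sepsis and control values are compared with a two-sided Welch
(unequal-variance) t-test — the source analysis says only "t test", and
unequal variances are the safe default for clinical labs. Tests are run
per visit, matching the feature table's unit of analysis (per-patient
aggregation would be the alternative; this is noted as an assumption).
Significance tiers are `*` p < .05, `**` p < .005, `***` p < .001, `****`
p < .0001: the published tier list repeats ".001", which this package reads
as a typo for .0001 (configurable). Selection uses a per-test α = .001 with
no multiple-testing correction, matching the original per-test usage; a
Bonferroni option exists but is off by default.

## Model evaluation

Classifiers are evaluated by stratified k-fold cross-validation (default 5;
assignment seeded). All preprocessing statistics that could leak —
feature centering and scaling — are fitted inside each training fold.
Six metrics are computed per fold: accuracy, AUROC (mid-rank
Mann–Whitney statistic), AUPRC (step integration of the precision–recall
curve, the average-precision convention), precision, recall and F1 at a 0.5
threshold (no threshold is prescribed by the source analysis; 0.5 is the
neutral default). Whether to aggregate as fold means or pooled predictions
is ambiguous in most published descriptions; the package computes both and
reports fold means as the headline.

Five families are provided. Logistic regression and the random forest
(default 20 trees) are fitted conventionally. The three neural families run
at smoke-test scale: the feed-forward net is a single-hidden-layer network,
and the residual CNN and LSTM are implemented as exact forward passes
(42×42 zero-padded single-channel images through seeded random 3×3
convolution filters with ReLU and residual addition; a standard LSTM cell
over zero-padded sequences) whose fixed random representations feed a
trained logistic readout. Training only the readout keeps these families
deterministic, dependency-free and fast while preserving their input-shape
conventions (the 1764-feature cap and zero-padding in manifest order for
the CNN; max-length padding for the LSTM); they are smoke-scale stand-ins
by design, not tuned deep models, and their performance should be read
accordingly. Grid search evaluates each candidate hyperparameter set by
inner cross-validation and picks the best mean AUROC, ties going to the
first-listed point.

Feature contributions are computed for the tree ensemble only, by exact
path-dependent Tree Shapley values implemented in-package (the polynomial
path algorithm; node covers recomputed by routing the training data through
each tree; verified in the test suite against exhaustive coalition
enumeration and the local-accuracy identity). Per-feature mean absolute
Shapley values are normalized to ratios summing to 1 and the top-k reported.

## The synthetic cohort generator

No hospital EHR extract can ship with the package, so the generator emulates
the statistical structure the analysis assumes. Its defaults are the
published cohort conditions:

* **Group sizes** 928 control / 455 sepsis; male fraction 52.8% / 71.2%;
  cancer mix (liver/lung/breast) 19.4/57.4/23.2% and 30.8/60.2/9.0%.
* **Age** normal (58.2, SD 11) and (60.3, SD 11) years clipped to [18, 95]
  (adults only); **weight** normal (63.7, SD 10.7) and (64.3, SD 11.3) kg.
  The published sepsis-group age SD of 0.5 (and total-cohort weight SD 0.9)
  are inconsistent with the ~11 scale of every neighbouring entry and are
  treated as typos.
* **Labs**: the eight tests whose group moments are published in running
  text (albumin 2.73/3.30 g/dL, total protein 4.77/5.27 g/dL, cholesterol
  81.06/111.46 mg/dL, A/G ratio 0.76/1.14, APTT 14.06/6.89 s, PT as %, INR
  and seconds) with their printed SDs. The remaining tests of the original
  64-test panel are not publicly tabulated; users supply their own rows.
* **Drugs** are abstract identifiers with per-group daily probabilities and
  same-day boost pairs; narcotic analgesics are boosted in the sepsis group
  so their pair exceeds support 0.05 only there. No pharmacology is
  simulated.
* **Trajectories**: every sepsis patient gets a culture shortly after ER
  arrival, an IV antibiotic on the culture date, and in-window measurements
  implying a SOFA rise ≥ 2 (thrombocytopenia, hypotension ± vasopressor,
  renal impairment) over a near-normal baseline; controls keep near-normal
  in-window values (rise ≤ 1), and 30% of them also receive a culture plus
  IV antibiotic so the window logic is exercised on nonsepsis visits.

Lab values flagged non-negative are drawn from a *moment-matched*
zero-truncated normal: the underlying location and scale are solved
numerically so the truncated draw has exactly the configured mean and SD.
Plain truncation at zero would inflate the mean (for the A/G ratio by ~0.18,
a quarter of the group difference) and silently break parameter recovery. A
zero-truncated normal cannot have mean ≤ SD, so labs whose printed SD
exceeds their mean (cholesterol, APTT, the PT family — plausibly
transformed quantities in the source) fall back to untruncated normal
draws; their configured moments are still reproduced exactly.

Determinism is a contract: identical configuration (including seed) gives
byte-identical cohorts, and cohorts round-trip exactly through the CSV
writer/reader (ISO-8601 UTC timestamps at whole-second resolution).

### What passing tests on synthetic data do and do not show

The generator produces *clean* group contrasts: trajectories that satisfy
the Sepsis-3 rule by construction (label recovery ≥ 95% is a design
property), drug contrasts far above the support threshold, and lab shifts at
exactly the published moments. Consequently the cross-validated AUROC of the
full feature set is near 1 on synthetic cohorts — far above what the same
pipeline achieves on real hospital data — and the nested-feature-set
ordering (labs + drugs ≥ EHR-only) is easy to reproduce. Passing tests
demonstrate that the pipeline's logic is correct and its statistics are
calibrated, not that the model would attain any particular performance on
real patients. Real EHR data add confounding, informative missingness,
coding drift and label noise that the generator deliberately does not
emulate; genomic, radiation and surgical-history fields are likewise out of
scope.

## Numerical choices and degenerate inputs

* Window and threshold boundaries are inclusive ("within 24 hours" read as
  ≤; support "0.05 or greater" as ≥, with an 1e-9 slack against floating
  count comparison; significance thresholds strict `<`).
* Welch's test on two zero-variance identical samples is defined as t = 0,
  p = 1 rather than an error.
* AUROC uses mid-ranks, so ties get half credit; AUPRC collapses tied score
  groups before integration.
* Mining, ranking, column layouts and fold assignments all have
  deterministic orderings (support descending then lexicographic; ties in
  node ranking lexicographic; pair columns lexicographic), so the full
  pipeline is order-deterministic and invariant to input row order.
* Empty cohorts, empty transaction sets, single-class label vectors,
  all-missing features and sub-minimum group sizes raise typed errors
  (`oncosepsis_config_error`, `oncosepsis_validation_error`,
  `oncosepsis_unsupported_model`) rather than propagating NaNs.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by choice:
cohorts of 90–300 patients for end-to-end checks (10 seeds at 200/100 for
the nested-feature comparison), the published 455/928 group sizes for the
distribution-recovery and screening-power checks (100 replicate seeds), 200
random instances for the mining oracle, and toy trees for the exhaustive
Shapley oracle. The full published scale (928/455 with all stages) runs in
well under a minute on one core.

## Known limitations

* The SOFA cardiovascular subscore ignores vasopressor dose tiers, and
  respiration depends on an explicit ventilation flag.
* Prescription events are day-granular; antibiotic timing inside a day is
  resolved to midnight unless a timestamp column is supplied.
* The (I, H, T) formulas are a documented reconstruction (see above).
* The deep families are smoke-scale readout-trained networks, not tuned
  deep models.
* Per-visit (not per-patient) lab testing is an assumption; cohorts with
  many repeat visits per patient would also need within-patient correlation,
  which the generator does not simulate (it defaults to one ER visit per
  patient, though the pipeline handles multiple visits per patient).
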