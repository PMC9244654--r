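window_rx <- function(cohort) {
  cohort$visits |>
    dplyr::select("patient_id", "visit_id", "er_visit_time") |>
    dplyr::inner_join(cohort$prescriptions, by = "patient_id",
                      relationship = "many-to-many") |>
    dplyr::filter(as.numeric(.data$date) >=
                    as.numeric(as.Date(.data$er_visit_time)) - 7,
                  as.numeric(.data$date) <=
                    as.numeric(as.Date(.data$er_visit_time)) - 2) |>
    dplyr::select("patient_id", "visit_id", "date", "drug_id", "route")
}

window_labs <- function(cohort) {
  cohort$visits |>
    dplyr::select("patient_id", "visit_id", "er_visit_time") |>
    dplyr::inner_join(cohort$labs, by = "patient_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$timestamp >= .data$er_visit_time - 7 * 86400,
                  .data$timestamp <= .data$er_visit_time - 2 * 86400) |>
    dplyr::select("patient_id", "visit_id", "lab_type", "value")
}

#' Run the full sepsis-risk analysis on a cohort
#'
#' Chains every stage: Sepsis-3 labelling of ER visits, per-group FP-growth
#' mining of same-day co-prescriptions with support selection, drug-pair
#' relationship vectorization over the union of group-selected drugs, Welch
#' screening of observation-window labs, feature-table assembly, and
#' stratified cross-validated evaluation of the requested model families over
#' the nested feature sets.
#'
#' @param cohort A `sepsis_cohort` (e.g. from [generate_cohort()]).
#' @param config The [cohort_config()] that produced it (supplies the
#'   antibiotic catalog); defaults to [cohort_config()].
#' @param families Model families to evaluate.
#' @param feature_sets Nested feature sets to evaluate.
#' @param min_support Support threshold for pair selection (default 0.05).
#' @param alpha Per-test significance level for lab selection (default 0.001).
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Seed for fold assignment and stochastic fits.
#' @return A `sepsis_pipeline` list: `labels`, `label_agreement` (fraction of
#'   visits whose Sepsis-3 label matches the generator's ground truth, when
#'   available), `pairs_by_group`, `selected_drugs` (per group and union),
#'   `lab_comparison`, `selected_labs`, `features`, and `evals` (tibble of
#'   `sepsis_eval` objects with their aggregate metrics).
#' @export
#' @examples
#' \donttest{
#' cfg <- cohort_config(n_control = 120, n_sepsis = 60, seed = 7)
#' res <- run_sepsis_pipeline(generate_cohort(cfg), cfg,
#'                            families = "random_forest")
#' res$evals[c("family", "feature_set", "auroc")]
#' }
run_sepsis_pipeline <- function(cohort, config = cohort_config(),
                                families = "random_forest",
                                feature_sets = c("ehr_only", "ehr_drug",
                                                 "ehr_drug_lab"),
                                min_support = 0.05, alpha = 0.001,
                                n_folds = 5, seed = 1L) {
  drugs_cat <- config$drug_catalog$drugs
  abx <- drugs_cat$drug_id[drugs_cat$is_antibiotic]
  labels <- label_cohort(cohort, antibiotic_ids = abx)

  label_agreement <- NA_real_
  if (!is.null(cohort$ground_truth) && nrow(cohort$ground_truth) > 0) {
    truth <- cohort$ground_truth |>
      dplyr::mutate(truth = ifelse(.data$group == "sepsis", "sepsis", "nonsepsis"))
    cmp <- dplyr::inner_join(labels, truth, by = "patient_id")
    label_agreement <- mean(cmp$label == cmp$truth)
  }

  rx <- window_rx(cohort)
  lab_tbl <- window_labs(cohort)
  visit_groups <- labels |>
    dplyr::mutate(group = ifelse(.data$label == "sepsis", "sepsis", "control"))

  pairs_by_group <- purrr::map(c(sepsis = "sepsis", control = "control"),
    function(g) {
      pids <- visit_groups$patient_id[visit_groups$group == g]
      rx_g <- rx[rx$patient_id %in% pids, ]
      if (nrow(rx_g) == 0) return(tibble(drug_i = character(),
                                         drug_j = character(),
                                         n_cooccur = integer(),
                                         support = numeric()))
      mine_frequent_pairs(build_transactions(rx_g), min_support)
    })
  selected_drugs <- purrr::map(pairs_by_group,
                               function(p) sort(union(p$drug_i, p$drug_j)))
  drug_union <- sort(unique(unlist(selected_drugs)))

  relationship_features <- NULL
  if (length(drug_union) >= 2) {
    profiles <- compute_drug_frequencies(rx, drug_union)
    relationship_features <- build_relationship_features(profiles, drug_union)
  }

  lab_comparison <- compare_labs(
    lab_tbl, visit_groups[c("patient_id", "group")] |> dplyr::distinct())
  selected_labs <- select_significant_labs(lab_comparison, alpha)

  features <- build_feature_table(
    cohort, labels, relationship_features = relationship_features,
    lab_exclude = setdiff(unique(lab_tbl$lab_type), selected_labs))

  evals <- tidyr::expand_grid(family = families, feature_set = feature_sets) |>
    dplyr::mutate(eval = purrr::map2(.data$family, .data$feature_set,
      function(fam, fs) {
        d <- select_feature_set(features, fs)
        run_cross_validation(d, d$group_label,
                             model_config(fam, feature_set = fs, seed = seed),
                             n_folds = n_folds)
      }))
  evals <- dplyr::bind_cols(evals,
                            purrr::map(evals$eval, "aggregate") |> list_rbind())

  structure(list(labels = labels, label_agreement = label_agreement,
                 pairs_by_group = pairs_by_group,
                 selected_drugs = c(selected_drugs, list(union = drug_union)),
                 lab_comparison = lab_comparison,
                 selected_labs = selected_labs,
                 features = features, evals = evals),
            class = "sepsis_pipeline")
}

#' @export
print.sepsis_pipeline <- function(x, ...) {
  cat("<sepsis_pipeline>\n")
  cat("  visits labelled:", nrow(x$labels),
      sprintf(" (sepsis %d / nonsepsis %d)", sum(x$labels$label == "sepsis"),
              sum(x$labels$label == "nonsepsis")), "\n")
  if (!is.na(x$label_agreement))
    cat(sprintf("  ground-truth agreement: %.1f%%\n", 100 * x$label_agreement))
  cat("  selected drugs: sepsis", length(x$selected_drugs$sepsis),
      "/ control", length(x$selected_drugs$control),
      "/ union", length(x$selected_drugs$union), "\n")
  cat("  selected labs:", length(x$selected_labs), "\n")
  print(x$evals[c("family", "feature_set", "accuracy", "auroc", "auprc", "f1")])
  invisible(x)
}
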