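#' Restrict events to the pre-visit observation window
#'
#' Predictive features are drawn from 2-7 days *before* the ER visit: recent
#' enough to matter, but excluding the 48 h immediately preceding the visit
#' so the model predicts in advance of onset. Events outside
#' \[visit - max_days, visit - min_days\] are discarded; a visit with no
#' retained event is flagged for dropping.
#'
#' @param events Tibble with a `timestamp` (POSIXct) or `date` (Date) column.
#' @param er_visit_time The visit's ER arrival time (POSIXct or Date).
#' @param min_days,max_days Window bounds in days before the visit
#'   (defaults 2 and 7, inclusive).
#' @return List with `events` (the retained rows) and `keep` (TRUE when at
#'   least one event survives).
#' @export
filter_observation_window <- function(events, er_visit_time,
                                      min_days = 2, max_days = 7) {
  if ("timestamp" %in% names(events)) {
    t <- as.numeric(events$timestamp)
    er <- as.numeric(as.POSIXct(er_visit_time))
    sel <- t >= er - max_days * 86400 & t <= er - min_days * 86400
  } else if ("date" %in% names(events)) {
    d <- as.numeric(events$date)
    er <- as.numeric(as.Date(er_visit_time))
    sel <- d >= er - max_days & d <= er - min_days
  } else {
    abort("events need a 'timestamp' or 'date' column",
          class = "oncosepsis_validation_error")
  }
  kept <- events[which(sel), ]
  list(events = kept, keep = nrow(kept) > 0)
}

#' Standardize a diagnosis code to 3 characters
#'
#' Strips punctuation, uppercases, and truncates to the first three
#' characters, turning full ICD-style codes (e.g. `"C22.0"`) into 3-digit
#' category codes (`"C22"`) usable as categorical features.
#'
#' @param code Character vector of diagnosis codes.
#' @return Character vector of 3-character codes.
#' @export
#' @examples
#' standardize_diagnosis_code(c("C22.0", "c34", "C509"))
standardize_diagnosis_code <- function(code) {
  stripped <- toupper(gsub("[^A-Za-z0-9]", "", code))
  if (any(is.na(code)) || any(nchar(stripped) < 3))
    abort("diagnosis codes must have at least 3 alphanumeric characters",
          class = "oncosepsis_validation_error")
  substr(stripped, 1, 3)
}

#' Select lab types by patient coverage
#'
#' Keeps a lab type only when strictly more than `min_fraction` of the
#' patients have at least one non-missing measurement of it; sparsely
#' ordered tests are dropped before modelling.
#'
#' @param labs Tibble with `patient_id`, `lab_type`, `value`.
#' @param patients Character vector of patient ids (or a tibble with a
#'   `patient_id` column) defining the denominator.
#' @param min_fraction Strict lower bound on coverage, in (0, 1\]; default 0.6.
#' @return Sorted character vector of retained lab types.
#' @export
filter_lab_coverage <- function(labs, patients, min_fraction = 0.6) {
  if (is.data.frame(patients)) patients <- patients$patient_id
  if (length(patients) == 0)
    abort("empty patient set", class = "oncosepsis_validation_error")
  stopifnot(min_fraction > 0, min_fraction <= 1)
  cov <- labs |>
    dplyr::filter(!is.na(.data$value), .data$patient_id %in% patients) |>
    dplyr::distinct(.data$patient_id, .data$lab_type) |>
    dplyr::count(.data$lab_type)
  sort(cov$lab_type[cov$n / length(patients) > min_fraction])
}

#' Mark extreme outliers missing
#'
#' Robust z-score rule: entries farther than `k` scaled median absolute
#' deviations (MAD x 1.4826) from the median are set `NA` (and later
#' imputed). The rule is applied literally when the MAD is zero: a constant
#' feature is untouched (all deviations are zero), while a lone extreme
#' among otherwise identical values is removed (its robust z is infinite).
#'
#' @param x Numeric vector.
#' @param k Cut-off in robust SD units; default 5.
#' @return `x` with extreme entries replaced by `NA`.
#' @export
#' @examples
#' remove_outliers(c(1, 1, 1, 1, 1000))
remove_outliers <- function(x, k = 5) {
  med <- median(x, na.rm = TRUE)
  s <- mad(x, na.rm = TRUE) # 1.4826 * MAD
  if (is.na(s)) return(x)
  x[!is.na(x) & abs(x - med) > k * s] <- NA
  x
}

#' Impute missing values by demographic stratum means
#'
#' Each missing numeric value is replaced by the mean of its (cancer type,
#' sex, age-bin) stratum; empty strata fall back by dropping age, then sex,
#' then to the global mean. Exact-age strata would be nearly empty, so "same
#' age" is interpreted as a configurable age bin (default 5 years). Row count
#' is never changed.
#'
#' @param feature_table Tibble containing `cancer_type`, `sex`, `age` and the
#'   numeric feature columns.
#' @param cols Columns to impute; defaults to all numeric columns except
#'   `age`.
#' @param age_bin_width Width of the age bins in years.
#' @return The table with no missing values in `cols`.
#' @export
impute_missing <- function(feature_table, cols = NULL, age_bin_width = 5) {
  stopifnot(all(c("cancer_type", "sex", "age") %in% names(feature_table)))
  if (is.null(cols)) {
    cols <- setdiff(names(feature_table)[vapply(feature_table, is.numeric,
                                                logical(1))], "age")
  }
  bin <- floor(feature_table$age / age_bin_width)
  strata <- list(
    paste(feature_table$cancer_type, feature_table$sex, bin),
    paste(feature_table$cancer_type, feature_table$sex),
    feature_table$cancer_type,
    rep("all", nrow(feature_table))
  )
  for (cl in cols) {
    x <- feature_table[[cl]]
    if (all(is.na(x)))
      abort(paste0("feature '", cl, "' is missing in all rows"),
            class = "oncosepsis_validation_error")
    for (s in strata) {
      if (!anyNA(x)) break
      means <- tapply(x, s, mean, na.rm = TRUE)
      fill <- means[s[is.na(x)]]
      x[is.na(x)] <- as.numeric(fill)
      x[is.nan(x)] <- NA # stratum had no observed value: try next level
    }
    feature_table[[cl]] <- x
  }
  feature_table
}

one_hot <- function(values, prefix) {
  lv <- sort(unique(values))
  out <- purrr::map(lv, function(l) as.integer(values == l))
  names(out) <- paste0(prefix, "_", lv)
  as_tibble(out)
}

#' Build the model-ready feature table
#'
#' Assembles one row per retained ER visit: demographics (sex indicator, age,
#' weight), one-hot cancer type and 3-digit diagnosis codes, mean in-window
#' values of coverage-filtered lab tests (outliers removed, stratified-mean
#' imputed), and optionally a pre-computed drug-relationship block. A column
#' manifest records each column's source stage, so nested feature sets can be
#' carved out later with [select_feature_set()].
#'
#' @param cohort A `sepsis_cohort`.
#' @param labels Visit labels from [label_cohort()] (their `label` column
#'   becomes `group_label`).
#' @param relationship_features Optional wide tibble keyed by `patient_id`
#'   with drug-pair vector columns (see [build_relationship_features()]).
#' @param lab_min_fraction Coverage threshold for [filter_lab_coverage()].
#' @param lab_exclude Lab types to drop regardless of coverage (tests tied to
#'   specific disease groups that would leak the outcome).
#' @param outlier_k Robust z cut-off for [remove_outliers()].
#' @param age_bin_width Age-bin width for [impute_missing()].
#' @return A tibble (class `sepsis_features`) with id columns `patient_id`,
#'   `visit_id`, `group_label`, stratifier columns and feature columns; the
#'   column manifest is available via [feature_manifest()].
#' @export
build_feature_table <- function(cohort, labels,
                                relationship_features = NULL,
                                lab_min_fraction = 0.6,
                                lab_exclude = character(),
                                outlier_k = 5,
                                age_bin_width = 5) {
  visits <- cohort$visits |>
    dplyr::inner_join(labels[c("patient_id", "visit_id", "label")],
                      by = c("patient_id", "visit_id"))
  # window-filter labs per visit; drop visits with no retained events at all
  win_labs <- visits |>
    dplyr::select("patient_id", "visit_id", "er_visit_time") |>
    dplyr::inner_join(cohort$labs, by = "patient_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$timestamp >= .data$er_visit_time - 7 * 86400,
                  .data$timestamp <= .data$er_visit_time - 2 * 86400)
  win_rx <- visits |>
    dplyr::select("patient_id", "visit_id", "er_visit_time") |>
    dplyr::inner_join(cohort$prescriptions, by = "patient_id",
                      relationship = "many-to-many") |>
    dplyr::filter(as.numeric(.data$date) >=
                    as.numeric(as.Date(.data$er_visit_time)) - 7,
                  as.numeric(.data$date) <=
                    as.numeric(as.Date(.data$er_visit_time)) - 2)
  kept_visits <- union(win_labs$visit_id, win_rx$visit_id)
  visits <- visits[visits$visit_id %in% kept_visits, ]

  keep_labs <- setdiff(
    filter_lab_coverage(win_labs, visits$patient_id, lab_min_fraction),
    lab_exclude
  )
  lab_block <- win_labs |>
    dplyr::filter(.data$lab_type %in% keep_labs, !is.na(.data$value)) |>
    dplyr::group_by(.data$visit_id, .data$lab_type) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "lab_type", values_from = "value",
                       names_prefix = "lab_") |>
    dplyr::right_join(visits["visit_id"], by = "visit_id")
  lab_cols <- setdiff(names(lab_block), "visit_id")
  lab_block[lab_cols] <- lapply(lab_block[lab_cols], remove_outliers, k = outlier_k)

  demo <- visits |>
    dplyr::inner_join(cohort$patients, by = "patient_id") |>
    dplyr::mutate(is_male = as.integer(.data$sex == "male"),
                  dx3 = standardize_diagnosis_code(.data$diagnosis_code))
  cancer_oh <- one_hot(demo$cancer_type, "cancer")
  dx_oh <- one_hot(demo$dx3, "dx")

  out <- dplyr::bind_cols(
    demo |>
      dplyr::select("patient_id", "visit_id",
                    group_label = "label", "cancer_type", "sex",
                    "is_male", "age", "weight"),
    cancer_oh, dx_oh
  ) |>
    dplyr::left_join(lab_block, by = "visit_id")

  manifest <- tibble(
    name = c("is_male", "age", "weight", names(cancer_oh), names(dx_oh), lab_cols),
    source_stage = c(rep("demographics", 3),
                     rep("diagnosis", ncol(cancer_oh) + ncol(dx_oh)),
                     rep("lab", length(lab_cols))),
    encoding = c("binary", "numeric", "numeric",
                 rep("one_hot", ncol(cancer_oh) + ncol(dx_oh)),
                 rep("numeric", length(lab_cols)))
  )
  if (!is.null(relationship_features)) {
    out <- dplyr::left_join(out, relationship_features, by = "patient_id")
    rel_cols <- setdiff(names(relationship_features), "patient_id")
    out[rel_cols][is.na(out[rel_cols])] <- 0 # no selected drug in window
    manifest <- dplyr::bind_rows(manifest, tibble(
      name = rel_cols, source_stage = "drug_relationship", encoding = "numeric"))
  }
  out <- impute_missing(out, cols = intersect(manifest$name, names(out)),
                        age_bin_width = age_bin_width)
  structure(out, manifest = manifest,
            class = c("sepsis_features", class(out)))
}

#' Column manifest of a feature table
#' @param features A `sepsis_features` table.
#' @return Tibble with `name`, `source_stage`, `encoding`.
#' @export
feature_manifest <- function(features) attr(features, "manifest")

#' Carve a nested feature set out of a feature table
#'
#' The three nested sets are `ehr_only` (demographics + diagnosis codes),
#' `ehr_drug` (plus drug-relationship vectors) and `ehr_drug_lab` (plus
#' selected lab values).
#'
#' @param features A `sepsis_features` table.
#' @param feature_set One of `"ehr_only"`, `"ehr_drug"`, `"ehr_drug_lab"`.
#' @return Tibble with id columns plus the selected feature columns.
#' @export
select_feature_set <- function(features,
                               feature_set = c("ehr_drug_lab", "ehr_only", "ehr_drug")) {
  feature_set <- match.arg(feature_set)
  manifest <- feature_manifest(features)
  stages <- switch(feature_set,
    ehr_only = c("demographics", "diagnosis"),
    ehr_drug = c("demographics", "diagnosis", "drug_relationship"),
    ehr_drug_lab = c("demographics", "diagnosis", "drug_relationship", "lab"))
  cols <- manifest$name[manifest$source_stage %in% stages]
  features[c("patient_id", "visit_id", "group_label", intersect(cols, names(features)))]
}
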