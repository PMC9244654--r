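#' Default per-group lab-value parameters
#'
#' Group-level means and standard deviations for the eight lab tests whose
#' sepsis/control distributions are published in running text of the source
#' cohort study (albumin, total protein, cholesterol, albumin/globulin ratio,
#' APTT, and prothrombin time as %, INR and seconds). All other lab types of
#' the original 64-test panel are not publicly tabulated; users supply their
#' own rows in the same format for additional tests.
#'
#' @return A tibble with one row per lab type and columns `lab_type`, `unit`,
#'   `mean_sepsis`, `sd_sepsis`, `mean_control`, `sd_control`, and
#'   `nonnegative` (whether draws should be restricted to non-negative values
#'   when a moment-matched zero-truncated normal exists; see
#'   [generate_lab_panel()]).
#' @export
#' @examples
#' default_lab_params()
default_lab_params <- function() {
  tibble::tribble(
    ~lab_type,       ~unit,    ~mean_sepsis, ~sd_sepsis, ~mean_control, ~sd_control,
    "albumin",       "g/dL",   2.73,         1.57,       3.30,          1.47,
    "total_protein", "g/dL",   4.77,         2.98,       5.27,          2.82,
    "cholesterol",   "mg/dL",  81.06,        84.79,      111.46,        84.30,
    "ag_ratio",      "ratio",  0.76,         0.70,       1.14,          0.69,
    "aptt",          "sec",    14.06,        19.72,      6.89,          15.01,
    "pt_percent",    "%",      33.27,        42.26,      17.51,         35.82,
    "pt_inr",        "INR",    0.49,         0.63,       0.23,          0.46,
    "pt_sec",        "sec",    6.14,         7.69,       2.90,          5.84
  ) |>
    dplyr::mutate(nonnegative = TRUE)
}

#' Default abstract drug catalog
#'
#' Drugs are abstract identifiers with per-group daily prescription
#' probabilities; no pharmacology is simulated. Narcotic analgesics are given
#' higher daily probabilities and a same-day co-prescription boost in the
#' sepsis group, so their pairs exceed the 0.05 support threshold only in the
#' sepsis-group mining run. Intravenous antibiotics are flagged
#' `is_antibiotic`; they anchor the suspected-infection windows.
#'
#' @return A list with components `drugs` (tibble: `drug_id`, `is_antibiotic`,
#'   `p_daily_control`, `p_daily_sepsis`) and `boost_pairs` (tibble:
#'   `drug_a`, `drug_b`, `boost_control`, `boost_sepsis` — the extra
#'   probability that both drugs are jointly forced into a day's basket).
#' @export
default_drug_catalog <- function() {
  drugs <- tibble::tribble(
    ~drug_id,              ~is_antibiotic, ~p_daily_control, ~p_daily_sepsis,
    "saline_solution",     FALSE,          0.80,             0.85,
    "opioid_alkaloids",    FALSE,          0.12,             0.55,
    "synthetic_narcotics", FALSE,          0.10,             0.50,
    "antipyretic_a",       FALSE,          0.18,             0.45,
    "antiemetic_a",        FALSE,          0.30,             0.35,
    "ppi_a",               FALSE,          0.30,             0.30,
    "anticancer_a",        FALSE,          0.25,             0.20,
    "anticancer_b",        FALSE,          0.20,             0.20,
    "corticosteroid_a",    FALSE,          0.20,             0.30,
    "laxative_a",          FALSE,          0.20,             0.20,
    "heparin_flush",       FALSE,          0.15,             0.25,
    "antihistamine_a",     FALSE,          0.15,             0.15,
    "antibiotic_iv_a",     TRUE,           0.08,             0.30,
    "antibiotic_iv_b",     TRUE,           0.05,             0.15
  )
  boost_pairs <- tibble::tribble(
    ~drug_a,             ~drug_b,               ~boost_control, ~boost_sepsis,
    "opioid_alkaloids",  "synthetic_narcotics", 0.01,           0.35,
    "synthetic_narcotics", "antipyretic_a",     0.01,           0.20
  )
  list(drugs = drugs, boost_pairs = boost_pairs)
}

#' Build a synthetic-cohort configuration
#'
#' Bundles and validates every knob of the synthetic EHR generator. Defaults
#' reproduce the published cohort: 928 control and 455 sepsis patients, the
#' per-group sex ratios and liver/lung/breast cancer mix, age and weight
#' distributions, the eight text-published lab distributions, and a
#' group-differential co-prescription structure.
#'
#' @param n_control,n_sepsis Number of control / sepsis patients (>= 0).
#' @param male_fraction_by_group Named numeric, probability of male sex per
#'   group (`control`, `sepsis`).
#' @param cancer_mix_by_group Named list of probability vectors over
#'   `c(liver, lung, breast)` per group; each must sum to 1 within 1e-9.
#' @param age_params,weight_params Named list per group of `c(mean, sd)` in
#'   years / kg; ages are clipped to \[18, 95\] (adult cohort), weights to
#'   \[30, 150\].
#' @param lab_params Tibble as returned by [default_lab_params()].
#' @param drug_catalog List as returned by [default_drug_catalog()].
#' @param missingness_rate Probability that a lab value is absent, in \[0, 1\].
#' @param control_culture_rate Probability that a control patient also has a
#'   bacterial culture with an in-window IV antibiotic (their SOFA change
#'   stays <= 1, so they remain nonsepsis under the Sepsis-3 rule).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   cohorts.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_control = 50, n_sepsis = 25, seed = 1)
#' cfg$n_sepsis
cohort_config <- function(n_control = 928,
                          n_sepsis = 455,
                          male_fraction_by_group = c(control = 0.528, sepsis = 0.712),
                          cancer_mix_by_group = list(
                            control = c(liver = 0.194, lung = 0.574, breast = 0.232),
                            sepsis  = c(liver = 0.308, lung = 0.602, breast = 0.090)
                          ),
                          age_params = list(control = c(mean = 58.2, sd = 11.0),
                                            sepsis  = c(mean = 60.3, sd = 11.0)),
                          weight_params = list(control = c(mean = 63.7, sd = 10.7),
                                               sepsis  = c(mean = 64.3, sd = 11.3)),
                          lab_params = default_lab_params(),
                          drug_catalog = default_drug_catalog(),
                          missingness_rate = 0.1,
                          control_culture_rate = 0.3,
                          seed = 1L) {
  cfg <- list(
    n_control = n_control, n_sepsis = n_sepsis,
    male_fraction_by_group = male_fraction_by_group,
    cancer_mix_by_group = cancer_mix_by_group,
    age_params = age_params, weight_params = weight_params,
    lab_params = lab_params, drug_catalog = drug_catalog,
    missingness_rate = missingness_rate,
    control_culture_rate = control_culture_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_control < 0 || cfg$n_sepsis < 0)
    abort("n_control and n_sepsis must be >= 0", class = "oncosepsis_config_error")
  for (g in c("control", "sepsis")) {
    p <- cfg$male_fraction_by_group[[g]]
    if (is.null(p) || p < 0 || p > 1)
      abort(paste0("male fraction for group '", g, "' must be in [0,1]"),
            class = "oncosepsis_config_error")
    mix <- cfg$cancer_mix_by_group[[g]]
    if (is.null(mix) || any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
      abort(paste0("cancer mix for group '", g, "' must be a probability vector summing to 1"),
            class = "oncosepsis_config_error")
  }
  if (any(cfg$lab_params$sd_sepsis < 0) || any(cfg$lab_params$sd_control < 0))
    abort("lab sd values must be >= 0", class = "oncosepsis_config_error")
  if (cfg$missingness_rate < 0 || cfg$missingness_rate > 1)
    abort("missingness_rate must be in [0,1]", class = "oncosepsis_config_error")
  d <- cfg$drug_catalog$drugs
  if (any(d$p_daily_control < 0 | d$p_daily_control > 1 |
          d$p_daily_sepsis < 0 | d$p_daily_sepsis > 1))
    abort("drug daily probabilities must be in [0,1]", class = "oncosepsis_config_error")
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  patients: ", x$n_control, " control + ", x$n_sepsis, " sepsis\n", sep = "")
  cat("  lab types:", nrow(x$lab_params), " drugs:", nrow(x$drug_catalog$drugs), "\n")
  cat("  missingness:", x$missingness_rate, " seed:", x$seed, "\n")
  invisible(x)
}
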