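sofa_systems <- c("respiration", "coagulation", "liver",
                  "cardiovascular", "cns", "renal")

#' SOFA component threshold table
#'
#' Reads the versioned, unit-annotated threshold configuration mapping each
#' organ-system measurement to a 0-4 subscore. The shipped file encodes the
#' standard six-system Sepsis-3 convention; pass `path` to override any
#' cutoff.
#'
#' @param path Path to a YAML threshold file; default is the version shipped
#'   with the package.
#' @return A named list, one entry per organ system.
#' @export
#' @examples
#' th <- sofa_thresholds()
#' th$coagulation$cutoffs
sofa_thresholds <- function(path = system.file("extdata", "sofa_thresholds.yaml",
                                               package = "oncosepsis")) {
  yaml::read_yaml(path)
}

score_component <- function(value, spec) {
  # value may be NA; returns NA for missing (caller maps to 0 + flag)
  if (is.na(value)) return(NA_integer_)
  if (spec$direction == "below") {
    s <- sum(value < spec$cutoffs)
  } else {
    s <- sum(value >= spec$cutoffs)
  }
  as.integer(s)
}

#' Compute SOFA scores from raw component measurements
#'
#' Maps each present measurement through the configured threshold table to a
#' 0-4 subscore and sums the six organ systems to a 0-24 total. Absent (`NA`
#' or missing-column) components contribute 0 and are listed in
#' `components_missing`, following the convention that an unmeasured score is
#' taken as 0. Respiration subscores above 2 require an `on_ventilation`
#' flag; vasopressor support (logical `vasopressor`) sets the cardiovascular
#' subscore to the configured value irrespective of MAP.
#'
#' @param measurements A data frame (one row per timepoint) or a named list
#'   with any of the columns `pao2_fio2`, `platelets`, `bilirubin`, `map`,
#'   `vasopressor`, `gcs`, `creatinine`, `on_ventilation`; extra columns
#'   (e.g. `patient_id`, `timestamp`) are carried through.
#' @param thresholds Threshold table from [sofa_thresholds()].
#' @return A tibble with one row per input row: carried-through id columns,
#'   the six subscores, `total`, and a `components_missing` list-column.
#' @export
#' @examples
#' compute_sofa_score(list(platelets = 90, map = 80, gcs = 15,
#'                         bilirubin = 0.5, creatinine = 0.8, pao2_fio2 = 450))
compute_sofa_score <- function(measurements, thresholds = sofa_thresholds()) {
  df <- as_tibble(as.data.frame(measurements, stringsAsFactors = FALSE))
  for (bad in c("platelets", "creatinine", "bilirubin")) {
    if (bad %in% names(df) && any(df[[bad]] < 0, na.rm = TRUE))
      abort(paste("negative", bad, "measurement"),
            class = "oncosepsis_validation_error")
  }
  n <- nrow(df)
  get_col <- function(nm, default = NA) {
    if (nm %in% names(df)) df[[nm]] else rep(default, n)
  }
  sub <- matrix(0L, n, length(sofa_systems),
                dimnames = list(NULL, sofa_systems))
  missing_lst <- vector("list", n)
  vaso <- get_col("vasopressor", NA)
  vent <- get_col("on_ventilation", NA)
  for (i in seq_len(n)) {
    miss <- character()
    for (sys in sofa_systems) {
      spec <- thresholds[[sys]]
      val <- get_col(spec$measurement)[i]
      s <- score_component(val, spec)
      if (sys == "respiration" && !is.na(s) && !isTRUE(vent[i])) {
        s <- min(s, as.integer(spec$cap_without_support))
      }
      if (sys == "cardiovascular" && isTRUE(vaso[i])) {
        s <- max(if (is.na(s)) 0L else s, as.integer(spec$vasopressor_score))
      }
      if (is.na(s)) {
        miss <- c(miss, sys)
        s <- 0L
      }
      sub[i, sys] <- s
    }
    missing_lst[[i]] <- miss
  }
  carried <- df[setdiff(names(df), c(vapply(thresholds[sofa_systems],
                                            function(s) s$measurement, ""),
                                     "vasopressor", "on_ventilation"))]
  dplyr::bind_cols(carried, as_tibble(sub)) |>
    dplyr::mutate(total = rowSums(sub), components_missing = missing_lst)
}

#' Compute a per-patient SOFA time series
#'
#' Scores every measurement timestamp, carrying each component's last
#' observation forward within a patient (the score is recomputed whenever any
#' new component value arrives).
#'
#' @param sofa_inputs Tibble with `patient_id`, `timestamp` and measurement
#'   columns as in [compute_sofa_score()].
#' @param thresholds Threshold table from [sofa_thresholds()].
#' @return Tibble of assessments sorted by patient and time.
#' @export
compute_sofa_series <- function(sofa_inputs, thresholds = sofa_thresholds()) {
  meas_cols <- intersect(names(sofa_inputs),
                         c("pao2_fio2", "platelets", "bilirubin", "map",
                           "vasopressor", "gcs", "creatinine", "on_ventilation"))
  sofa_inputs |>
    dplyr::arrange(.data$patient_id, .data$timestamp) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(meas_cols), locf)) |>
    dplyr::ungroup() |>
    compute_sofa_score(thresholds)
}

locf <- function(x) {
  ok <- !is.na(x)
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  out <- x[pmax(idx, 1L)]
  out[idx == 0L] <- x[NA_integer_]
  out
}

#' Find suspected-infection windows
#'
#' A suspected-infection window is the interval from 24 h before to 24 h
#' after a bacterial culture that has at least one intravenous antibiotic
#' administration inside it (boundaries inclusive). Non-intravenous routes
#' are ignored; `"IV"` is matched case-insensitively. Prescription dates are
#' day-granular and are interpreted as midnight UTC.
#'
#' @param cultures Tibble with `patient_id`, `timestamp`.
#' @param prescriptions Tibble with `patient_id`, `date`, `drug_id`, `route`;
#'   an optional `timestamp` column, where present, gives the administration
#'   time at full resolution and takes precedence over `date`.
#' @param antibiotic_ids Character vector of drug ids considered antibiotics.
#' @param window_hours Half-width of the window in hours (default 24).
#' @return Tibble with `patient_id`, `culture_time`, `window_start`,
#'   `window_end`, `antibiotic_time` (the closest qualifying administration);
#'   empty when no culture qualifies.
#' @export
find_infection_windows <- function(cultures, prescriptions, antibiotic_ids,
                                   window_hours = 24) {
  empty <- tibble(patient_id = character(),
                  culture_time = as.POSIXct(character(), tz = "UTC"),
                  window_start = as.POSIXct(character(), tz = "UTC"),
                  window_end = as.POSIXct(character(), tz = "UTC"),
                  antibiotic_time = as.POSIXct(character(), tz = "UTC"))
  if (nrow(cultures) == 0) return(empty)
  abx <- prescriptions |>
    dplyr::filter(toupper(.data$route) == "IV",
                  .data$drug_id %in% antibiotic_ids)
  abx$antibiotic_time <- if ("timestamp" %in% names(abx)) {
    abx$timestamp
  } else {
    as.POSIXct(paste(abx$date, "00:00:00"), tz = "UTC")
  }
  abx <- abx[c("patient_id", "antibiotic_time")]
  if (nrow(abx) == 0) return(empty)
  half <- window_hours * 3600
  cultures |>
    dplyr::rename(culture_time = "timestamp") |>
    dplyr::inner_join(abx, by = "patient_id", relationship = "many-to-many") |>
    dplyr::filter(abs(as.numeric(.data$antibiotic_time) -
                        as.numeric(.data$culture_time)) <= half) |>
    dplyr::group_by(.data$patient_id, .data$culture_time) |>
    dplyr::slice_min(abs(as.numeric(.data$antibiotic_time) -
                           as.numeric(.data$culture_time)),
                     n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(window_start = .data$culture_time - half,
                  window_end = .data$culture_time + half) |>
    dplyr::select("patient_id", "culture_time", "window_start", "window_end",
                  "antibiotic_time")
}

#' Label one ER visit by the Sepsis-3 rule
#'
#' For each suspected-infection window the baseline is the last SOFA total
#' strictly before the window start (0 when never measured) and the delta is
#' the maximum in-window total minus that baseline. The visit is labelled
#' sepsis when any window reaches a delta of 2 or more; the triggering window
#' is the earliest such window.
#'
#' @param sofa_series Tibble with `timestamp` and `total` for one visit (may
#'   be empty: baseline is then 0).
#' @param windows Tibble of windows for this visit (columns as returned by
#'   [find_infection_windows()]; may be empty).
#' @param er_visit_time ER-visit timestamp (used for the reported baseline
#'   when no window exists).
#' @return One-row tibble: `label` (`"sepsis"`/`"nonsepsis"`),
#'   `baseline_sofa`, `max_delta`, `window_start`, `window_end` (NA when no
#'   window triggered).
#' @export
label_visit <- function(sofa_series, windows, er_visit_time) {
  totals <- sofa_series$total %||% numeric()
  times <- sofa_series$timestamp %||% as.POSIXct(character(), tz = "UTC")
  last_before <- function(t) {
    sel <- times < t
    if (!any(sel)) 0 else totals[sel][which.max(as.numeric(times[sel]))]
  }
  if (nrow(windows) == 0) {
    return(tibble(label = "nonsepsis", baseline_sofa = last_before(er_visit_time),
                  max_delta = 0,
                  window_start = as.POSIXct(NA, tz = "UTC"),
                  window_end = as.POSIXct(NA, tz = "UTC")))
  }
  windows <- dplyr::arrange(windows, .data$window_start)
  deltas <- purrr::pmap_dfr(
    windows[c("window_start", "window_end")],
    function(window_start, window_end) {
      base <- last_before(window_start)
      inw <- totals[times >= window_start & times <= window_end]
      delta <- if (length(inw) == 0) 0 else max(inw) - base
      tibble(baseline = base, delta = delta,
             window_start = window_start, window_end = window_end)
    })
  hit <- which(deltas$delta >= 2)
  if (length(hit) > 0) {
    w <- deltas[hit[1], ] # earliest triggering window
    tibble(label = "sepsis", baseline_sofa = w$baseline,
           max_delta = max(deltas$delta),
           window_start = w$window_start, window_end = w$window_end)
  } else {
    tibble(label = "nonsepsis", baseline_sofa = deltas$baseline[1],
           max_delta = max(deltas$delta),
           window_start = as.POSIXct(NA, tz = "UTC"),
           window_end = as.POSIXct(NA, tz = "UTC"))
  }
}

#' Label every ER visit of a cohort
#'
#' Runs the full Sepsis-3 procedure: SOFA series per patient (last
#' observation carried forward per component), suspected-infection windows
#' from cultures and IV antibiotics, and the 2-point-rise rule per visit.
#' Only windows whose culture falls within `culture_match_days` of the ER
#' visit are attributed to that visit.
#'
#' @param cohort A `sepsis_cohort` (or any list with `visits`, `sofa_inputs`,
#'   `cultures`, `prescriptions` tibbles).
#' @param antibiotic_ids Drug ids considered antibiotics; defaults to the
#'   antibiotics of [default_drug_catalog()].
#' @param thresholds SOFA threshold table.
#' @param culture_match_days Maximum |culture time - ER time| in days for a
#'   window to count toward a visit (default 7).
#' @return Tibble with `patient_id`, `visit_id`, `label`, `baseline_sofa`,
#'   `max_delta`, `window_start`, `window_end`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_control = 20, n_sepsis = 10, seed = 3))
#' labels <- label_cohort(cohort)
#' table(labels$label)
label_cohort <- function(cohort,
                         antibiotic_ids = NULL,
                         thresholds = sofa_thresholds(),
                         culture_match_days = 7) {
  if (is.null(antibiotic_ids)) {
    cat_drugs <- default_drug_catalog()$drugs
    antibiotic_ids <- cat_drugs$drug_id[cat_drugs$is_antibiotic]
  }
  series <- compute_sofa_series(cohort$sofa_inputs, thresholds)
  windows <- find_infection_windows(cohort$cultures, cohort$prescriptions,
                                    antibiotic_ids)
  series_by <- split(series, series$patient_id)
  windows_by <- split(windows, windows$patient_id)
  purrr::pmap_dfr(
    cohort$visits[c("patient_id", "visit_id", "er_visit_time")],
    function(patient_id, visit_id, er_visit_time) {
      s <- series_by[[patient_id]] %||% tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                                               total = numeric())
      w <- windows_by[[patient_id]]
      if (is.null(w)) {
        w <- windows[0, ]
      } else {
        w <- w[abs(as.numeric(w$culture_time) - as.numeric(er_visit_time)) <=
                 culture_match_days * 86400, ]
      }
      label_visit(s, w, er_visit_time) |>
        dplyr::mutate(patient_id = patient_id, visit_id = visit_id,
                      .before = 1)
    })
}
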