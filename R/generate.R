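#' Moment-matched zero-truncated normal draws
#'
#' Draws from a normal distribution truncated at zero whose *truncated* mean
#' and standard deviation equal the requested `mean` and `sd`: the underlying
#' location/scale are solved for numerically, so published group moments are
#' reproduced exactly in expectation while keeping draws non-negative. A
#' zero-truncated normal cannot have mean/sd <= 1, so when the requested
#' moments are unattainable (or nearly so, ratio <= 1.05) the function falls
#' back to untruncated normal draws.
#'
#' @param n Number of draws.
#' @param mean,sd Target moments of the returned sample's distribution.
#' @return Numeric vector of length `n`.
#' @keywords internal
rtruncnorm_mm <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  ratio <- mean / sd
  if (!is.finite(ratio) || ratio <= 1.05) return(rnorm(n, mean, sd))
  # standardized truncation point a = (0 - mu0)/s0; lambda = Mills ratio
  moment_ratio <- function(a) {
    lam <- dnorm(a) / pnorm(a, lower.tail = FALSE)
    m <- lam - a
    v <- 1 + a * lam - lam^2
    if (v <= 0) return(Inf)
    m / sqrt(v)
  }
  lo <- -50; hi <- 8
  if (moment_ratio(hi) >= ratio) return(rnorm(n, mean, sd)) # ratio ~1, degenerate
  a <- uniroot(function(x) moment_ratio(x) - ratio, c(lo, hi), tol = 1e-10)$root
  lam <- dnorm(a) / pnorm(a, lower.tail = FALSE)
  v <- 1 + a * lam - lam^2
  s0 <- sd / sqrt(v)
  mu0 <- -a * s0
  # inverse-CDF sampling restricted to the upper tail beyond the truncation
  p_lo <- pnorm(a)
  mu0 + s0 * qnorm(p_lo + runif(n) * (1 - p_lo))
}

new_sepsis_cohort <- function(patients, visits, labs, prescriptions,
                              cultures, sofa_inputs, ground_truth) {
  structure(
    list(patients = patients, visits = visits, labs = labs,
         prescriptions = prescriptions, cultures = cultures,
         sofa_inputs = sofa_inputs, ground_truth = ground_truth),
    class = "sepsis_cohort"
  )
}

#' @export
print.sepsis_cohort <- function(x, ...) {
  cat("<sepsis_cohort>\n")
  cat("  patients:     ", nrow(x$patients), "\n")
  cat("  visits:       ", nrow(x$visits), "\n")
  cat("  labs:         ", nrow(x$labs), "\n")
  cat("  prescriptions:", nrow(x$prescriptions), "\n")
  cat("  cultures:     ", nrow(x$cultures), "\n")
  cat("  sofa inputs:  ", nrow(x$sofa_inputs), "\n")
  invisible(x)
}

#' Generate per-group lab records
#'
#' Draws one value per (subject, lab type) from the configured per-group
#' (mean, sd). Labs flagged `nonnegative` use a moment-matched zero-truncated
#' normal where one exists (see [rtruncnorm_mm()]); values are set missing
#' (`NA`) at the configured `missingness_rate`.
#'
#' @param config A [cohort_config()].
#' @param group `"sepsis"` or `"control"`.
#' @param n Number of subjects.
#' @param lab_types Lab types to draw; defaults to all configured types.
#'   Unknown types raise a configuration error.
#' @param seed Optional integer; when given, draws are made under this seed
#'   without touching the caller's RNG state.
#' @return A tibble with columns `subject`, `lab_type`, `value` (NA when
#'   missing).
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' panel <- generate_lab_panel(cfg, "sepsis", n = 100, seed = 7)
#' mean(panel$value[panel$lab_type == "albumin"], na.rm = TRUE)
generate_lab_panel <- function(config, group, n,
                               lab_types = NULL, seed = NULL) {
  group <- match.arg(group, c("sepsis", "control"))
  lp <- config$lab_params
  lab_types <- lab_types %||% lp$lab_type
  unknown <- setdiff(lab_types, lp$lab_type)
  if (length(unknown) > 0)
    abort(paste("unknown lab type(s):", paste(unknown, collapse = ", ")),
          class = "oncosepsis_config_error")
  draw <- function() {
    lp <- lp[match(lab_types, lp$lab_type), ]
    purrr::pmap(lp, function(lab_type, unit, mean_sepsis, sd_sepsis,
                             mean_control, sd_control, nonnegative, ...) {
      m <- if (group == "sepsis") mean_sepsis else mean_control
      s <- if (group == "sepsis") sd_sepsis else sd_control
      vals <- if (isTRUE(nonnegative)) rtruncnorm_mm(n, m, s) else rnorm(n, m, s)
      if (config$missingness_rate > 0)
        vals[runif(n) < config$missingness_rate] <- NA_real_
      tibble(subject = seq_len(n), lab_type = lab_type, value = vals)
    }) |>
      list_rbind() |>
      dplyr::arrange(.data$subject, .data$lab_type)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate SOFA-relevant trajectories and culture/antibiotic events
#'
#' For each ER visit, emits a pre-window baseline measurement set (all organ
#' systems near-normal) and an in-window follow-up. Sepsis-group patients get
#' a bacterial culture shortly after ER arrival, an intravenous antibiotic on
#' the culture date, and in-window measurements implying a SOFA rise of at
#' least 2 (thrombocytopenia, hypotension, renal impairment). Control
#' patients keep near-normal in-window values (rise at most 1); a configurable
#' fraction of them also receive a culture plus IV antibiotic so that the
#' labeler's window logic is exercised on nonsepsis visits.
#'
#' Vectorized over patients; draws come from the caller's RNG state unless
#' `seed` is given.
#'
#' @param group `"sepsis"` or `"control"` (applies to all patients passed).
#' @param er_time POSIXct vector of ER-visit times, one per patient.
#' @param config A [cohort_config()].
#' @param patient_id Character vector parallel to `er_time`.
#' @param seed Optional integer seed.
#' @return List of tibbles: `sofa_inputs` (patient_id, timestamp, pao2_fio2,
#'   platelets, bilirubin, map, vasopressor, gcs, creatinine), `cultures`
#'   (patient_id, timestamp), and `prescriptions` (patient_id, date, drug_id,
#'   route) holding the peri-culture IV antibiotics.
#' @export
generate_sofa_trajectory <- function(group, er_time, config,
                                     patient_id = paste0("P", seq_along(er_time)),
                                     seed = NULL) {
  group <- match.arg(group, c("sepsis", "control"))
  n <- length(er_time)
  gen <- function() {
    if (n == 0) {
      return(list(sofa_inputs = empty_sofa_inputs(), cultures = empty_cultures(),
                  prescriptions = empty_prescriptions()))
    }
    trunc_min <- function(x, lo) pmax(x, lo)
    baseline_t <- round_secs(er_time - 30 * 3600)
    base <- tibble(
      patient_id = patient_id, timestamp = baseline_t,
      pao2_fio2 = trunc_min(rnorm(n, 430, 30), 401),
      platelets = trunc_min(rnorm(n, 250, 40), 160),
      bilirubin = runif(n, 0.3, 1.0),
      map = trunc_min(rnorm(n, 85, 7), 72),
      vasopressor = FALSE, gcs = 15L,
      creatinine = runif(n, 0.5, 1.0)
    )
    follow_t <- round_secs(er_time + runif(n, 3, 8) * 3600)
    if (group == "sepsis") {
      has_culture <- rep(TRUE, n)
      follow <- tibble(
        patient_id = patient_id, timestamp = follow_t,
        pao2_fio2 = trunc_min(rnorm(n, 430, 30), 401),
        platelets = trunc_min(rnorm(n, 85, 10), 25),
        bilirubin = runif(n, 0.3, 1.0),
        map = pmin(rnorm(n, 60, 4), 68),
        vasopressor = runif(n) < 0.5, gcs = 15L,
        creatinine = trunc_min(rnorm(n, 2.3, 0.3), 1.3)
      )
    } else {
      has_culture <- runif(n) < config$control_culture_rate
      follow <- tibble(
        patient_id = patient_id, timestamp = follow_t,
        pao2_fio2 = trunc_min(rnorm(n, 450, 20), 410),
        platelets = trunc_min(rnorm(n, 230, 30), 160),
        bilirubin = runif(n, 0.3, 1.0),
        map = trunc_min(rnorm(n, 80, 5), 70.5),
        vasopressor = FALSE, gcs = 15L,
        creatinine = runif(n, 0.6, 1.3)
      )
    }
    culture_t <- round_secs(er_time + runif(n, 1, 6) * 3600)
    cultures <- tibble(patient_id = patient_id,
                       timestamp = culture_t)[has_culture, ]
    abx_ids <- config$drug_catalog$drugs$drug_id[config$drug_catalog$drugs$is_antibiotic]
    if (length(abx_ids) == 0)
      abort("drug catalog has no antibiotic", class = "oncosepsis_config_error")
    abx_pick <- abx_ids[1 + (runif(n) > 0.5) * (length(abx_ids) > 1)]
    prescriptions <- tibble(
      patient_id = patient_id,
      date = as.Date(culture_t, tz = "UTC"),
      drug_id = abx_pick, route = "IV"
    )[has_culture, ]
    list(
      sofa_inputs = dplyr::bind_rows(base, follow) |>
        dplyr::arrange(.data$patient_id, .data$timestamp),
      cultures = cultures,
      prescriptions = prescriptions
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

round_secs <- function(t) as.POSIXct(round(as.numeric(t)), origin = "1970-01-01", tz = "UTC")

empty_patients <- function() tibble(
  patient_id = character(), sex = character(), age = numeric(),
  weight = numeric(), cancer_type = character(), diagnosis_code = character())
empty_visits <- function() tibble(
  patient_id = character(), visit_id = character(),
  er_visit_time = as.POSIXct(character(), tz = "UTC"))
empty_labs <- function() tibble(
  patient_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
  lab_type = character(), value = numeric())
empty_prescriptions <- function() tibble(
  patient_id = character(), date = as.Date(character()),
  drug_id = character(), route = character())
empty_cultures <- function() tibble(
  patient_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"))
empty_sofa_inputs <- function() tibble(
  patient_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
  pao2_fio2 = numeric(), platelets = numeric(), bilirubin = numeric(),
  map = numeric(), vasopressor = logical(), gcs = integer(),
  creatinine = numeric())
empty_ground_truth <- function() tibble(patient_id = character(), group = character())

dx_codes <- list(
  liver = c("C22.0", "C22.1"),
  lung = c("C34.1", "C34.9"),
  breast = c("C50.4", "C50.9")
)

#' Generate a synthetic longitudinal EHR cohort
#'
#' Produces a full event-table bundle — patients, ER visits, window lab
#' records, daily prescriptions, bacterial cultures and SOFA-relevant raw
#' measurements — with the statistical structure the downstream analysis
#' assumes: per-group demographics and cancer mix, per-group lab
#' distributions, group-differential co-prescription frequencies, and
#' Sepsis-3-consistent SOFA trajectories. Ground-truth group membership is
#' returned as separate metadata, never encoded in the events themselves.
#' Identical `config` (including its seed) yields byte-identical output.
#'
#' @param config A [cohort_config()].
#' @return A `sepsis_cohort`: a list of tibbles `patients`, `visits`, `labs`,
#'   `prescriptions`, `cultures`, `sofa_inputs`, and `ground_truth`
#'   (patient_id, group).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_control = 30, n_sepsis = 15, seed = 42))
#' cohort
generate_cohort <- function(config) {
  validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n_all <- config$n_control + config$n_sepsis
  if (n_all == 0) {
    return(new_sepsis_cohort(empty_patients(), empty_visits(), empty_labs(),
                             empty_prescriptions(), empty_cultures(),
                             empty_sofa_inputs(), empty_ground_truth()))
  }
  width <- max(4, nchar(as.character(n_all)))
  ids <- sprintf(paste0("P%0", width, "d"), seq_len(n_all))
  groups <- rep(c("control", "sepsis"), c(config$n_control, config$n_sepsis))
  ground_truth <- tibble(patient_id = ids, group = groups)

  parts <- purrr::map(c("control", "sepsis"), function(g) {
    idx <- which(groups == g)
    n <- length(idx)
    if (n == 0) return(NULL)
    pid <- ids[idx]
    mix <- config$cancer_mix_by_group[[g]]
    cancer <- sample(names(mix), n, replace = TRUE, prob = mix)
    dx <- map_chr(cancer, function(ct) sample(dx_codes[[ct]], 1))
    ap <- config$age_params[[g]]; wp <- config$weight_params[[g]]
    patients <- tibble(
      patient_id = pid,
      sex = ifelse(runif(n) < config$male_fraction_by_group[[g]], "male", "female"),
      age = pmin(pmax(rnorm(n, ap[["mean"]], ap[["sd"]]), 18), 95),
      weight = pmin(pmax(rnorm(n, wp[["mean"]], wp[["sd"]]), 30), 150),
      cancer_type = cancer, diagnosis_code = dx
    )
    er0 <- as.POSIXct("2014-01-01 00:00:00", tz = "UTC")
    er_time <- round_secs(er0 + runif(n, 0, 6 * 365.25 * 86400))
    visits <- tibble(patient_id = pid, visit_id = paste0(pid, "-V1"),
                     er_visit_time = er_time)
    # lab records inside the 2-7 day observation window before the ER visit
    panel <- generate_lab_panel(config, g, n)
    labs <- panel |>
      dplyr::mutate(
        patient_id = pid[.data$subject],
        timestamp = round_secs(er_time[.data$subject] -
                                 runif(nrow(panel), 2, 7) * 86400)
      ) |>
      dplyr::select("patient_id", "timestamp", "lab_type", "value")
    prescriptions <- generate_window_prescriptions(g, er_time, config, pid)
    traj <- generate_sofa_trajectory(g, er_time, config, patient_id = pid)
    list(patients = patients, visits = visits, labs = labs,
         prescriptions = dplyr::bind_rows(prescriptions, traj$prescriptions),
         cultures = traj$cultures, sofa_inputs = traj$sofa_inputs)
  })
  parts <- purrr::compact(parts)
  pull <- function(nm) {
    purrr::map(parts, nm) |> list_rbind() |> dplyr::arrange(.data$patient_id)
  }
  new_sepsis_cohort(
    patients = pull("patients"), visits = pull("visits"),
    labs = pull("labs") |> dplyr::arrange(.data$patient_id, .data$lab_type),
    prescriptions = pull("prescriptions") |>
      dplyr::arrange(.data$patient_id, .data$date, .data$drug_id),
    cultures = pull("cultures"), sofa_inputs = pull("sofa_inputs"),
    ground_truth = ground_truth
  )
}

# Daily prescription baskets over the 2-7 day observation window.
# Each drug enters a patient-day independently at its per-group daily
# probability; boost pairs are additionally forced in jointly at the
# per-group boost probability, producing the group-differential
# co-prescription support the association miner should detect.
generate_window_prescriptions <- function(group, er_time, config, patient_id) {
  drugs <- config$drug_catalog$drugs
  boosts <- config$drug_catalog$boost_pairs
  n <- length(patient_id)
  days_back <- 2:7
  grid <- tidyr::expand_grid(pi = seq_len(n), day_back = days_back)
  grid$date <- as.Date(er_time[grid$pi], tz = "UTC") - grid$day_back
  p_col <- if (group == "sepsis") drugs$p_daily_sepsis else drugs$p_daily_control
  hits <- purrr::map(seq_len(nrow(drugs)), function(j) {
    on <- runif(nrow(grid)) < p_col[j]
    tibble(pi = grid$pi[on], date = grid$date[on], drug_id = drugs$drug_id[j])
  }) |> list_rbind()
  if (nrow(boosts) > 0) {
    b_col <- if (group == "sepsis") boosts$boost_sepsis else boosts$boost_control
    boost_hits <- purrr::map(seq_len(nrow(boosts)), function(j) {
      on <- runif(nrow(grid)) < b_col[j]
      tibble(pi = rep(grid$pi[on], 2), date = rep(grid$date[on], 2),
             drug_id = rep(c(boosts$drug_a[j], boosts$drug_b[j]), each = sum(on)))
    }) |> list_rbind()
    hits <- dplyr::bind_rows(hits, boost_hits)
  }
  hits <- dplyr::distinct(hits, .data$pi, .data$date, .data$drug_id)
  is_abx <- hits$drug_id %in% drugs$drug_id[drugs$is_antibiotic]
  route <- ifelse(runif(nrow(hits)) < ifelse(is_abx, 0.8, 0.2), "IV", "oral")
  tibble(patient_id = patient_id[hits$pi], date = hits$date,
         drug_id = hits$drug_id, route = route)
}

#' Write / read a cohort as delimited text files
#'
#' One UTF-8 comma-separated file per event stream (`patients.csv`,
#' `visits.csv`, `labs.csv`, `prescriptions.csv`, `cultures.csv`,
#' `sofa_inputs.csv`) plus `ground_truth.csv`. Timestamps are ISO-8601 UTC,
#' dates `YYYY-MM-DD`; `read_cohort()` restores column types so a write/read
#' round trip reproduces the cohort exactly.
#'
#' @param cohort A `sepsis_cohort`.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns a
#'   `sepsis_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(cohort)) {
    readr::write_csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")), na = "")
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  col_specs <- list(
    patients = readr::cols(patient_id = "c", sex = "c", age = "d", weight = "d",
                           cancer_type = "c", diagnosis_code = "c"),
    visits = readr::cols(patient_id = "c", visit_id = "c",
                         er_visit_time = readr::col_datetime()),
    labs = readr::cols(patient_id = "c", timestamp = readr::col_datetime(),
                       lab_type = "c", value = "d"),
    prescriptions = readr::cols(patient_id = "c", date = readr::col_date(),
                                drug_id = "c", route = "c"),
    cultures = readr::cols(patient_id = "c", timestamp = readr::col_datetime()),
    sofa_inputs = readr::cols(patient_id = "c", timestamp = readr::col_datetime(),
                              pao2_fio2 = "d", platelets = "d", bilirubin = "d",
                              map = "d", vasopressor = "l", gcs = "i",
                              creatinine = "d"),
    ground_truth = readr::cols(patient_id = "c", group = "c")
  )
  tabs <- purrr::imap(col_specs, function(spec, nm) {
    df <- readr::read_csv(file.path(dir, paste0(nm, ".csv")),
                          col_types = spec, na = "", progress = FALSE)
    dt <- vapply(df, inherits, logical(1), "POSIXct")
    df[dt] <- lapply(df[dt], function(x) { attr(x, "tzone") <- "UTC"; x })
    df
  })
  do.call(new_sepsis_cohort, tabs)
}
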