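ts <- function(h) as.POSIXct("2016-03-01 00:00:00", tz = "UTC") + h * 3600

test_that("SOFA subscores follow the threshold table", {
  # independent fixture: hand-written expected subscores for the standard
  # six-system table, kept separate from the shipped YAML
  fixture <- tibble::tribble(
    ~measure,     ~value, ~system,          ~expected,
    "platelets",  250,    "coagulation",    0L,
    "platelets",  149,    "coagulation",    1L,
    "platelets",  90,     "coagulation",    2L,
    "platelets",  49,     "coagulation",    3L,
    "platelets",  15,     "coagulation",    4L,
    "bilirubin",  0.5,    "liver",          0L,
    "bilirubin",  1.2,    "liver",          1L,
    "bilirubin",  2.0,    "liver",          2L,
    "bilirubin",  6.0,    "liver",          3L,
    "bilirubin",  12.0,   "liver",          4L,
    "map",        80,     "cardiovascular", 0L,
    "map",        69,     "cardiovascular", 1L,
    "gcs",        15,     "cns",            0L,
    "gcs",        13,     "cns",            1L,
    "gcs",        10,     "cns",            2L,
    "gcs",        6,      "cns",            3L,
    "gcs",        3,      "cns",            4L,
    "creatinine", 1.0,    "renal",          0L,
    "creatinine", 1.2,    "renal",          1L,
    "creatinine", 2.0,    "renal",          2L,
    "creatinine", 3.5,    "renal",          3L,
    "creatinine", 5.0,    "renal",          4L,
    "pao2_fio2",  450,    "respiration",    0L,
    "pao2_fio2",  399,    "respiration",    1L,
    "pao2_fio2",  299,    "respiration",    2L
  )
  for (i in seq_len(nrow(fixture))) {
    m <- setNames(list(fixture$value[i]), fixture$measure[i])
    sc <- compute_sofa_score(m)
    expect_equal(sc[[fixture$system[i]]], fixture$expected[i],
                 label = paste(fixture$measure[i], fixture$value[i]))
  }
  # ventilation gate: ratio < 200 caps at 2 without support, scores 3 with
  expect_equal(compute_sofa_score(list(pao2_fio2 = 150))$respiration, 2L)
  expect_equal(compute_sofa_score(list(pao2_fio2 = 150,
                                       on_ventilation = TRUE))$respiration, 3L)
  expect_equal(compute_sofa_score(list(pao2_fio2 = 80,
                                       on_ventilation = TRUE))$respiration, 4L)
  # vasopressor presence dominates MAP
  expect_equal(compute_sofa_score(list(map = 80, vasopressor = TRUE))$cardiovascular, 2L)
})

test_that("absent components score zero and are flagged", {
  sc <- compute_sofa_score(list(heart_rate = 90)) # no SOFA component at all
  expect_equal(sc$total, 0)
  expect_setequal(sc$components_missing[[1]],
                  c("respiration", "coagulation", "liver", "cardiovascular",
                    "cns", "renal"))
  # all-normal physiology scores zero with nothing missing
  sc2 <- compute_sofa_score(list(platelets = 250, bilirubin = 0.5, map = 80,
                                 gcs = 15, creatinine = 0.8, pao2_fio2 = 450,
                                 vasopressor = FALSE))
  expect_equal(sc2$total, 0)
  expect_length(sc2$components_missing[[1]], 0)
  # isolated thrombocytopenia
  sc3 <- compute_sofa_score(list(platelets = 90, bilirubin = 0.5, map = 80,
                                 gcs = 15, creatinine = 0.8, pao2_fio2 = 450))
  expect_equal(sc3$total, 2)
  expect_equal(sc3$coagulation, 2L)
})

test_that("negative physiological measurements are rejected", {
  expect_error(compute_sofa_score(list(platelets = -1)),
               class = "oncosepsis_validation_error")
  expect_error(compute_sofa_score(list(creatinine = -0.5)),
               class = "oncosepsis_validation_error")
  expect_error(compute_sofa_score(list(bilirubin = -2)),
               class = "oncosepsis_validation_error")
})

test_that("infection windows require an in-window IV antibiotic", {
  cultures <- tibble::tibble(patient_id = "P1", timestamp = ts(0))
  rx <- function(h, route) tibble::tibble(
    patient_id = "P1", date = as.Date(ts(h), tz = "UTC"), drug_id = "abx",
    route = route, timestamp = ts(h))
  w <- find_infection_windows(cultures, rx(10, "IV"), "abx")
  expect_equal(nrow(w), 1)
  expect_equal(w$window_start, ts(-24))
  expect_equal(w$window_end, ts(24))
  # out of window
  expect_equal(nrow(find_infection_windows(cultures, rx(30, "IV"), "abx")), 0)
  # oral route ignored
  expect_equal(nrow(find_infection_windows(cultures, rx(1, "oral"), "abx")), 0)
  # boundary at exactly 24 h is inclusive; route is case-insensitive
  expect_equal(nrow(find_infection_windows(cultures, rx(24, "iv"), "abx")), 1)
  expect_equal(nrow(find_infection_windows(cultures, rx(-24, "Iv"), "abx")), 1)
  # non-antibiotic drug ignored
  expect_equal(nrow(find_infection_windows(cultures, rx(1, "IV"), "other")), 0)
})

test_that("the 2-point SOFA rise rule labels visits", {
  win <- tibble::tibble(window_start = ts(-24), window_end = ts(24))
  series <- function(hours, totals) tibble::tibble(timestamp = ts(hours),
                                                   total = totals)
  # no pre-window measurement: baseline treated as 0, in-window total 2 triggers
  v <- label_visit(series(2, 2), win, ts(0))
  expect_equal(v$label, "sepsis")
  expect_equal(v$baseline_sofa, 0)
  expect_equal(v$max_delta, 2)
  # delta below threshold
  v2 <- label_visit(series(c(-30, 2), c(3, 4)), win, ts(0))
  expect_equal(v2$label, "nonsepsis")
  expect_equal(v2$max_delta, 1)
  # delta well above threshold
  v3 <- label_visit(series(c(-30, 2), c(1, 6)), win, ts(0))
  expect_equal(v3$label, "sepsis")
  expect_equal(v3$max_delta, 5)
  # empty series: baseline 0 and nothing in window
  v4 <- label_visit(series(numeric(), numeric()), win, ts(0))
  expect_equal(v4$label, "nonsepsis")
  # no windows at all
  v5 <- label_visit(series(2, 6), win[0, ], ts(0))
  expect_equal(v5$label, "nonsepsis")
})

test_that("the earliest satisfying window is the trigger", {
  wins <- tibble::tibble(window_start = ts(c(-24, 10)),
                         window_end = ts(c(24, 58)))
  v <- label_visit(tibble::tibble(timestamp = ts(c(2, 40)), total = c(3, 5)),
                   wins, ts(0))
  expect_equal(v$label, "sepsis")
  expect_equal(v$window_start, ts(-24))
})

test_that("label_visit agrees with exhaustive window-by-assessment enumeration", {
  set.seed(404)
  for (trial in 1:60) {
    n_obs <- sample(0:20, 1)
    series <- tibble::tibble(
      timestamp = ts(sort(runif(n_obs, -72, 72))),
      total = sample(0:10, n_obs, replace = TRUE))
    n_win <- sample(0:3, 1)
    starts <- runif(n_win, -48, 24)
    wins <- tibble::tibble(window_start = ts(starts),
                           window_end = ts(starts + 48))
    got <- label_visit(series, wins, ts(0))$label
    expect_equal(got, label_by_enumeration(series, wins))
  }
})

test_that("raising in-window severity never decreases the delta", {
  win <- tibble::tibble(window_start = ts(-24), window_end = ts(24))
  base <- list(platelets = 250, bilirubin = 0.5, map = 80, gcs = 15,
               creatinine = 0.8, pao2_fio2 = 450)
  worsen <- seq(0.8, 6, length.out = 12)
  deltas <- vapply(worsen, function(cr) {
    m <- base; m$creatinine <- cr
    series <- tibble::tibble(
      timestamp = ts(c(-30, 3)),
      total = c(compute_sofa_score(base)$total, compute_sofa_score(m)$total))
    label_visit(series, win, ts(0))$max_delta
  }, numeric(1))
  expect_true(all(diff(deltas) >= 0))
})

test_that("relabelling a cohort is idempotent", {
  co <- generate_cohort(tiny_config(seed = 8))
  expect_identical(label_cohort(co), label_cohort(co))
})

test_that("last observation is carried forward per component", {
  inputs <- tibble::tibble(
    patient_id = "P1", timestamp = ts(c(-30, 3)),
    platelets = c(250, NA), map = c(80, 60), bilirubin = c(0.5, NA),
    gcs = c(15L, NA), creatinine = c(0.8, 2.5), pao2_fio2 = c(450, NA),
    vasopressor = c(FALSE, NA))
  series <- compute_sofa_series(inputs)
  # at t=3h platelets/bilirubin/gcs carried from baseline; creatinine new
  expect_equal(series$total, c(0, 1 + 2)) # map<70 (1) + creatinine>=2 (2)
  expect_length(series$components_missing[[2]], 0)
})
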