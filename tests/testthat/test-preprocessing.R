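er <- as.POSIXct("2016-05-10 12:00:00", tz = "UTC")

test_that("the observation window keeps only events 2-7 days before the visit", {
  ev <- function(days_before) tibble::tibble(timestamp = er - days_before * 86400,
                                             what = "x")
  expect_false(filter_observation_window(ev(1), er)$keep)   # too close
  expect_true(filter_observation_window(ev(3), er)$keep)    # interior
  expect_false(filter_observation_window(ev(8), er)$keep)   # too early
  expect_true(filter_observation_window(ev(2), er)$keep)    # inclusive edges
  expect_true(filter_observation_window(ev(7), er)$keep)
  # date-typed events use day arithmetic
  dev <- tibble::tibble(date = as.Date(er) - 3)
  expect_true(filter_observation_window(dev, er)$keep)
  mixed <- dplyr::bind_rows(ev(1), ev(3), ev(9))
  out <- filter_observation_window(mixed, er)
  expect_equal(nrow(out$events), 1)
})

test_that("diagnosis codes standardize to 3 characters", {
  expect_equal(standardize_diagnosis_code("C22.0"), "C22")
  expect_equal(standardize_diagnosis_code("c34"), "C34")
  expect_equal(standardize_diagnosis_code("C509"), "C50")
  expect_equal(standardize_diagnosis_code(c("C22.0", "c50.9")), c("C22", "C50"))
  expect_error(standardize_diagnosis_code("C2"),
               class = "oncosepsis_validation_error")
})

test_that("lab coverage filtering is strict and monotone", {
  mk_labs <- function(n_with) tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n_with)),
    lab_type = "alb", value = 1)
  pats <- sprintf("P%03d", 1:100)
  expect_equal(filter_lab_coverage(mk_labs(55), pats), character())
  expect_equal(filter_lab_coverage(mk_labs(61), pats), "alb")
  expect_equal(filter_lab_coverage(mk_labs(60), pats), character()) # strict >
  expect_error(filter_lab_coverage(mk_labs(10), character()),
               class = "oncosepsis_validation_error")
  # NA values do not count as measurements
  labs_na <- tibble::tibble(patient_id = pats, lab_type = "alb",
                            value = c(rep(1, 50), rep(NA, 50)))
  expect_equal(filter_lab_coverage(labs_na, pats), character())
  # monotone: raising the threshold can only shrink the selection
  labs2 <- dplyr::bind_rows(mk_labs(70),
                            tibble::tibble(patient_id = sprintf("P%03d", 1:50),
                                           lab_type = "bili", value = 1))
  sel <- lapply(c(0.3, 0.5, 0.65, 0.9),
                function(f) filter_lab_coverage(labs2, pats, f))
  for (i in seq_len(length(sel) - 1)) {
    expect_true(all(sel[[i + 1]] %in% sel[[i]]))
  }
})

test_that("robust outlier removal follows the MAD rule", {
  expect_equal(remove_outliers(rep(3, 10)), rep(3, 10)) # zero spread
  expect_equal(remove_outliers(c(1, 1, 1, 1, 1000)), c(1, 1, 1, 1, NA))
  x <- c(10, 10.5, 11, 9.5, 9)                           # all within 1 MAD
  expect_equal(remove_outliers(x), x)
  # hand-derived robust z: median 5, mad 1.4826*1; 5 + 5*1.4826 < 13
  expect_equal(remove_outliers(c(4, 5, 6, 5, 13)), c(4, 5, 6, 5, NA))
})

test_that("stratified mean imputation fills by the closest populated stratum", {
  df <- tibble::tibble(
    cancer_type = c("lung", "lung", "lung", "liver"),
    sex = c("male", "male", "male", "female"),
    age = c(60, 61, 62, 70),
    lab_x = c(3, 5, NA, 7))
  out <- impute_missing(df)
  expect_equal(out$lab_x[3], 4) # mean of its (lung, male, 60-65) stratum
  # no missing values: table unchanged
  expect_equal(impute_missing(out), out)
  # singleton stratum with only a missing value falls back
  df2 <- tibble::tibble(
    cancer_type = c("lung", "lung", "lung"),
    sex = c("male", "male", "male"),
    age = c(60, 61, 90), # the 90-year-old is alone in their age bin
    lab_x = c(2, 4, NA))
  expect_equal(impute_missing(df2)$lab_x[3], 3) # (lung, male) mean
  # global fallback once cancer and sex strata are exhausted
  df3 <- tibble::tibble(
    cancer_type = c("lung", "liver"), sex = c("male", "female"),
    age = c(60, 70), lab_x = c(6, NA))
  expect_equal(impute_missing(df3)$lab_x[2], 6)
  expect_error(impute_missing(tibble::tibble(
    cancer_type = "lung", sex = "male", age = 60, lab_x = NA_real_)),
    class = "oncosepsis_validation_error")
})

test_that("the assembled feature table is complete and manifest-consistent", {
  cfg <- tiny_config(n_control = 60, n_sepsis = 30, seed = 21)
  co <- generate_cohort(cfg)
  labels <- label_cohort(co)
  ft <- build_feature_table(co, labels)
  manifest <- feature_manifest(ft)
  expect_equal(anyDuplicated(manifest$name), 0)
  feat_cols <- intersect(manifest$name, names(ft))
  expect_false(anyNA(ft[feat_cols]))           # imputation left no gaps
  expect_equal(nrow(ft), nrow(labels))         # imputation drops no rows
  # one-hot encodings are 0/1
  oh <- manifest$name[manifest$encoding %in% c("one_hot", "binary")]
  expect_true(all(unlist(ft[oh]) %in% c(0L, 1L)))
  # nested feature sets select by source stage
  ehr <- select_feature_set(ft, "ehr_only")
  expect_false(any(grepl("^lab_", names(ehr))))
  full <- select_feature_set(ft, "ehr_drug_lab")
  expect_true(ncol(full) >= ncol(ehr))
})

test_that("feature assembly is invariant to input row order", {
  cfg <- tiny_config(n_control = 30, n_sepsis = 15, seed = 33)
  co <- generate_cohort(cfg)
  labels <- label_cohort(co)
  ft1 <- build_feature_table(co, labels)
  co2 <- co
  set.seed(5)
  for (nm in c("labs", "prescriptions", "patients")) {
    co2[[nm]] <- co2[[nm]][sample(nrow(co2[[nm]])), ]
  }
  ft2 <- build_feature_table(co2, labels)
  ft2 <- ft2[match(ft1$visit_id, ft2$visit_id), names(ft1)]
  expect_equal(as.data.frame(ft1), as.data.frame(ft2), ignore_attr = TRUE)
})
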