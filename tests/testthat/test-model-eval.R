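test_that("classification metrics evaluate the confusion table directly", {
  # perfect scorer
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_true(all(unlist(m) == 1))
  # TP=2 FP=1 FN=1 TN=6
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  s <- c(0.9, 0.8, 0.2, 0.7, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  m2 <- compute_metrics(y, s)
  expect_equal(m2$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(m2$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(m2$f1, 2 / 3, tolerance = 1e-12)
  expect_equal(m2$accuracy, 0.8)
  # uninformative constant scorer on balanced classes
  expect_equal(compute_metrics(c(1, 1, 0, 0), rep(0.5, 4))$auroc, 0.5)
  expect_error(auroc(c(1, 1), c(0.2, 0.3)),
               class = "oncosepsis_validation_error")
  expect_error(auprc(c(0, 0), c(0.2, 0.3)),
               class = "oncosepsis_validation_error")
})

test_that("AUROC equals the normalized Mann-Whitney U statistic", {
  set.seed(14)
  for (trial in 1:30) {
    n1 <- sample(2:15, 1); n0 <- sample(2:15, 1)
    y <- c(rep(1, n1), rep(0, n0))
    s <- round(runif(n1 + n0), sample(1:2, 1)) # rounding forces ties
    u <- suppressWarnings(wilcox.test(s[y == 1], s[y == 0]))$statistic
    expect_equal(auroc(y, s), unname(u) / (n1 * n0), tolerance = 1e-8)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  y <- rbinom(60, 1, 0.4); s <- runif(60)
  expect_equal(auroc(y, s),
               as.numeric(suppressMessages(pROC::auc(y, s))),
               tolerance = 1e-8)
})

test_that("AUPRC integrates the precision-recall steps", {
  # scores separate 3 of 4 positives cleanly: hand-integrated AP
  y <- c(1, 1, 1, 0, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  # thresholds descending: recall gains at ranks 1,2,3 (prec 1) and rank 5 (prec 4/5)
  want <- 3 / 4 * 1 + 1 / 4 * (4 / 5)
  expect_equal(auprc(y, s), want, tolerance = 1e-12)
  expect_equal(auprc(c(1, 0), c(0.9, 0.1)), 1)
  # F1 identity wherever defined
  set.seed(3)
  for (trial in 1:20) {
    y <- rbinom(30, 1, 0.5); s <- runif(30)
    if (length(unique(y)) < 2) next
    m <- compute_metrics(y, s)
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-12)
    }
  }
})

test_that("feature reshaping follows each family's input convention", {
  r <- reshape_features(matrix(0, 3, 1738), "conv_resnet")
  expect_equal(r$shape, c(1, 42, 42))
  expect_equal(r$n_pad, 26)
  expect_equal(dim(r$data), c(3, 1764))
  expect_error(reshape_features(matrix(0, 2, 1800), "conv_resnet"),
               class = "oncosepsis_validation_error")
  flat <- reshape_features(matrix(0, 5, 4), "logistic_regression")
  expect_equal(flat$shape, c(5, 4))
  seqs <- list(matrix(1, 2, 3), matrix(2, 5, 3))
  r2 <- reshape_features(matrix(0, 2, 3), "recurrent_lstm", sequences = seqs)
  expect_equal(r2$shape, c(2, 5, 3))
  expect_equal(r2$data[1, 3:5, ], matrix(0, 3, 3)) # zero padding
})

sep_data <- function(n = 80, noise = 0.05, seed = 10) {
  withr::with_seed(seed, {
    x <- tibble::tibble(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
    list(x = x, y = as.integer(x$f1 + noise * rnorm(n) > 0))
  })
}

test_that("cross-validation separates separable data and is deterministic", {
  d <- sep_data()
  for (fam in c("logistic_regression", "random_forest")) {
    ev <- run_cross_validation(d$x, d$y, model_config(fam, seed = 4))
    expect_gte(ev$aggregate$auroc, 0.99)
    expect_equal(nrow(ev$per_fold), 5)
    expect_true(all(unlist(ev$per_fold[-1]) >= 0 & unlist(ev$per_fold[-1]) <= 1))
    # same config + seed: identical report
    ev2 <- run_cross_validation(d$x, d$y, model_config(fam, seed = 4))
    expect_identical(ev$per_fold, ev2$per_fold)
    expect_identical(ev$aggregate, ev2$aggregate)
  }
  # aggregate is the arithmetic fold mean
  ev <- run_cross_validation(d$x, d$y, model_config("random_forest", seed = 4))
  expect_equal(ev$aggregate$auroc, mean(ev$per_fold$auroc))
  expect_error(
    run_cross_validation(d$x[1:8, ], d$y[1:8],
                         model_config("logistic_regression"), n_folds = 7),
    class = "oncosepsis_validation_error")
})

test_that("permuted labels give chance-level AUROC", {
  d <- sep_data(n = 60)
  aurocs <- vapply(1:20, function(s) {
    y_perm <- withr::with_seed(1000 + s, sample(d$y))
    run_cross_validation(d$x, y_perm,
                         model_config("logistic_regression", seed = s),
                         n_folds = 4)$aggregate$auroc
  }, numeric(1))
  expect_gt(mean(aurocs), 0.4)
  expect_lt(mean(aurocs), 0.6)
})

test_that("every model family trains and scores at smoke scale", {
  d <- sep_data(n = 60)
  for (fam in c("feedforward_net", "conv_resnet", "recurrent_lstm")) {
    ev <- run_cross_validation(d$x, d$y, model_config(fam, seed = 6), n_folds = 3)
    expect_true(all(unlist(ev$aggregate) >= 0 & unlist(ev$aggregate) <= 1))
    ev2 <- run_cross_validation(d$x, d$y, model_config(fam, seed = 6), n_folds = 3)
    expect_equal(ev$aggregate, ev2$aggregate)
  }
})

test_that("held-out labels never influence the training-fold fit", {
  d <- sep_data(n = 40)
  tr <- 1:30; te <- 31:40
  x <- as.matrix(d$x)
  fit_and_score <- function(y_test) {
    withr::with_seed(11, {
      sc <- oncosepsis:::scale01(x[tr, ])
      fit <- oncosepsis:::fit_family(sc$x, d$y[tr],
                                     model_config("random_forest", seed = 11))
      oncosepsis:::predict_scores(fit, oncosepsis:::scale01(x[te, ], sc$scaler)$x)
    })
  }
  expect_identical(fit_and_score(d$y[te]), fit_and_score(1 - d$y[te]))
})

test_that("grid search picks the best configuration deterministically", {
  d <- sep_data(n = 70)
  single <- grid_search(d$x, d$y, "random_forest",
                        grid = list(list(n_trees = 7)), seed = 2)
  expect_equal(single$hyperparameters$n_trees, 7)
  # an effectively untrained network versus a sane one on separable data
  grid <- list(list(hidden_units = 1, maxit = 1),
               list(hidden_units = 8, maxit = 200))
  best <- grid_search(d$x, d$y, "feedforward_net", grid = grid, seed = 2)
  expect_equal(best$hyperparameters$hidden_units, 8)
  best2 <- grid_search(d$x, d$y, "feedforward_net", grid = grid, seed = 2)
  expect_identical(attr(best, "grid_auroc"), attr(best2, "grid_auroc"))
  # ties break toward the first-listed grid point
  tie <- grid_search(d$x, d$y, "random_forest",
                     grid = list(list(n_trees = 5), list(n_trees = 5)), seed = 3)
  expect_identical(attr(tie, "grid_auroc")[1], max(attr(tie, "grid_auroc")))
})

test_that("hyperparameters are validated against the family schema", {
  expect_error(model_config("random_forest", list(n_trees = 0)),
               class = "oncosepsis_validation_error")
  expect_error(model_config("logistic_regression", list(n_trees = 5)),
               class = "oncosepsis_validation_error")
  expect_error(model_config("gradient_boosting"))
})

test_that("tidy and glance summarize an evaluation", {
  d <- sep_data(n = 50)
  ev <- run_cross_validation(d$x, d$y, model_config("logistic_regression",
                                                    seed = 3), n_folds = 4)
  td <- tidy(ev)
  expect_equal(nrow(td), 4 * 6)
  expect_setequal(unique(td$metric),
                  c("accuracy", "auroc", "auprc", "precision", "recall", "f1"))
  gl <- glance(ev)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$auroc, ev$aggregate$auroc)
  expect_s3_class(autoplot(ev), "ggplot")
})
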