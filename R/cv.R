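stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated evaluation of one model configuration
#'
#' Stratified k-fold cross-validation (fold assignment controlled by the
#' config seed). All preprocessing statistics — feature centering and scaling
#' — are fitted inside each training fold only, the model is fitted on the
#' training folds, and the six metrics are computed on the held-out fold's
#' predictions. Both the fold-mean aggregate and the pooled-prediction
#' variant are reported; the fold mean is the headline aggregate.
#'
#' @param data Feature tibble (id columns dropped automatically).
#' @param labels Visit labels (`"sepsis"`/`"nonsepsis"`, 0/1, or factor);
#'   defaults to `data$group_label` when present.
#' @param config A [model_config()].
#' @param n_folds Number of folds (default 5; must be >= 2 with at least
#'   `n_folds` rows per class).
#' @param threshold Binarization threshold for the thresholded metrics.
#' @return A `sepsis_eval`: list with `per_fold` (tibble of the six metrics
#'   per fold), `aggregate` (their mean), `pooled` (metrics of pooled
#'   held-out predictions), `model_config`, `n_folds`.
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(f1 = rnorm(60), f2 = rnorm(60))
#' y <- as.integer(d$f1 + rnorm(60, sd = 0.3) > 0)
#' run_cross_validation(d, y, model_config("logistic_regression"), n_folds = 3)
run_cross_validation <- function(data, labels = NULL, config,
                                 n_folds = 5, threshold = 0.5) {
  labels <- labels %||% data$group_label
  y <- normalize_labels(labels)
  x <- numeric_feature_matrix(data)
  stopifnot(n_folds >= 2)
  if (min(table(y)) < n_folds)
    abort("need at least n_folds rows per class",
          class = "oncosepsis_validation_error")
  withr::with_seed(config$seed, {
    fold <- stratified_folds(y, n_folds)
    pooled_scores <- numeric(length(y))
    per_fold <- purrr::map(seq_len(n_folds), function(k) {
      tr <- fold != k; te <- !tr
      if (length(unique(y[tr])) < 2)
        abort("a class is absent from a training fold",
              class = "oncosepsis_validation_error")
      sc <- scale01(x[tr, , drop = FALSE])
      fit <- fit_family(sc$x, y[tr], config)
      scores <- predict_scores(fit, scale01(x[te, , drop = FALSE], sc$scaler)$x)
      pooled_scores[te] <<- scores
      compute_metrics(y[te], scores, threshold) |>
        dplyr::mutate(fold = k, .before = 1)
    }) |> list_rbind()
    structure(list(
      per_fold = per_fold,
      aggregate = dplyr::summarise(per_fold,
                                   dplyr::across(-"fold", mean))[1, ],
      pooled = compute_metrics(y, pooled_scores, threshold),
      model_config = config, n_folds = n_folds
    ), class = "sepsis_eval")
  })
}

#' @export
print.sepsis_eval <- function(x, ...) {
  cat("<sepsis_eval> ", x$model_config$family, " / ",
      x$model_config$feature_set, ", ", x$n_folds, "-fold CV\n", sep = "")
  agg <- x$aggregate
  cat(sprintf("  accuracy %.3f  AUROC %.3f  AUPRC %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
              agg$accuracy, agg$auroc, agg$auprc, agg$precision, agg$recall,
              agg$f1))
  invisible(x)
}

#' @rdname run_cross_validation
#' @param x A `sepsis_eval`.
#' @param ... Unused.
#' @export
tidy.sepsis_eval <- function(x, ...) {
  x$per_fold |>
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value")
}

#' @rdname run_cross_validation
#' @export
glance.sepsis_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble(family = x$model_config$family,
           feature_set = x$model_config$feature_set,
           n_folds = x$n_folds),
    x$aggregate
  )
}

#' @rdname run_cross_validation
#' @param object A `sepsis_eval`.
#' @export
autoplot.sepsis_eval <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$metric, y = .data$value)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_jitter(width = 0.1, alpha = 0.7, size = 1.5) +
    stat_summary(fun = mean, geom = "point", shape = 4, size = 3,
                 colour = "red3") +
    ylim(0, 1) +
    labs(x = NULL, y = "held-out value",
         title = paste(object$model_config$family, "-",
                       object$model_config$feature_set)) +
    theme_minimal()
}

#' Hyperparameter grid search
#'
#' Exhaustively evaluates each grid point by cross-validation on the supplied
#' (training) data and returns the configuration with the highest mean AUROC;
#' ties are broken by the first-listed grid point. Deterministic given the
#' seed and grid order.
#'
#' @param data,labels As in [run_cross_validation()].
#' @param family Model family name.
#' @param grid Nonempty list of hyperparameter lists.
#' @param n_folds Folds of the inner cross-validation (default 3).
#' @param seed Seed shared by every grid point's fold assignment.
#' @return The winning [model_config()], with the grid AUROCs attached as
#'   attribute `"grid_auroc"`.
#' @export
grid_search <- function(data, labels = NULL, family, grid,
                        n_folds = 3, seed = 1L) {
  stopifnot(length(grid) > 0)
  configs <- purrr::map(grid, function(hp) model_config(family, hp, seed = seed))
  aurocs <- purrr::map_dbl(configs, function(cfg) {
    run_cross_validation(data, labels, cfg, n_folds = n_folds)$aggregate$auroc
  })
  best <- configs[[which.max(aurocs)]] # which.max takes the first maximum
  attr(best, "grid_auroc") <- aurocs
  best
}
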