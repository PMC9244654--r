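model_families <- c("logistic_regression", "random_forest",
                    "feedforward_net", "conv_resnet", "recurrent_lstm")

default_hyperparameters <- list(
  logistic_regression = list(maxit = 100),
  random_forest = list(n_trees = 20, mtry = NULL),
  feedforward_net = list(hidden_units = 8, decay = 0.01, maxit = 200),
  conv_resnet = list(n_filters = 4, n_blocks = 2),
  recurrent_lstm = list(hidden_units = 8)
)

#' Build a model configuration
#'
#' Bundles a classifier family, its hyperparameters (validated against the
#' family's schema), the nested feature set it trains on, and a seed. The
#' random-forest default is 20 trees.
#'
#' @param family One of `"logistic_regression"`, `"random_forest"`,
#'   `"feedforward_net"`, `"conv_resnet"`, `"recurrent_lstm"`.
#' @param hyperparameters Named list overriding the family defaults; unknown
#'   names are rejected.
#' @param feature_set `"ehr_only"`, `"ehr_drug"`, or `"ehr_drug_lab"`.
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fitting.
#' @return A `model_config` list.
#' @export
#' @examples
#' model_config("random_forest", list(n_trees = 20))
model_config <- function(family, hyperparameters = list(),
                         feature_set = "ehr_drug_lab", seed = 1L) {
  family <- match.arg(family, model_families)
  feature_set <- match.arg(feature_set, c("ehr_drug_lab", "ehr_only", "ehr_drug"))
  schema <- default_hyperparameters[[family]]
  unknown <- setdiff(names(hyperparameters), names(schema))
  if (length(unknown) > 0)
    abort(paste0("unknown hyperparameter(s) for ", family, ": ",
                 paste(unknown, collapse = ", ")),
          class = "oncosepsis_validation_error")
  hp <- utils::modifyList(schema, hyperparameters)
  if (family == "random_forest" && hp$n_trees < 1)
    abort("n_trees must be >= 1", class = "oncosepsis_validation_error")
  structure(list(family = family, hyperparameters = hp,
                 feature_set = feature_set, seed = as.integer(seed)),
            class = "model_config")
}

#' Reshape a flat feature table for a model family
#'
#' Most families consume the flat (rows, features) matrix. The residual CNN
#' expects square single-channel images: features are zero-padded (in
#' manifest column order) to 1764 and reshaped to (1, 42, 42) per row. The
#' LSTM consumes per-visit sequences zero-padded to the cohort maximum
#' length, shape (rows, time, features); a flat table is treated as a bundle
#' of length-1 sequences.
#'
#' @param feature_table Tibble or matrix of numeric features.
#' @param family Model family name.
#' @param sequences Optional list of (time x features) matrices, one per row,
#'   for `recurrent_lstm`.
#' @return List with `family`, `shape`, `n_pad` (conv only) and `data` (a
#'   matrix for flat families, an n x 1764 matrix viewed as (1, 42, 42)
#'   images for the CNN, an (n, time, features) array for the LSTM).
#' @export
#' @examples
#' reshape_features(matrix(rnorm(20), 5), "conv_resnet")$shape
reshape_features <- function(feature_table, family, sequences = NULL) {
  family <- match.arg(family, model_families)
  x <- as.matrix(feature_table)
  if (family == "conv_resnet") {
    if (ncol(x) > 1764)
      abort("conv_resnet supports at most 1764 features (42 x 42)",
            class = "oncosepsis_validation_error")
    n_pad <- 1764 - ncol(x)
    padded <- cbind(x, matrix(0, nrow(x), n_pad))
    return(list(family = family, shape = c(1, 42, 42), n_pad = n_pad,
                data = padded))
  }
  if (family == "recurrent_lstm") {
    if (is.null(sequences)) sequences <- purrr::map(seq_len(nrow(x)),
                                                    function(i) x[i, , drop = FALSE])
    t_max <- max(vapply(sequences, nrow, integer(1)))
    f <- ncol(sequences[[1]])
    arr <- array(0, c(length(sequences), t_max, f))
    for (i in seq_along(sequences)) {
      ti <- nrow(sequences[[i]])
      arr[i, seq_len(ti), ] <- sequences[[i]]
    }
    return(list(family = family, shape = c(length(sequences), t_max, f),
                data = arr))
  }
  list(family = family, shape = dim(x), data = x)
}

# ---- family fits ----------------------------------------------------------
# The two deep families are smoke-scale reservoir-style networks: an exact
# convolutional-residual / LSTM forward pass with seeded fixed weights
# extracts representations, and a logistic readout is the trained layer.
# This keeps them deterministic and desk-fast; widths are config-driven.

safe_logistic <- function(x, y, maxit = 100) {
  fit <- suppressWarnings(glm.fit(cbind(1, x), y,
                                  family = binomial(),
                                  control = list(maxit = maxit)))
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  coefs
}

logistic_scores <- function(coefs, x) as.numeric(stats::plogis(cbind(1, x) %*% coefs))

conv_residual_features <- function(x_img, filters) {
  # x_img: n x 1764 (42 x 42 row-major); 'same' 3x3 convolution via shifts
  n <- nrow(x_img); side <- 42L
  row_i <- rep(seq_len(side), each = side)
  col_i <- rep(seq_len(side), times = side)
  offsets <- expand.grid(di = -1:1, dj = -1:1)
  shifted <- purrr::map(seq_len(9), function(k) {
    ri <- row_i + offsets$di[k]; ci <- col_i + offsets$dj[k]
    ok <- ri >= 1 & ri <= side & ci >= 1 & ci <= side
    idx <- ifelse(ok, (ri - 1) * side + ci, NA)
    xs <- matrix(0, n, side * side)
    xs[, ok] <- x_img[, idx[ok], drop = FALSE]
    xs
  })
  feats <- purrr::map(seq_len(nrow(filters)), function(f) {
    conv <- Reduce(`+`, purrr::map(seq_len(9),
                                   function(k) filters[f, k] * shifted[[k]]))
    h <- pmax(conv, 0) + x_img # ReLU then residual add of the input
    cbind(rowMeans(h), apply(h, 1, max), apply(h, 1, sd))
  })
  cbind(do.call(cbind, feats), rowMeans(x_img))
}

lstm_features <- function(x_seq, hidden_units, weights) {
  # x_seq: (n, T, F) array; standard LSTM cell, returns final hidden state
  n <- dim(x_seq)[1]; t_max <- dim(x_seq)[2]
  h <- matrix(0, n, hidden_units); cst <- matrix(0, n, hidden_units)
  for (t in seq_len(t_max)) {
    xt <- matrix(x_seq[, t, ], nrow = n)
    z <- xt %*% weights$W + h %*% weights$U +
      matrix(weights$b, n, 4 * hidden_units, byrow = TRUE)
    i_g <- stats::plogis(z[, seq_len(hidden_units)])
    f_g <- stats::plogis(z[, hidden_units + seq_len(hidden_units)])
    o_g <- stats::plogis(z[, 2 * hidden_units + seq_len(hidden_units)])
    g <- tanh(z[, 3 * hidden_units + seq_len(hidden_units)])
    cst <- f_g * cst + i_g * g
    h <- o_g * tanh(cst)
  }
  h
}

fit_family <- function(x, y, config) {
  hp <- config$hyperparameters
  fit <- switch(config$family,
    logistic_regression = list(coefs = safe_logistic(x, y, hp$maxit)),
    random_forest = {
      mtry <- hp$mtry %||% max(1, floor(sqrt(ncol(x))))
      list(forest = randomForest::randomForest(
        x, factor(y, levels = c(0, 1)), ntree = hp$n_trees, mtry = mtry))
    },
    feedforward_net = list(net = nnet::nnet(
      x, y, size = hp$hidden_units, decay = hp$decay, maxit = hp$maxit,
      entropy = TRUE, trace = FALSE)),
    conv_resnet = {
      filters <- matrix(rnorm(hp$n_filters * 9, sd = 1 / 3), hp$n_filters, 9)
      img <- reshape_features(x, "conv_resnet")
      feats <- conv_residual_features(img$data, filters)
      list(filters = filters, coefs = safe_logistic(scale01(feats)$x, y),
           scaler = scale01(feats)$scaler)
    },
    recurrent_lstm = {
      hu <- hp$hidden_units
      weights <- list(W = matrix(rnorm(ncol(x) * 4 * hu, sd = 1 / sqrt(ncol(x))),
                                 ncol(x), 4 * hu),
                      U = matrix(rnorm(hu * 4 * hu, sd = 1 / sqrt(hu)), hu, 4 * hu),
                      b = rnorm(4 * hu, sd = 0.1))
      seq_x <- reshape_features(x, "recurrent_lstm")
      feats <- lstm_features(seq_x$data, hu, weights)
      list(weights = weights, hidden_units = hu,
           coefs = safe_logistic(feats, y))
    }
  )
  fit$family <- config$family
  fit
}

scale01 <- function(x, scaler = NULL) {
  if (is.null(scaler)) {
    scaler <- list(center = colMeans(x), sd = apply(x, 2, sd))
    scaler$sd[scaler$sd == 0 | is.na(scaler$sd)] <- 1
  }
  list(x = sweep(sweep(x, 2, scaler$center), 2, scaler$sd, "/"),
       scaler = scaler)
}

predict_scores <- function(fit, x) {
  switch(fit$family,
    logistic_regression = logistic_scores(fit$coefs, x),
    random_forest = as.numeric(predict(fit$forest, x, type = "prob")[, "1"]),
    feedforward_net = as.numeric(predict(fit$net, x)),
    conv_resnet = {
      img <- reshape_features(x, "conv_resnet")
      feats <- conv_residual_features(img$data, fit$filters)
      logistic_scores(fit$coefs, scale01(feats, fit$scaler)$x)
    },
    recurrent_lstm = {
      seq_x <- reshape_features(x, "recurrent_lstm")
      logistic_scores(fit$coefs,
                      lstm_features(seq_x$data, fit$hidden_units, fit$weights))
    }
  )
}

numeric_feature_matrix <- function(data) {
  drop_cols <- c("patient_id", "visit_id", "group_label", "cancer_type", "sex")
  df <- data[setdiff(names(data), drop_cols)]
  num <- vapply(df, is.numeric, logical(1))
  as.matrix(df[num])
}

normalize_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(as.integer(labels %in% c("sepsis", "1")))
  as.integer(labels)
}

#' Fit one classifier on a full feature table
#'
#' Scales features (train statistics stored for prediction) and fits the
#' configured family; mainly used to produce the tree ensemble consumed by
#' [rank_feature_contributions()].
#'
#' @param data Feature tibble (id columns are dropped automatically).
#' @param labels Vector of visit labels (`"sepsis"`/`"nonsepsis"`, 0/1, or a
#'   factor).
#' @param config A [model_config()].
#' @return A `sepsis_model`: list with the family fit, feature names and
#'   scaler.
#' @export
fit_sepsis_model <- function(data, labels, config) {
  x <- numeric_feature_matrix(data)
  y <- normalize_labels(labels)
  withr::with_seed(config$seed, {
    sc <- scale01(x)
    fit <- fit_family(sc$x, y, config)
    structure(list(fit = fit, config = config, scaler = sc$scaler,
                   feature_names = colnames(x), x_train = sc$x, y_train = y),
              class = "sepsis_model")
  })
}

#' @export
predict.sepsis_model <- function(object, newdata, ...) {
  x <- numeric_feature_matrix(newdata)[, object$feature_names, drop = FALSE]
  predict_scores(object$fit, scale01(x, object$scaler)$x)
}
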