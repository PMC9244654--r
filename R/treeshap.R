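# ---- Tree SHAP (path-dependent) -------------------------------------------
# Shapley values of a decision-tree ensemble, computed exactly with the
# polynomial-time path algorithm: a path of (feature, zero-fraction,
# one-fraction, weight) elements is extended down the tree and unwound at
# leaves, so each feature's Shapley contribution accumulates without
# enumerating coalitions. The value function is the tree's cover-weighted
# conditional expectation (node covers are recomputed by routing the
# training data through each tree).

# internal tree format: parallel vectors, root = 1, leaf when left == 0
new_tree <- function(left, right, feature, threshold, value, cover) {
  list(left = as.integer(left), right = as.integer(right),
       feature = as.integer(feature), threshold = as.numeric(threshold),
       value = as.numeric(value), cover = as.numeric(cover))
}

# route rows of x through the tree to obtain per-node sample counts
tree_covers <- function(tree, x) {
  cover <- numeric(length(tree$left))
  route <- function(j, idx) {
    cover[j] <<- length(idx)
    if (tree$left[j] == 0L || length(idx) == 0) return(invisible())
    goes_left <- x[idx, tree$feature[j]] <= tree$threshold[j]
    route(tree$left[j], idx[goes_left])
    route(tree$right[j], idx[!goes_left])
  }
  route(1L, seq_len(nrow(x)))
  cover
}

# extract tree k of a randomForest classification fit; leaf value is the
# positive-class vote (0/1)
rf_tree_structure <- function(forest, k, x_train) {
  m <- randomForest::getTree(forest, k, labelVar = FALSE)
  leaf <- m[, "status"] == -1
  tree <- new_tree(
    left = m[, "left daughter"], right = m[, "right daughter"],
    feature = ifelse(leaf, 0L, m[, "split var"]),
    threshold = ifelse(leaf, 0, m[, "split point"]),
    value = ifelse(leaf, m[, "prediction"] - 1, 0),
    cover = 0
  )
  tree$cover <- tree_covers(tree, x_train)
  tree
}

tree_base_value <- function(tree) {
  leaves <- tree$left == 0L
  sum(tree$value[leaves] * tree$cover[leaves]) / sum(tree$cover[leaves])
}

path_extend <- function(m, pz, po, pi) {
  l <- length(m$w)
  m$d <- c(m$d, pi); m$z <- c(m$z, pz); m$o <- c(m$o, po)
  m$w <- c(m$w, if (l == 0) 1 else 0)
  if (l >= 1) {
    for (i in l:1) {
      m$w[i + 1] <- m$w[i + 1] + po * m$w[i] * i / (l + 1)
      m$w[i] <- pz * m$w[i] * (l + 1 - i) / (l + 1)
    }
  }
  m
}

path_unwind <- function(m, i) {
  l <- length(m$w) - 1L
  n <- m$w[l + 1]
  oi <- m$o[i]; zi <- m$z[i]
  if (l >= 1) {
    for (j in l:1) {
      if (oi != 0) {
        t <- m$w[j]
        m$w[j] <- n * (l + 1) / (j * oi)
        n <- t - m$w[j] * zi * (l + 1 - j) / (l + 1)
      } else {
        m$w[j] <- m$w[j] * (l + 1) / (zi * (l + 1 - j))
      }
    }
  }
  if (i <= l) {
    for (j in i:l) {
      m$d[j] <- m$d[j + 1]; m$z[j] <- m$z[j + 1]; m$o[j] <- m$o[j + 1]
    }
  }
  m$d <- m$d[1:l]; m$z <- m$z[1:l]; m$o <- m$o[1:l]; m$w <- m$w[1:l]
  m
}

# Shapley values of one tree's prediction at x (length = n_features)
tree_shap <- function(tree, x) {
  phi <- numeric(length(x))
  recurse <- function(j, m, pz, po, pi) {
    m <- path_extend(m, pz, po, pi)
    if (tree$left[j] == 0L) {
      len <- length(m$w)
      if (len >= 2) {
        for (i in 2:len) {
          w <- sum(path_unwind(m, i)$w)
          phi[m$d[i]] <<- phi[m$d[i]] + w * (m$o[i] - m$z[i]) * tree$value[j]
        }
      }
      return(invisible())
    }
    d <- tree$feature[j]
    if (x[d] <= tree$threshold[j]) {
      hot <- tree$left[j]; cold <- tree$right[j]
    } else {
      hot <- tree$right[j]; cold <- tree$left[j]
    }
    iz <- 1; io <- 1
    k <- which(m$d == d)
    k <- k[k > 1]
    if (length(k) > 0) {
      k <- k[1]
      iz <- m$z[k]; io <- m$o[k]
      m <- path_unwind(m, k)
    }
    cj <- tree$cover[j]
    recurse(hot, m, iz * tree$cover[hot] / cj, io, d)
    recurse(cold, m, iz * tree$cover[cold] / cj, 0, d)
  }
  recurse(1L, list(d = integer(), z = numeric(), o = numeric(), w = numeric()),
          1, 1, 0L)
  phi
}

#' Rank feature contributions of a tree-ensemble model
#'
#' Computes exact path-dependent Tree Shapley values for every row, averages
#' their absolute values per feature, normalizes to contribution ratios
#' summing to 1, and extracts the top-k features. Restricted to tree
#' ensembles (the random-forest family); other families raise an
#' unsupported-model error.
#'
#' @param model A `sepsis_model` fitted with the `random_forest` family (see
#'   [fit_sepsis_model()]).
#' @param data Optional feature tibble to explain; defaults to the model's
#'   training rows.
#' @param top_k How many features to report in the ranking (default 50).
#' @return A `contribution_ranking`: list with `contributions` (tibble
#'   `feature`, `mean_abs_shap`, `ratio`, sorted descending), `top_k`
#'   (character vector), `phi` (rows x features Shapley matrix) and
#'   `base_value`.
#' @export
#' @examples
#' \donttest{
#' d <- tibble::tibble(a = rnorm(80), b = rnorm(80))
#' y <- as.integer(d$a > 0)
#' m <- fit_sepsis_model(d, y, model_config("random_forest"))
#' rank_feature_contributions(m, top_k = 2)$top_k
#' }
rank_feature_contributions <- function(model, data = NULL, top_k = 50) {
  if (!inherits(model, "sepsis_model") || model$fit$family != "random_forest")
    abort("feature contributions require a tree-ensemble (random_forest) model",
          class = "oncosepsis_unsupported_model")
  forest <- model$fit$forest
  x_train <- model$x_train
  x <- if (is.null(data)) x_train else
    scale01(numeric_feature_matrix(data)[, model$feature_names, drop = FALSE],
            model$scaler)$x
  ntree <- forest$ntree
  trees <- purrr::map(seq_len(ntree), function(k)
    rf_tree_structure(forest, k, x_train))
  phi <- matrix(0, nrow(x), ncol(x), dimnames = list(NULL, colnames(x)))
  for (tr in trees) {
    for (i in seq_len(nrow(x))) {
      phi[i, ] <- phi[i, ] + tree_shap(tr, x[i, ]) / ntree
    }
  }
  base_value <- mean(purrr::map_dbl(trees, tree_base_value))
  mean_abs <- colMeans(abs(phi))
  total <- sum(mean_abs)
  ratio <- if (total == 0) rep(0, length(mean_abs)) else mean_abs / total
  contributions <- tibble(feature = colnames(x),
                          mean_abs_shap = unname(mean_abs),
                          ratio = unname(ratio)) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap), .data$feature)
  structure(list(contributions = contributions,
                 top_k = head(contributions$feature, top_k),
                 phi = phi, base_value = base_value),
            class = "contribution_ranking")
}

#' @export
print.contribution_ranking <- function(x, ...) {
  cat("<contribution_ranking> ", nrow(x$contributions), " features, base value ",
      round(x$base_value, 4), "\n", sep = "")
  print(head(x$contributions, 10))
  invisible(x)
}

#' @rdname rank_feature_contributions
#' @param x A `contribution_ranking`.
#' @param ... Unused.
#' @export
tidy.contribution_ranking <- function(x, ...) x$contributions

#' @rdname rank_feature_contributions
#' @param object A `contribution_ranking`.
#' @param n_features Number of top features to plot.
#' @export
autoplot.contribution_ranking <- function(object, n_features = 20, ...) {
  df <- head(object$contributions, n_features)
  ggplot(df, aes(x = .data$ratio,
                 y = stats::reorder(.data$feature, .data$ratio))) +
    geom_col(fill = "steelblue") +
    labs(x = "contribution ratio", y = NULL) +
    theme_minimal()
}
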