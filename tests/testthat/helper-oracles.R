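# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package's code paths.

# brute-force pairwise support: O(drugs^2 * transactions) counting
brute_pair_support <- function(baskets, min_support) {
  n <- length(baskets)
  drugs <- sort(unique(unlist(baskets)))
  out <- list()
  if (length(drugs) >= 2) {
    for (i in seq_len(length(drugs) - 1)) {
      for (j in (i + 1):length(drugs)) {
        cnt <- sum(vapply(baskets, function(b)
          drugs[i] %in% b && drugs[j] %in% b, logical(1)))
        if (cnt / n >= min_support - 1e-12) {
          out[[length(out) + 1]] <- tibble::tibble(
            drug_i = drugs[i], drug_j = drugs[j],
            n_cooccur = cnt, support = cnt / n)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(drug_i = character(), drug_j = character(),
                          n_cooccur = integer(), support = numeric()))
  }
  res <- dplyr::bind_rows(out)
  res[order(-res$support, res$drug_i, res$drug_j), ]
}

# random transaction databases for the mining oracle suite
random_baskets <- function(n_drugs, n_tx) {
  drugs <- LETTERS[seq_len(n_drugs)]
  lapply(seq_len(n_tx), function(i) {
    k <- sample(seq_len(max(1, n_drugs %/% 2)), 1)
    sort(sample(drugs, k))
  })
}

baskets_to_rx <- function(baskets) {
  tibble::tibble(
    patient_id = rep(sprintf("P%03d", seq_along(baskets)),
                     lengths(baskets)),
    date = as.Date("2015-06-01") + rep(seq_along(baskets), lengths(baskets)),
    drug_id = unlist(baskets)
  )
}

# hand-evaluated Welch statistic and Welch-Satterthwaite df
welch_by_hand <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  list(t = t_stat, df = df, p = p)
}

# exhaustive (window x assessment) enumeration of the Sepsis-3 rule
label_by_enumeration <- function(sofa_series, windows) {
  if (nrow(windows) == 0) return("nonsepsis")
  for (w in seq_len(nrow(windows))) {
    before <- sofa_series[sofa_series$timestamp < windows$window_start[w], ]
    base <- if (nrow(before) == 0) 0 else
      before$total[which.max(as.numeric(before$timestamp))]
    for (a in seq_len(max(1, nrow(sofa_series)))) {
      if (nrow(sofa_series) == 0) break
      ts <- sofa_series$timestamp[a]
      if (ts >= windows$window_start[w] && ts <= windows$window_end[w] &&
          sofa_series$total[a] - base >= 2) {
        return("sepsis")
      }
    }
  }
  "nonsepsis"
}

# cover-weighted conditional expectation of a tree given a feature coalition
tree_expv <- function(tree, x, S) {
  rec <- function(j) {
    if (tree$left[j] == 0L) return(tree$value[j])
    d <- tree$feature[j]
    if (d %in% S) {
      if (x[d] <= tree$threshold[j]) rec(tree$left[j]) else rec(tree$right[j])
    } else {
      (tree$cover[tree$left[j]] * rec(tree$left[j]) +
         tree$cover[tree$right[j]] * rec(tree$right[j])) / tree$cover[j]
    }
  }
  rec(1L)
}

# exhaustive-coalition Shapley values of one tree (2^M subsets)
shapley_by_enumeration <- function(tree, x, n_features) {
  phi <- numeric(n_features)
  for (i in seq_len(n_features)) {
    others <- setdiff(seq_len(n_features), i)
    for (sz in 0:length(others)) {
      combos <- if (sz == 0) list(integer()) else
        asplit(utils::combn(others, sz), 2)
      for (S in combos) {
        w <- factorial(sz) * factorial(n_features - sz - 1) /
          factorial(n_features)
        phi[i] <- phi[i] +
          w * (tree_expv(tree, x, c(S, i)) - tree_expv(tree, x, S))
      }
    }
  }
  phi
}

# a hand-built depth-2 tree over 3 features (internal tree format)
toy_tree <- function() {
  oncosepsis:::new_tree(
    left = c(2, 4, 6, 0, 0, 0, 0), right = c(3, 5, 7, 0, 0, 0, 0),
    feature = c(1, 2, 3, 0, 0, 0, 0),
    threshold = c(0, 0.5, -1, 0, 0, 0, 0),
    value = c(0, 0, 0, 1, 0, 0.3, 0.9),
    cover = c(10, 6, 4, 2, 4, 3, 1))
}

tiny_config <- function(n_control = 40, n_sepsis = 20, seed = 1, ...) {
  cohort_config(n_control = n_control, n_sepsis = n_sepsis, seed = seed, ...)
}
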