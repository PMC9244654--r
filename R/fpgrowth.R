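#' Build same-day prescription baskets
#'
#' One transaction per (patient, day) with at least one prescription; the
#' drug set of a transaction is deduplicated. The total number of
#' transactions is the denominator of the support statistic.
#'
#' @param prescriptions Tibble with `patient_id`, `date`, `drug_id`.
#' @return A `transaction_set`: list with `transactions` (tibble
#'   `patient_id`, `date`, `drugs` list-column) and `n_transactions`.
#' @export
#' @examples
#' rx <- tibble::tibble(patient_id = "P1",
#'                      date = as.Date("2015-01-01") + c(0, 0, 1),
#'                      drug_id = c("A", "B", "C"))
#' build_transactions(rx)$n_transactions
build_transactions <- function(prescriptions) {
  tx <- prescriptions |>
    dplyr::distinct(.data$patient_id, .data$date, .data$drug_id) |>
    dplyr::group_by(.data$patient_id, .data$date) |>
    dplyr::summarise(drugs = list(sort(.data$drug_id)), .groups = "drop")
  structure(list(transactions = tx, n_transactions = nrow(tx)),
            class = "transaction_set")
}

#' @export
print.transaction_set <- function(x, ...) {
  cat("<transaction_set> ", x$n_transactions, " same-day baskets, ",
      length(unique(unlist(x$transactions$drugs))), " drugs\n", sep = "")
  invisible(x)
}

# ---- FP-growth ------------------------------------------------------------
# Frequent-itemset mining by frequent-pattern tree projection: transactions
# are inserted into a prefix tree in descending item-frequency order, and
# itemsets are extracted by recursively mining conditional pattern bases —
# no candidate generation.

fp_new_tree <- function() {
  env <- new.env(parent = emptyenv())
  env$item <- NA_character_
  env$count <- 0
  env$parent <- 0L
  env$children <- list(structure(integer(), names = character()))
  env$header <- list()
  env
}

fp_insert <- function(tree, items, count) {
  cur <- 1L
  for (it in items) {
    kid <- tree$children[[cur]][it]
    if (is.na(kid)) {
      tree$item <- c(tree$item, it)
      tree$count <- c(tree$count, 0)
      tree$parent <- c(tree$parent, cur)
      tree$children <- c(tree$children,
                         list(structure(integer(), names = character())))
      kid <- length(tree$item)
      tree$children[[cur]][it] <- kid
      tree$header[[it]] <- c(tree$header[[it]], kid)
    }
    tree$count[kid] <- tree$count[kid] + count
    cur <- kid
  }
}

fp_build <- function(itemsets, counts, min_count) {
  items <- unlist(itemsets, use.names = FALSE)
  if (length(items) == 0) return(NULL)
  w <- rep(counts, lengths(itemsets))
  sup <- tapply(w, items, sum)
  sup <- sup[sup >= min_count]
  if (length(sup) == 0) return(NULL)
  # descending frequency, lexicographic tie-break, for a deterministic tree
  order_items <- names(sup)[order(-sup, names(sup))]
  tree <- fp_new_tree()
  for (i in seq_along(itemsets)) {
    keep <- itemsets[[i]][itemsets[[i]] %in% order_items]
    if (length(keep) == 0) next
    keep <- keep[order(match(keep, order_items))]
    fp_insert(tree, keep, counts[i])
  }
  tree$order_items <- order_items
  tree
}

fp_mine <- function(tree, min_count, suffix, acc) {
  if (is.null(tree)) return(acc)
  # least-frequent first, so conditional bases only contain more frequent items
  for (it in rev(tree$order_items)) {
    nodes <- tree$header[[it]]
    sup <- sum(tree$count[nodes])
    itemset <- c(it, suffix)
    acc[[length(acc) + 1L]] <- list(items = sort(itemset), count = sup)
    # conditional pattern base: prefix path of every node carrying `it`
    paths <- list(); path_counts <- numeric()
    for (nd in nodes) {
      path <- character()
      cur <- tree$parent[nd]
      while (cur != 0L && !is.na(tree$item[cur])) {
        path <- c(tree$item[cur], path)
        cur <- tree$parent[cur]
      }
      if (length(path) > 0) {
        paths[[length(paths) + 1L]] <- path
        path_counts <- c(path_counts, tree$count[nd])
      }
    }
    cond <- fp_build(paths, path_counts, min_count)
    acc <- fp_mine(cond, min_count, c(it, suffix), acc)
  }
  acc
}

#' Mine frequent itemsets with FP-growth
#'
#' @param transactions A `transaction_set` from [build_transactions()].
#' @param min_support Minimum support in (0, 1\]; default 0.05.
#' @return Tibble with `items` (sorted character list-column), `size`,
#'   `n_cooccur` and `support = n_cooccur / n_transactions`, ordered by
#'   support descending then lexicographically.
#' @export
mine_frequent_itemsets <- function(transactions, min_support = 0.05) {
  stopifnot(inherits(transactions, "transaction_set"))
  if (transactions$n_transactions == 0)
    abort("empty transaction set", class = "oncosepsis_validation_error")
  stopifnot(min_support > 0, min_support <= 1)
  n <- transactions$n_transactions
  min_count <- min_support * n - 1e-9
  tree <- fp_build(transactions$transactions$drugs,
                   rep(1, n), min_count)
  found <- fp_mine(tree, min_count, character(), list())
  if (length(found) == 0) {
    return(tibble(items = list(), size = integer(),
                  n_cooccur = integer(), support = numeric()))
  }
  out <- tibble(
    items = purrr::map(found, "items"),
    size = lengths(purrr::map(found, "items")),
    n_cooccur = as.integer(purrr::map_dbl(found, "count"))
  ) |>
    dplyr::mutate(support = .data$n_cooccur / n)
  key <- purrr::map_chr(out$items, paste, collapse = "\r")
  out[order(-out$support, key), ]
}

#' Mine frequent drug pairs
#'
#' Runs FP-growth and returns exactly the unordered drug pairs whose same-day
#' co-prescription support meets the threshold, with exact co-occurrence
#' counts. Pairs are stored with `drug_i < drug_j` lexicographically and
#' ordered by support descending, then lexicographically.
#'
#' @inheritParams mine_frequent_itemsets
#' @return Tibble with `drug_i`, `drug_j`, `n_cooccur`, `support`.
#' @export
#' @examples
#' rx <- tibble::tibble(
#'   patient_id = "P1", date = as.Date("2015-01-01") + rep(1:3, each = 2),
#'   drug_id = c("A", "B", "A", "B", "A", "C"))
#' mine_frequent_pairs(build_transactions(rx), min_support = 0.6)
mine_frequent_pairs <- function(transactions, min_support = 0.05) {
  sets <- mine_frequent_itemsets(transactions, min_support)
  pairs <- sets[sets$size == 2, ]
  tibble(
    drug_i = purrr::map_chr(pairs$items, 1),
    drug_j = purrr::map_chr(pairs$items, 2),
    n_cooccur = pairs$n_cooccur,
    support = pairs$support
  )
}
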