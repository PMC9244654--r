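#' Per-patient drug prescription-day frequencies
#'
#' The frequency of a drug for a patient is the number of *distinct days* on
#' which it was prescribed inside the observation window; drugs outside the
#' selected set are excluded.
#'
#' @param prescriptions Window-filtered tibble with `patient_id`, `date`,
#'   `drug_id`.
#' @param selected_drugs Character vector of drugs retained by the
#'   association analysis.
#' @return Tibble with `patient_id`, `drug_id`, `frequency` (absent rows mean
#'   frequency 0).
#' @export
compute_drug_frequencies <- function(prescriptions, selected_drugs) {
  prescriptions |>
    dplyr::filter(.data$drug_id %in% selected_drugs) |>
    dplyr::distinct(.data$patient_id, .data$drug_id, .data$date) |>
    dplyr::count(.data$patient_id, .data$drug_id, name = "frequency")
}

#' Drug-pair relationship formulas
#'
#' The default triple maps a pair of prescription frequencies (x, y) to the
#' interaction `I = x * y` (level of joint use), the harmonized average
#' `H = 2xy / (x + y)` (overall intensity, sensitive to the weaker member;
#' 0 when both are absent), and the arctangent `T = atan2(y, x)` in radians
#' (the geometric angle of the pair as a single scalar; 0 when both are
#' absent). Alternative functional forms can be swapped in without touching
#' the pipeline by passing a different strategy.
#'
#' @param interaction,harmonized,arctangent Functions of `(x, y)`.
#' @return A named list of the three functions, class
#'   `relationship_strategy`.
#' @export
relationship_strategy <- function(
    interaction = function(x, y) x * y,
    harmonized = function(x, y) ifelse(x + y == 0, 0, 2 * x * y / (x + y)),
    arctangent = function(x, y) atan2(y, x)) {
  structure(list(I = interaction, H = harmonized, T = arctangent),
            class = "relationship_strategy")
}

#' Vectorize one drug pair
#'
#' @param x,y Non-negative prescription frequencies of the two drugs.
#' @param strategy A [relationship_strategy()].
#' @return Named numeric vector `c(I, H, T)`.
#' @export
#' @examples
#' vectorize_pair(2, 2) # c(I = 4, H = 2, T = pi / 4)
vectorize_pair <- function(x, y, strategy = relationship_strategy()) {
  if (any(x < 0) || any(y < 0))
    abort("frequencies must be non-negative",
          class = "oncosepsis_validation_error")
  c(I = strategy$I(x, y), H = strategy$H(x, y), T = strategy$T(x, y))
}

#' Build the drug-relationship feature block
#'
#' One column triple `<drugA>__<drugB>__{I,H,T}` per unordered pair of the
#' `k` selected drugs (pairs oriented and ordered lexicographically, so the
#' block layout is deterministic), giving `3 * k * (k - 1) / 2` columns per
#' patient.
#'
#' @param profiles Frequency tibble from [compute_drug_frequencies()].
#' @param selected_drugs The `k >= 2` selected drugs.
#' @param strategy A [relationship_strategy()].
#' @return Wide tibble: `patient_id` plus `3 * choose(k, 2)` numeric columns.
#' @export
build_relationship_features <- function(profiles, selected_drugs,
                                        strategy = relationship_strategy()) {
  selected_drugs <- sort(unique(selected_drugs))
  k <- length(selected_drugs)
  if (k < 2)
    abort("need at least 2 selected drugs",
          class = "oncosepsis_validation_error")
  patients <- sort(unique(profiles$patient_id))
  freq <- matrix(0, nrow = length(patients), ncol = k,
                 dimnames = list(patients, selected_drugs))
  keep <- profiles$drug_id %in% selected_drugs
  freq[cbind(match(profiles$patient_id[keep], patients),
             match(profiles$drug_id[keep], selected_drugs))] <-
    profiles$frequency[keep]
  pair_idx <- utils::combn(k, 2)
  cols <- purrr::map(seq_len(ncol(pair_idx)), function(p) {
    i <- pair_idx[1, p]; j <- pair_idx[2, p]
    x <- unname(freq[, i]); y <- unname(freq[, j])
    out <- list(strategy$I(x, y), strategy$H(x, y), strategy$T(x, y))
    names(out) <- paste(selected_drugs[i], selected_drugs[j],
                        c("I", "H", "T"), sep = "__")
    out
  })
  dplyr::bind_cols(tibble(patient_id = patients),
                   as_tibble(purrr::flatten(cols)))
}
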