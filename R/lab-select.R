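default_tier_map <- c("*" = 0.05, "**" = 0.005, "***" = 0.001, "****" = 1e-4)

#' Compare one lab's distribution between groups
#'
#' Two-sided unequal-variance (Welch) t-test of sepsis versus control values,
#' with group summary moments and a significance tier.
#'
#' @param values_sepsis,values_control Numeric vectors with at least 2 finite
#'   values each; `NA`s are dropped.
#' @param lab_type Optional label carried into the result.
#' @param tier_map Named vector of strictly decreasing p-value thresholds
#'   (most stringent last); see [assign_significance_tier()].
#' @return One-row tibble: `lab_type`, per-group mean/sd/n, `t_statistic`,
#'   `p_value`, `tier`.
#' @export
#' @examples
#' compare_lab_distributions(rnorm(50, 2.7), rnorm(80, 3.3), lab_type = "albumin")
compare_lab_distributions <- function(values_sepsis, values_control,
                                      lab_type = NA_character_,
                                      tier_map = default_tier_map) {
  vs <- values_sepsis[is.finite(values_sepsis)]
  vc <- values_control[is.finite(values_control)]
  if (length(vs) < 2 || length(vc) < 2)
    abort("each group needs at least 2 finite values",
          class = "oncosepsis_validation_error")
  if (sd(vs) == 0 && sd(vc) == 0 && mean(vs) == mean(vc)) {
    tt <- list(statistic = c(t = 0), p.value = 1) # degenerate: no variance
  } else {
    tt <- t.test(vs, vc, var.equal = FALSE)
  }
  tibble(
    lab_type = lab_type,
    mean_sepsis = mean(vs), sd_sepsis = sd(vs), n_sepsis = length(vs),
    mean_control = mean(vc), sd_control = sd(vc), n_control = length(vc),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    tier = assign_significance_tier(tt$p.value, tier_map)
  )
}

#' Assign a significance tier to a p-value
#'
#' Returns the most stringent satisfied tier symbol, or `"NS"` when no
#' threshold is met. The default map is `*` p<.05, `**` p<.005, `***` p<.001,
#' `****` p<.0001.
#'
#' @param p_value Numeric p-value(s).
#' @param tier_map Named numeric vector of thresholds, strictly decreasing.
#' @return Character vector of tier symbols.
#' @export
#' @examples
#' assign_significance_tier(c(0.5, 0.04, 1e-6))
assign_significance_tier <- function(p_value, tier_map = default_tier_map) {
  stopifnot(all(diff(tier_map) < 0))
  vapply(p_value, function(p) {
    hit <- which(p < tier_map)
    if (length(hit) == 0) "NS" else names(tier_map)[max(hit)]
  }, character(1))
}

#' Compare every lab type between groups
#'
#' @param labs Tibble with `patient_id` (or `visit_id`), `lab_type`, `value`.
#' @param groups Tibble mapping `patient_id` to `group`
#'   (`"sepsis"`/`"control"` or the labels `"sepsis"`/`"nonsepsis"`).
#' @param tier_map See [assign_significance_tier()].
#' @return A `lab_comparison` tibble, one row per lab type, ordered by
#'   p-value.
#' @export
compare_labs <- function(labs, groups, tier_map = default_tier_map) {
  groups <- groups |>
    dplyr::mutate(group = ifelse(.data$group %in% c("control", "nonsepsis"),
                                 "control", "sepsis"))
  joined <- dplyr::inner_join(labs, groups, by = "patient_id")
  out <- joined |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$lab_type) |>
    dplyr::group_map(function(df, key) {
      compare_lab_distributions(df$value[df$group == "sepsis"],
                                df$value[df$group == "control"],
                                lab_type = key$lab_type, tier_map = tier_map)
    }) |>
    list_rbind() |>
    dplyr::arrange(.data$p_value, .data$lab_type)
  class(out) <- c("lab_comparison", class(out))
  out
}

#' Select significantly different lab types
#'
#' @param comparisons A `lab_comparison` table (or any tibble with
#'   `lab_type`, `p_value`).
#' @param alpha Per-test significance level; default 0.001.
#' @return Character vector of selected lab types, ordered by ascending
#'   p-value then name (deterministic).
#' @export
select_significant_labs <- function(comparisons, alpha = 0.001) {
  stopifnot(alpha > 0, alpha <= 1)
  sel <- comparisons[comparisons$p_value < alpha, ]
  sel$lab_type[order(sel$p_value, sel$lab_type)]
}

#' Plot group-wise lab comparisons
#'
#' Group means with +/- 1 SD bars per lab type, annotated with significance
#' tiers.
#'
#' @param object A `lab_comparison` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lab_comparison <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(cols = c("mean_sepsis", "mean_control"),
                        names_to = "group", values_to = "mean",
                        names_prefix = "mean_") |>
    dplyr::mutate(sd = ifelse(.data$group == "sepsis",
                              object$sd_sepsis[match(.data$lab_type, object$lab_type)],
                              object$sd_control[match(.data$lab_type, object$lab_type)]))
  ggplot(long, aes(x = .data$lab_type, y = .data$mean, colour = .data$group)) +
    geom_pointrange(aes(ymin = .data$mean - .data$sd,
                        ymax = .data$mean + .data$sd),
                    position = position_dodge(width = 0.5)) +
    geom_text(data = object, inherit.aes = FALSE,
              aes(x = .data$lab_type, label = .data$tier),
              y = Inf, vjust = 1.5, size = 3) +
    labs(x = NULL, y = "group mean ± SD", colour = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
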