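# ggplot2 display helpers for the main result types.

#' Plot odds ratios from a family of function regressions
#'
#' Point-and-interval display of the per-unit odds ratios (log scale) with
#' their 95% confidence intervals, solid for units significant after
#' permutation adjustment.
#'
#' @param object A `vdm_fun_regression` tibble from
#'   [gene_function_regression()] or [ld_function_regression()].
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vdm_fun_regression <- function(object, alpha = 0.05, ...) {
  df <- mutate(as_tibble(object), significant = .data$p_perm <= alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or_per_unit,
                                   y = stats::reorder(.data$unit, .data$or_per_unit))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi,
                                          shape = .data$significant)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "odds ratio per unit association strength", y = NULL,
                  shape = sprintf("adjusted p <= %.2f", alpha),
                  title = unique(df$scope)) +
    ggplot2::theme_minimal()
}

#' Plot gene-set enrichment effects
#'
#' Enrichment effect `E` with a 1.96 SE interval per gene set, ordered by
#' effect.
#'
#' @param object A `vdm_enrichment` tibble from [usgsa()],
#'   [usgsa_perm_adjust()] or [candidate_enrichment()].
#' @param top Show only the `top` sets by effect (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vdm_enrichment <- function(object, top = 20, ...) {
  df <- as_tibble(object) |>
    arrange(dplyr::desc(.data$effect)) |>
    head(top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect,
                                   y = stats::reorder(.data$set_name, .data$effect))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$effect - 1.96 * .data$se,
                                          xmax = .data$effect + 1.96 * .data$se)) +
    ggplot2::labs(x = "enrichment effect E (with 1.96 SE)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of per-cohort enrichment with the random-effects summary
#'
#' Per-cohort enrichment effects and 95% intervals for one gene set, with
#' the pooled random-effects estimate appended.
#'
#' @param enrichments Long tibble with columns `cohort_id`, `effect`, `se`
#'   for one set.
#' @param meta Optional one-row [re_meta()] result for the same set; pooled
#'   row drawn when supplied.
#' @return A ggplot object.
#' @export
plot_enrichment_forest <- function(enrichments, meta = NULL) {
  df <- tibble(
    label = enrichments$cohort_id,
    effect = enrichments$effect,
    se = enrichments$se,
    pooled = FALSE
  )
  if (!is.null(meta)) {
    df <- bind_rows(df, tibble(label = "RE summary", effect = meta$re_effect,
                               se = meta$re_se, pooled = TRUE))
  }
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$label,
                                   colour = .data$pooled)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$effect - 1.96 * .data$se,
                                          xmax = .data$effect + 1.96 * .data$se),
                             show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "enrichment effect E", y = NULL) +
    ggplot2::theme_minimal()
}
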