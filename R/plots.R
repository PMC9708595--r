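#' Forest plot of gene-set enrichment results
#'
#' Betas with 95% confidence bars per set, faceted by variant class,
#' FDR-significant sets highlighted.
#'
#' @param results Enrichment tibble (primary rows are plotted).
#' @param top_n Show at most this many sets per class, by p-value.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, top_n = 30) {
  assert_cols(results, c("set", "variant_class", "beta", "se", "p"),
              "results")
  df <- results %>%
    filter(.data$conditioned_on == "",
           .data$status %in% c("ok", "firth")) %>%
    group_by(.data$variant_class) %>%
    arrange(.data$p, .by_group = TRUE) %>%
    slice(seq_len(min(n(), top_n))) %>%
    ungroup() %>%
    mutate(sig = if ("fdr_significant" %in% names(results)) {
      dplyr::coalesce(.data$fdr_significant, FALSE)
    } else FALSE)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$beta, y = stats::reorder(.data$set, .data$beta),
    colour = .data$sig
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$beta - 1.96 * .data$se,
      xmax = .data$beta + 1.96 * .data$se
    )) +
    ggplot2::facet_wrap(~variant_class, scales = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
      name = "FDR significant"
    ) +
    ggplot2::labs(x = "enrichment beta (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a convergence result
#'
#' Paired enrichment betas, point size proportional to the inverse
#' product of standard errors, sets significant in both arms labelled.
#'
#' @param object A `convergence_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot convergence_result
#' @export
autoplot.convergence_result <- function(object, ...) {
  df <- object$pairs
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_a,
                                        y = .data$beta_b)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2,
                        colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2,
                        colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight),
                        alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.6) +
    ggplot2::labs(
      x = "enrichment beta (arm A)",
      y = "enrichment beta (arm B)",
      size = "1 / (SE_a x SE_b)",
      subtitle = sprintf("%s r = %.3f; weighted r = %.3f",
                         object$method, object$correlation,
                         object$weighted_correlation)
    ) +
    ggplot2::theme_minimal()
  sig <- df %>% filter(dplyr::coalesce(.data$sig_both, FALSE))
  if (nrow(sig) > 0) {
    p <- p + ggplot2::geom_text(
      data = sig, ggplot2::aes(label = .data$set),
      vjust = -0.8, size = 3
    )
  }
  p
}

#' @rdname autoplot.convergence_result
#' @param x A `convergence_result`.
#' @param y Unused.
#' @export
plot.convergence_result <- function(x, y, ...) {
  print(autoplot.convergence_result(x, ...))
  invisible(x)
}
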