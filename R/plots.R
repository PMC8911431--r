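#' Scatter plot of paired log2 fold changes
#'
#' Seed-contrast versus partner-contrast fold change, one point per
#' homolog pair, with the least-squares line.
#'
#' @param pairs Tibble with `seed_log2`, `partner_log2` (and optionally
#'   `family` for coloring).
#' @return A ggplot object.
#' @export
plot_pairs <- function(pairs) {
  aes_args <- ggplot2::aes(x = .data$seed_log2, y = .data$partner_log2)
  p <- ggplot2::ggplot(pairs, aes_args)
  if ("family" %in% names(pairs) && !all(is.na(pairs$family))) {
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$family),
                                 alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, color = "grey30") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "seed contrast log2 fold change",
                  y = "partner contrast log2 fold change") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-seed-gene sign-concordance counts
#'
#' Opposite-sign versus matching-sign partner counts for each seed gene,
#' with Bonferroni-significant genes marked.
#'
#' @param concordance Output of [sign_concordance_table()].
#' @param alpha Significance threshold for the marker.
#' @return A ggplot object.
#' @export
plot_concordance <- function(concordance, alpha = 0.05) {
  dat <- concordance |>
    filter(.data$flag != "ND") |>
    tidyr::pivot_longer(c("n_pc1", "n_pc2"), names_to = "direction",
                        values_to = "count") |>
    mutate(direction = ifelse(.data$direction == "n_pc1",
                              "opposite sign", "matching sign"),
           significant = !is.na(.data$p_adj) & .data$p_adj < alpha)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$gene, y = .data$count,
                                    fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(
      data = dat |> filter(.data$significant, .data$direction ==
                             "opposite sign"),
      ggplot2::aes(y = .data$count + 1), shape = 8, show.legend = FALSE
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "homologous DEG records",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' qPCR group summary plot
#'
#' Group means with per-animal points, one panel per gene.
#'
#' @param measurements Tibble of qPCR data (see [summarize_group()]).
#' @return A ggplot object.
#' @export
plot_qpcr <- function(measurements) {
  summaries <- summarize_qpcr(measurements)
  value_col <- if ("value" %in% names(measurements)) "value" else "m0"
  per_rat <- measurements |>
    group_by(.data$gene, .data$group, .data$rat_id) |>
    summarise(m0 = mean(.data[[value_col]], na.rm = TRUE),
              .groups = "drop") |>
    filter(is.finite(.data$m0))
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$group, y = .data$group_mean)) +
    ggplot2::geom_col(fill = "grey80", color = "grey20", width = 0.6) +
    ggplot2::geom_jitter(data = per_rat,
                         ggplot2::aes(y = .data$m0), width = 0.1,
                         alpha = 0.7, size = 1.5) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "relative expression") +
    ggplot2::theme_minimal()
}
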