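# ggplot2 displays for the main result types

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed vs expected correlating percentages per delta-beta bin
#'
#' Histogram-style comparison, per delta-beta bin, of the observed and
#' expected percentage of genes whose expression is at least 2-fold lower
#' in the hypermethylated target line, with significance stars above
#' significant bins.
#'
#' @param object A `contingency_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contingency_tbl
#' @export
autoplot.contingency_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    filter(.data$total > 0) |>
    mutate(
      pct_obs = 100 * .data$obs_correlating / .data$total,
      pct_exp = 100 * .data$exp_correlating / .data$total,
      bin = sprintf("%.2f-%.2f", .data$bin_lo, .data$bin_hi)
    )
  long <- df |>
    tidyr::pivot_longer(c("pct_obs", "pct_exp"), names_to = "what",
                        values_to = "pct") |>
    mutate(what = ifelse(.data$what == "pct_obs", "Observed", "Expected"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$pct,
                                     fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = df, inherit.aes = FALSE,
      ggplot2::aes(x = .data$bin, label = .data$stars,
                   y = pmax(.data$pct_obs, .data$pct_exp) + 2)
    ) +
    ggplot2::scale_fill_manual(values = c(Observed = "#2166ac",
                                          Expected = "#b2182b")) +
    ggplot2::labs(x = "Delta-beta bin",
                  y = "% genes >= 2-fold lower in target",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Plot methylation-state fractions by island relation
#'
#' Stacked bars of the fraction of probes methylated, intermediate and
#' unmethylated within each island-relation class, per sample.
#'
#' @param summary Tibble from [region_methylation_summary()].
#' @return A ggplot object.
#' @export
plot_region_methylation <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(dplyr::starts_with("f_"), names_to = "state",
                        values_to = "fraction") |>
    mutate(state = factor(
      sub("^f_", "", .data$state),
      levels = c("methylated", "intermediate", "unmethylated")),
      island_relation = factor(.data$island_relation,
                               levels = ISLAND_RELATIONS))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$island_relation,
                                     y = .data$fraction,
                                     fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sample) +
    ggplot2::scale_fill_manual(values = c(methylated = "#b2182b",
                                          intermediate = "grey70",
                                          unmethylated = "#2166ac")) +
    ggplot2::labs(x = "Relation to CpG island", y = "Fraction of probes",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot Pfaffl reactivation ratios
#'
#' Bar chart of relative expression ratios after demethylating treatment,
#' on a log2 scale; the dashed line at ratio 1 marks no change.
#'
#' @param ratios Tibble from [pfaffl_ratios()] (`gene`, `ratio`).
#' @return A ggplot object.
#' @export
plot_pfaffl <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = stats::reorder(.data$gene,
                                                          -.data$ratio),
                                       y = .data$ratio)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL,
                  y = "Relative expression (treated / control)") +
    ggplot2::theme_minimal()
}
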