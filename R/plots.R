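#' Stacked bar plot of expansion by group
#'
#' @param summary An [expansion_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_expansion <- function(summary) {
  group_col <- names(summary)[1]
  long <- summary %>%
    select(all_of(group_col), "pct_expanded", "pct_singleton") %>%
    tidyr::pivot_longer(-all_of(group_col),
                        names_to = "state", values_to = "pct") %>%
    mutate(state = ifelse(.data$state == "pct_expanded", "expanded", "singleton"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data[[group_col]], y = .data$pct, fill = .data$state
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "% of cells", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Chain-usage donut plot
#'
#' @param usage A [chain_usage_table()] tibble.
#' @return A ggplot object.
#' @export
plot_chain_usage <- function(usage) {
  ggplot2::ggplot(usage, ggplot2::aes(
    x = 2, y = .data$overall_pct, fill = .data$vd_gene
  )) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::xlim(0.5, 2.5) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "Vdelta gene")
}

#' Volcano plot of a differential-expression result
#'
#' Highlights genes with adjusted p below `p_cutoff` and absolute (display)
#' log fold change above `lfc_cutoff`.
#'
#' @param de A [wilcoxon_de()] result.
#' @param p_cutoff Adjusted p threshold (default 0.05).
#' @param lfc_cutoff Absolute log fold change threshold (default 0.4).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, p_cutoff = 0.05, lfc_cutoff = 0.4) {
  df <- de %>%
    mutate(
      sig = .data$p_adj < p_cutoff & abs(.data$logfc_display) > lfc_cutoff,
      neglog10p = -log10(pmax(.data$p_adj, 1e-300))
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$logfc_display, y = .data$neglog10p, colour = .data$sig
  )) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "red3"),
                                 guide = "none") +
    ggplot2::geom_vline(xintercept = c(-lfc_cutoff, lfc_cutoff), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(p_cutoff), linetype = 2) +
    ggplot2::labs(x = "log fold change (clipped)", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step curves
#'
#' @param object A [kaplan_meier()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gdtcr_km
#' @export
autoplot.gdtcr_km <- function(object, ...) {
  df <- tidy(object)
  if (!"group" %in% names(df)) df$group <- "all"
  start <- df %>% distinct(.data$group) %>%
    mutate(time = 0, estimate = 1)
  df <- bind_rows(start, df) %>% arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time, y = .data$estimate, colour = .data$group
  )) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival", colour = NULL) +
    ggplot2::theme_minimal()
}
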