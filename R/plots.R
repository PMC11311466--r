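# ggplot2 displays for the main result types. All return a ggplot object.

#' Plot the cohort histamine-release distribution
#'
#' Histogram of percent release with the responder cutoffs (mean +/- 1 SD)
#' as dashed lines.
#'
#' @param data Donor tibble with a `release_pct` column.
#' @param stats Optional `release_stats`; fitted from `data` when `NULL`.
#' @param binwidth Histogram bin width in percent (default 5).
#' @return A ggplot.
#' @export
plot_release_distribution <- function(data, stats = NULL, binwidth = 5) {
  check_columns(data, "release_pct", "data")
  if (is.null(stats)) stats <- fit_release_stats(data)
  ggplot(data, aes(x = .data$release_pct)) +
    geom_histogram(binwidth = binwidth, boundary = 0, fill = "grey70",
                   colour = "grey30") +
    geom_vline(xintercept = c(stats$lower_cutoff_pct,
                              stats$upper_cutoff_pct),
               linetype = "dashed") +
    labs(x = "Histamine release (%)", y = "Donors",
         title = sprintf("Release %.1f%% ± %.1f%% (n = %d)",
                         stats$mean_pct, stats$sd_pct, stats$n)) +
    theme_minimal()
}

#' Plot per-gene expression by responder group
#'
#' Boxplots of Log2 expression per gene, split by responder group.
#'
#' @param expr Long expression tibble (`donor_id`, `gene`, `log2_level`).
#' @param labels Tibble (`donor_id`, `label`).
#' @return A ggplot.
#' @export
plot_expression_by_group <- function(expr, labels) {
  check_columns(expr, c("donor_id", "gene", "log2_level"), "expr")
  check_columns(labels, c("donor_id", "label"), "labels")
  df <- left_join(as_tibble(expr),
                  distinct(as_tibble(labels), .data$donor_id, .data$label),
                  by = "donor_id") |>
    mutate(label = as_responder_factor(.data$label))
  ggplot(df, aes(x = .data$label, y = .data$log2_level,
                 fill = .data$label)) +
    geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    facet_wrap(~gene, scales = "free_y") +
    labs(x = "Responder group", y = "Log2 expression level") +
    theme_minimal()
}

#' Plot perturbation rates per gene and group
#'
#' Bar chart of the percent perturbed (Up + Down) by gene and responder
#' group, the graphical counterpart of the group summary table.
#'
#' @param object A `peep_group_summary` from [summarize_groups()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.peep_group_summary <- function(object, ...) {
  df <- filter(as_tibble(object),
               .data$group %in% c("High", "Ave", "Low"))
  ggplot(df, aes(x = .data$gene, y = .data$pct_perturbed,
                 fill = .data$group)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "% perturbed", fill = "Group") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot barcode category frequencies per responder group
#'
#' Grouped bar chart of the within-group fraction of each barcode category.
#'
#' @param object A `category_freq` from [category_frequencies()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.category_freq <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$category, y = .data$fraction, fill = .data$group)) +
    geom_col(position = position_dodge()) +
    labs(x = "Barcode category", y = "Fraction of group", fill = "Group") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
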