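#' Screen genes by fold change and p-value
#'
#' Simplified differential-expression screen between one responder group and a
#' pooled control: per gene, the fold change is the ratio of case to control
#' group means on the linear scale (2 raised to the group Log2 means), folded
#' to a signed convention (ratio if >= 1, else -1/ratio so that a halving is
#' reported as -2), and the p-value comes from a two-sided Welch t-test on the
#' Log2 levels. A gene is selected when p < `p_cutoff` and the signed fold
#' change is strictly outside `[-fc_cutoff, fc_cutoff]`. No multiple-testing
#' correction is applied.
#'
#' @param expr Long expression tibble (`donor_id`, `gene`, `log2_level`).
#' @param labels Tibble (`donor_id`, `label`) covering every donor in `expr`.
#' @param case_group Label of the case group (default `"High"`).
#' @param control_groups Labels pooled into the control group (default
#'   `c("Ave", "Low")`).
#' @param fc_cutoff,p_cutoff Selection cutoffs (defaults 1.2 and 0.05).
#' @return Tibble with columns `gene`, `fold_change`, `p_value`, `selected`.
#' @export
screen_genes <- function(expr, labels, case_group = "High",
                         control_groups = c("Ave", "Low"),
                         fc_cutoff = 1.2, p_cutoff = 0.05) {
  check_columns(expr, c("donor_id", "gene", "log2_level"), "expr")
  check_columns(labels, c("donor_id", "label"), "labels")
  check_positive_scalar(fc_cutoff, "fc_cutoff")
  check_positive_scalar(p_cutoff, "p_cutoff")
  groups <- as_responder_factor(c(case_group, control_groups),
                                "case/control groups")
  if (case_group %in% control_groups) {
    abort("`case_group` must not be one of `control_groups`.")
  }
  labels <- as_tibble(labels) |>
    distinct(.data$donor_id, .data$label) |>
    mutate(label = as_responder_factor(.data$label))
  joined <- left_join(as_tibble(expr), labels, by = "donor_id")
  if (anyNA(joined$label)) {
    unl <- unique(joined$donor_id[is.na(joined$label)])
    abort(sprintf(
      "Unlabelled donor%s: %s.", if (length(unl) > 1) "s" else "",
      paste(head(unl, 5), collapse = ", ")
    ))
  }
  joined <- joined |>
    mutate(arm = case_when(
      .data$label == case_group ~ "case",
      .data$label %in% control_groups ~ "control",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$arm))
  n_arm <- joined |>
    distinct(.data$donor_id, .data$arm) |>
    count(.data$arm)
  for (a in c("case", "control")) {
    n_a <- n_arm$n[n_arm$arm == a]
    if (length(n_a) == 0 || n_a < 2) {
      abort(sprintf("The %s group needs at least 2 donors.", a))
    }
  }
  welch_p <- function(x, y) {
    # Degenerate zero-variance genes: no evidence if the means agree,
    # unambiguous separation otherwise.
    if (sd(x) == 0 && sd(y) == 0) {
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    }
    tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
  }
  genes <- unique(joined$gene)
  out <- map_dfr(genes, function(g) {
    sub <- joined[joined$gene == g, ]
    x <- sub$log2_level[sub$arm == "case"]
    y <- sub$log2_level[sub$arm == "control"]
    ratio <- 2^(mean(x) - mean(y))
    tibble(
      gene = g,
      fold_change = if (ratio >= 1) ratio else -1 / ratio,
      p_value = welch_p(x, y)
    )
  })
  out |>
    mutate(selected = !is.na(.data$p_value) & .data$p_value < p_cutoff &
             (.data$fold_change > fc_cutoff | .data$fold_change < -fc_cutoff))
}
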