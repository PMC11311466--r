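#' Fit per-gene control statistics and perturbation cutoffs
#'
#' Computes, for every gene, the mean and sample SD (n - 1 denominator) of the
#' Log2 expression levels over the designated control donors (the combined
#' Average + Low responders in the reference analysis), and the perturbation
#' cutoffs at mean + SD (up-regulation) and mean - SD (down-regulation).
#' Levels between the cutoffs define each gene's "normal range".
#'
#' @param expr Long expression tibble (`donor_id`, `gene`, `log2_level`).
#' @param control_donors Character vector of donor identifiers forming the
#'   control set; at least 2, all present in `expr`.
#' @return A `control_stats` tibble: columns `gene`, `n_ctrl`, `m_ctrl`,
#'   `sd_ctrl`, `up_cutoff`, `down_cutoff`.
#' @examples
#' expr <- tibble::tibble(
#'   donor_id = c("a", "b"), gene = "NELL2", log2_level = c(1, 3)
#' )
#' fit_control_stats(expr, c("a", "b")) # mean 2, sd sqrt(2)
#' @export
fit_control_stats <- function(expr, control_donors) {
  check_columns(expr, c("donor_id", "gene", "log2_level"), "expr")
  control_donors <- unique(as.character(control_donors))
  if (length(control_donors) < 2) {
    abort("At least 2 control donors are required to estimate an SD.")
  }
  absent <- setdiff(control_donors, unique(expr$donor_id))
  if (length(absent) > 0) {
    abort(sprintf(
      "Control donor%s absent from the expression table: %s.",
      if (length(absent) > 1) "s" else "",
      paste(head(absent, 5), collapse = ", ")
    ))
  }
  out <- as_tibble(expr) |>
    filter(.data$donor_id %in% control_donors) |>
    group_by(.data$gene) |>
    summarise(
      n_ctrl = dplyr::n(),
      m_ctrl = mean(.data$log2_level),
      sd_ctrl = sd(.data$log2_level),
      .groups = "drop"
    ) |>
    mutate(
      up_cutoff = .data$m_ctrl + .data$sd_ctrl,
      down_cutoff = .data$m_ctrl - .data$sd_ctrl
    )
  class(out) <- c("control_stats", class(out))
  out
}

#' Call a perturbation status against control cutoffs
#'
#' A level strictly above the up-regulation cutoff is "Up", strictly below the
#' down-regulation cutoff "Down", and anything else (boundaries included)
#' "Norm". "Perturbed" means any status other than "Norm".
#'
#' @param level Numeric vector of Log2 expression levels.
#' @param up_cutoff,down_cutoff Cutoffs (recycled against `level`).
#' @return Factor with levels `Up`, `Norm`, `Down`.
#' @export
call_status <- function(level, up_cutoff, down_cutoff) {
  if (any(up_cutoff < down_cutoff, na.rm = TRUE)) {
    abort("`up_cutoff` must be >= `down_cutoff`.")
  }
  out <- ifelse(level > up_cutoff, "Up",
                ifelse(level < down_cutoff, "Down", "Norm"))
  factor(out, levels = STATUS_LEVELS)
}

#' Build personalized perturbation profiles (PEEP)
#'
#' Classifies every donor x gene Log2 level as Up, Norm or Down relative to
#' the control-range cutoffs of that gene. The result is each donor's
#' personalized perturbation profile.
#'
#' @param expr Long expression tibble (`donor_id`, `gene`, `log2_level`).
#' @param control_stats Per-gene cutoffs from [fit_control_stats()]; every
#'   gene in `expr` must be covered.
#' @return Tibble with columns `donor_id`, `gene`, `status`.
#' @export
build_peep <- function(expr, control_stats) {
  check_columns(expr, c("donor_id", "gene", "log2_level"), "expr")
  check_columns(control_stats, c("gene", "up_cutoff", "down_cutoff"),
                "control_stats")
  missing_genes <- setdiff(unique(expr$gene), control_stats$gene)
  if (length(missing_genes) > 0) {
    abort(sprintf(
      "No control stats for gene%s: %s.",
      if (length(missing_genes) > 1) "s" else "",
      paste(head(missing_genes, 5), collapse = ", ")
    ))
  }
  as_tibble(expr) |>
    left_join(
      select(as_tibble(control_stats), "gene", "up_cutoff", "down_cutoff"),
      by = "gene"
    ) |>
    mutate(status = call_status(.data$log2_level, .data$up_cutoff,
                                .data$down_cutoff)) |>
    select("donor_id", "gene", "status")
}

#' Summarize perturbation rates per gene and responder group
#'
#' For each gene, tabulates the number and percentage of donors called Up,
#' Down, or perturbed (Up + Down), within each responder group plus the
#' derived "Ave+Low" and "Total" rows. Percentages are rounded half-up to one
#' decimal.
#'
#' @param peep PEEP tibble from [build_peep()] (`donor_id`, `gene`, `status`).
#' @param labels Tibble with columns `donor_id`, `label` covering every donor
#'   in `peep`.
#' @return A `peep_group_summary` tibble: columns `gene`, `group`, `n_group`,
#'   `n_perturbed`, `n_up`, `n_down`, `pct_perturbed`, `pct_up`, `pct_down`.
#' @export
summarize_groups <- function(peep, labels) {
  check_columns(peep, c("donor_id", "gene", "status"), "peep")
  check_columns(labels, c("donor_id", "label"), "labels")
  labels <- as_tibble(labels) |>
    distinct(.data$donor_id, .data$label) |>
    mutate(label = as_responder_factor(.data$label))
  joined <- as_tibble(peep) |>
    mutate(status = as_status_factor(.data$status)) |>
    left_join(labels, by = "donor_id")
  if (anyNA(joined$label)) {
    unl <- unique(joined$donor_id[is.na(joined$label)])
    abort(sprintf(
      "Unlabelled donor%s: %s.", if (length(unl) > 1) "s" else "",
      paste(head(unl, 5), collapse = ", ")
    ))
  }
  base <- joined |>
    group_by(.data$gene, group = .data$label) |>
    summarise(
      n_group = dplyr::n(),
      n_up = sum(.data$status == "Up"),
      n_down = sum(.data$status == "Down"),
      .groups = "drop"
    ) |>
    complete(.data$gene, .data$group,
             fill = list(n_group = 0L, n_up = 0L, n_down = 0L)) |>
    mutate(group = as.character(.data$group))
  derived <- function(df, members, name) {
    df |>
      filter(.data$group %in% members) |>
      group_by(.data$gene) |>
      summarise(
        n_group = sum(.data$n_group),
        n_up = sum(.data$n_up),
        n_down = sum(.data$n_down),
        .groups = "drop"
      ) |>
      mutate(group = name)
  }
  out <- bind_rows(
    base,
    derived(base, c("Ave", "Low"), "Ave+Low"),
    derived(base, RESPONDER_LEVELS, "Total")
  ) |>
    mutate(
      group = factor(.data$group,
                     levels = c("High", "Ave", "Low", "Ave+Low", "Total")),
      n_perturbed = .data$n_up + .data$n_down,
      pct_perturbed = ifelse(.data$n_group > 0,
                             round_half_up(100 * .data$n_perturbed / .data$n_group), NA_real_),
      pct_up = ifelse(.data$n_group > 0,
                      round_half_up(100 * .data$n_up / .data$n_group), NA_real_),
      pct_down = ifelse(.data$n_group > 0,
                        round_half_up(100 * .data$n_down / .data$n_group), NA_real_)
    ) |>
    select("gene", "group", "n_group", "n_perturbed", "n_up", "n_down",
           "pct_perturbed", "pct_up", "pct_down") |>
    arrange(.data$gene, .data$group)
  class(out) <- c("peep_group_summary", class(out))
  out
}
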