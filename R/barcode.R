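barcode_code <- function(n_up, n_norm, n_down) {
  sprintf("%dU%dN%dD", n_up, n_norm, n_down)
}

# Category rule induced from the 4-gene reference table, valid for any panel
# size: k Up-calls and no Down-call -> "k-Up"; exactly one Up and one Down ->
# "1-Up-1-Down"; everything else -> "Others".
categorize_counts <- function(n_up, n_down) {
  case_when(
    n_up >= 1 & n_down == 0 ~ paste0(n_up, "-Up"),
    n_up == 1 & n_down == 1 ~ "1-Up-1-Down",
    TRUE ~ "Others"
  )
}

# Ordered category levels for a panel of `n_genes` genes.
category_levels <- function(n_genes) {
  ups <- if (n_genes >= 1) paste0(seq(n_genes, 1), "-Up") else character()
  c(ups, "1-Up-1-Down", "Others")
}

#' Summarize an ordered status tuple into a combination pattern
#'
#' Counts the Up/Norm/Down calls of one donor over a gene panel and renders
#' the canonical combination code (e.g. `"3U1N0D"`) and its category. Gene
#' order never affects the result.
#'
#' @param statuses Character or factor vector of per-gene statuses (`Up`,
#'   `Norm`, `Down`); non-empty.
#' @return One-row tibble: `n_up`, `n_norm`, `n_down`, `code`, `category`.
#' @examples
#' make_combination(c("Up", "Norm", "Up", "Up")) # 3U1N0D, 3-Up
#' @export
make_combination <- function(statuses) {
  if (length(statuses) == 0) {
    abort("`statuses` must contain at least one per-gene status.")
  }
  st <- as_status_factor(statuses, "statuses")
  if (anyNA(st)) {
    abort("`statuses` must not contain missing values.")
  }
  n_up <- sum(st == "Up")
  n_norm <- sum(st == "Norm")
  n_down <- sum(st == "Down")
  tibble(
    n_up = n_up, n_norm = n_norm, n_down = n_down,
    code = barcode_code(n_up, n_norm, n_down),
    category = categorize_counts(n_up, n_down)
  )
}

#' Categorize a combination pattern
#'
#' Maps Up/Down counts to the pattern category: `"<k>-Up"` when k genes are
#' Up and none Down, `"1-Up-1-Down"` for exactly one of each, `"Others"`
#' otherwise. Vectorized.
#'
#' @param n_up,n_down Non-negative integer counts of Up and Down calls.
#' @return Character vector of categories.
#' @examples
#' categorize(2, 0) # "2-Up"
#' categorize(2, 1) # "Others"
#' categorize(1, 1) # "1-Up-1-Down"
#' @export
categorize <- function(n_up, n_down) {
  if (any(n_up < 0) || any(n_down < 0) ||
      any(n_up != trunc(n_up)) || any(n_down != trunc(n_down))) {
    abort("`n_up` and `n_down` must be non-negative integers.")
  }
  categorize_counts(n_up, n_down)
}

#' Enumerate all combination patterns for a panel
#'
#' Lists every distinct (Up, Norm, Down) count composition of `n_genes`
#' genes — the full theoretical barcode space. There are
#' (n + 1)(n + 2) / 2 such patterns: 15 for a 4-gene panel, 45 for an
#' 8-gene panel. Rows are ordered by ascending Down count, then descending
#' Up count.
#'
#' @param n_genes Panel size (non-negative integer).
#' @return Tibble with columns `n_up`, `n_norm`, `n_down`, `code`,
#'   `category`.
#' @examples
#' nrow(enumerate_patterns(4)) # 15
#' nrow(enumerate_patterns(8)) # 45
#' @export
enumerate_patterns <- function(n_genes) {
  n_genes <- check_count(n_genes, "n_genes")
  out <- map_dfr(0:n_genes, function(d) {
    tibble(n_up = seq(n_genes - d, 0L), n_down = d)
  }) |>
    mutate(
      n_norm = n_genes - .data$n_up - .data$n_down,
      code = barcode_code(.data$n_up, .data$n_norm, .data$n_down),
      category = categorize_counts(.data$n_up, .data$n_down)
    ) |>
    select("n_up", "n_norm", "n_down", "code", "category")
  stopifnot(nrow(out) == (n_genes + 1) * (n_genes + 2) / 2)
  out
}

#' Barcode every donor over a signature gene panel
#'
#' Integrates the per-gene PEEP statuses of the panel genes into one
#' combination code and category per donor. The per-gene statuses are kept as
#' one column per panel gene (in panel order) for display; the code and
#' category are order-invariant.
#'
#' @param peep PEEP tibble from [build_peep()] (`donor_id`, `gene`,
#'   `status`).
#' @param panel Ordered character vector of panel gene identifiers, all
#'   present in `peep`.
#' @return Tibble with one row per donor: `donor_id`, one status column per
#'   panel gene, `n_up`, `n_norm`, `n_down`, `code`, `category`.
#' @export
barcode_cohort <- function(peep, panel = signature_panel()) {
  check_columns(peep, c("donor_id", "gene", "status"), "peep")
  panel <- as.character(panel)
  if (length(panel) == 0 || anyDuplicated(panel) > 0) {
    abort("`panel` must be a non-empty set of distinct gene identifiers.")
  }
  if (nrow(peep) == 0) {
    empty <- c(list(donor_id = character()),
               setNames(rep(list(character()), length(panel)), panel),
               list(n_up = numeric(), n_norm = numeric(),
                    n_down = numeric(), code = character(),
                    category = character()))
    return(as_tibble(empty))
  }
  missing_genes <- setdiff(panel, unique(peep$gene))
  if (length(missing_genes) > 0) {
    abort(sprintf(
      "Panel gene%s absent from the PEEP table: %s.",
      if (length(missing_genes) > 1) "s" else "",
      paste(missing_genes, collapse = ", ")
    ))
  }
  peep <- as_tibble(peep) |>
    mutate(status = as.character(as_status_factor(.data$status)))
  wide <- peep |>
    filter(.data$gene %in% panel) |>
    pivot_wider(id_cols = "donor_id", names_from = "gene",
                values_from = "status") |>
    select(all_of(c("donor_id", panel)))
  if (anyNA(wide)) {
    miss <- wide$donor_id[!stats::complete.cases(wide)]
    abort(sprintf(
      "Missing panel status for donor%s: %s.",
      if (length(miss) > 1) "s" else "",
      paste(head(miss, 5), collapse = ", ")
    ))
  }
  status_mat <- as.matrix(wide[, panel, drop = FALSE])
  wide |>
    mutate(
      n_up = rowSums(status_mat == "Up"),
      n_norm = rowSums(status_mat == "Norm"),
      n_down = rowSums(status_mat == "Down"),
      code = barcode_code(.data$n_up, .data$n_norm, .data$n_down),
      category = categorize_counts(.data$n_up, .data$n_down)
    )
}

#' Category frequencies per responder group
#'
#' Tabulates, within each responder group, how many donors fall into each
#' barcode category, as counts, exact fractions of the group, and
#' nearest-integer percentages. All categories are reported for every group,
#' including zero counts.
#'
#' @param barcodes Tibble from [barcode_cohort()].
#' @param labels Tibble (`donor_id`, `label`) covering every barcoded donor.
#' @return A `category_freq` tibble: columns `group`, `category`, `count`,
#'   `fraction`, `pct`.
#' @export
category_frequencies <- function(barcodes, labels) {
  check_columns(barcodes, c("donor_id", "category", "n_up", "n_norm",
                            "n_down"), "barcodes")
  check_columns(labels, c("donor_id", "label"), "labels")
  labels <- as_tibble(labels) |>
    distinct(.data$donor_id, .data$label) |>
    mutate(label = as_responder_factor(.data$label))
  joined <- as_tibble(barcodes) |>
    select("donor_id", "category", "n_up", "n_norm", "n_down") |>
    left_join(labels, by = "donor_id")
  if (anyNA(joined$label)) {
    unl <- unique(joined$donor_id[is.na(joined$label)])
    abort(sprintf(
      "Unlabelled donor%s: %s.", if (length(unl) > 1) "s" else "",
      paste(head(unl, 5), collapse = ", ")
    ))
  }
  n_panel <- joined$n_up[1] + joined$n_norm[1] + joined$n_down[1]
  cats <- category_levels(n_panel)
  group_sizes <- joined |>
    count(.data$label, name = "n_group")
  out <- joined |>
    mutate(category = factor(.data$category, levels = cats)) |>
    count(group = .data$label, .data$category, name = "count",
          .drop = FALSE) |>
    inner_join(group_sizes, by = c(group = "label")) |>
    mutate(
      fraction = .data$count / .data$n_group,
      pct = round_half_up(100 * .data$fraction, 0)
    ) |>
    select("group", "category", "count", "fraction", "pct")
  class(out) <- c("category_freq", class(out))
  out
}
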