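#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct on log10(quantity) over a dilution series of a
#' reference RNA. A valid amplification curve has a negative slope (about
#' -3.32 Ct per decade at 100% efficiency).
#'
#' @param points Data frame of calibration points.
#' @param quantity,ct Columns holding the known input quantity and the
#'   measured Ct (tidy-eval); defaults `quantity` and `ct`.
#' @param gene Optional gene identifier stored with the curve.
#' @return An object of class `standard_curve` with elements `gene`, `slope`
#'   (Ct per log10 quantity), `intercept` (Ct at quantity 1) and `n`.
#' @examples
#' pts <- tibble::tibble(quantity = c(1, 10, 100), ct = c(30, 26.68, 23.36))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points, quantity = quantity, ct = ct,
                               gene = NULL) {
  q <- eval_tidy(enquo(quantity), points)
  y <- eval_tidy(enquo(ct), points)
  if (!is.numeric(q) || !is.numeric(y) || anyNA(q) || anyNA(y)) {
    abort("Standard-curve quantities and Ct values must be numeric, no NA.")
  }
  if (any(q <= 0)) {
    abort("Standard-curve quantities must be strictly positive.")
  }
  if (length(unique(q)) < 2) {
    abort("At least 2 distinct quantities are required to fit a curve.")
  }
  fit <- lm(y ~ log10(q))
  b <- unname(coef(fit))
  structure(
    list(gene = gene, slope = b[2], intercept = b[1], n = length(q)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve%s: Ct = %.4f + %.4f * log10(quantity)  (n = %d)\n",
    if (is.null(x$gene)) "" else paste0(" [", x$gene, "]"),
    x$intercept, x$slope, x$n
  ))
  invisible(x)
}

#' Convert Ct values to quantities via a standard curve
#'
#' Inverts the fitted line: quantity = 10^((ct - intercept) / slope).
#'
#' @param ct Numeric vector of Ct values.
#' @param curve A `standard_curve` from [fit_standard_curve()].
#' @return Positive numeric vector of quantities.
#' @export
ct_to_quantity <- function(ct, curve) {
  if (!inherits(curve, "standard_curve")) {
    abort("`curve` must be a `standard_curve` object.")
  }
  if (curve$slope >= 0) {
    abort("Invalid standard curve: slope must be negative.")
  }
  10^((ct - curve$intercept) / curve$slope)
}

#' Plate-to-plate normalization factors
#'
#' For each plate and target gene, the normalization factor is the plate's
#' reference-control quantity divided by the average of that control over all
#' plates: NFq = Qc / mean(Qc) for the target-gene channel and
#' NFg = Gc / mean(Gc) for the GAPDH channel, both per gene. By construction
#' the per-gene mean of each factor over plates is exactly 1.
#'
#' @param plate_controls Data frame with columns `plate_id`, `gene`, `Qc`,
#'   `Gc`; extra columns (e.g. the per-sample quantities of a full plate
#'   table) are ignored, but control values must be consistent within each
#'   plate x gene.
#' @return Tibble with columns `plate_id`, `gene`, `NFq`, `NFg`.
#' @examples
#' ctrl <- tibble::tibble(
#'   plate_id = c("P1", "P2"), gene = "NELL2", Qc = c(2, 4), Gc = c(1, 1)
#' )
#' normalization_factors(ctrl) # NFq = 2/3, 4/3
#' @export
normalization_factors <- function(plate_controls) {
  check_columns(plate_controls, c("plate_id", "gene", "Qc", "Gc"),
                "plate_controls")
  ctrl <- distinct(as_tibble(plate_controls), .data$plate_id, .data$gene,
                   .data$Qc, .data$Gc)
  dup <- ctrl |>
    count(.data$plate_id, .data$gene) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Conflicting control quantities for plate x gene: %s.",
      paste(paste0(dup$plate_id, "/", dup$gene), collapse = ", ")
    ))
  }
  if (any(!is.finite(ctrl$Qc)) || any(!is.finite(ctrl$Gc)) ||
      any(ctrl$Qc <= 0) || any(ctrl$Gc <= 0)) {
    abort("Control quantities Qc and Gc must be strictly positive.")
  }
  ctrl |>
    group_by(.data$gene) |>
    mutate(NFq = .data$Qc / mean(.data$Qc), NFg = .data$Gc / mean(.data$Gc)) |>
    ungroup() |>
    select("plate_id", "gene", "NFq", "NFg")
}

#' Normalized expression levels from plate measurements
#'
#' Applies the ratio normalization (Qs / NFq) / (Gs / NFg): the sample's
#' target-gene quantity, corrected by its plate's target-channel factor, over
#' the sample's GAPDH quantity corrected by the plate's GAPDH-channel factor.
#' Because both corrections are ratios to a cross-plate average, any
#' multiplicative plate effect cancels exactly.
#'
#' @param plates Data frame with one row per donor x gene: columns `plate_id`,
#'   `donor_id`, `gene`, `Qs`, `Gs`, `Qc`, `Gc` (triplicate-mean quantities).
#' @param factors Optional precomputed factors from
#'   [normalization_factors()]; computed from `plates` when `NULL`.
#' @return Tibble with columns `donor_id`, `gene`, `level` (linear scale,
#'   strictly positive).
#' @export
expression_levels <- function(plates, factors = NULL) {
  check_columns(plates, c("plate_id", "donor_id", "gene", "Qs", "Gs"),
                "plates")
  plates <- as_tibble(plates)
  if (is.null(factors)) {
    factors <- normalization_factors(plates)
  }
  check_columns(factors, c("plate_id", "gene", "NFq", "NFg"), "factors")
  bad <- plates |>
    filter(!is.finite(.data$Qs) | !is.finite(.data$Gs) |
             .data$Qs <= 0 | .data$Gs <= 0)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Non-positive sample quantity for donor x gene: %s.",
      paste(head(paste0(bad$donor_id, "/", bad$gene), 5), collapse = ", ")
    ))
  }
  dup <- plates |>
    count(.data$donor_id, .data$gene) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Duplicate measurement for donor x gene: %s.",
      paste(head(paste0(dup$donor_id, "/", dup$gene), 5), collapse = ", ")
    ))
  }
  joined <- left_join(plates, factors, by = c("plate_id", "gene"))
  if (anyNA(joined$NFq) || anyNA(joined$NFg)) {
    miss <- joined |> filter(is.na(.data$NFq) | is.na(.data$NFg))
    abort(sprintf(
      "Missing plate control (normalization factor) for plate x gene: %s.",
      paste(head(unique(paste0(miss$plate_id, "/", miss$gene)), 5),
            collapse = ", ")
    ))
  }
  joined |>
    mutate(level = (.data$Qs / .data$NFq) / (.data$Gs / .data$NFg)) |>
    select("donor_id", "gene", "level")
}

#' Assemble a Log2 expression table
#'
#' Log2-transforms normalized levels into the long donor x gene expression
#' table used by all downstream analysis. Levels above 1 (expressed above the
#' reference) map to positive Log2 values, levels below 1 to negative values.
#'
#' @param levels Data frame with columns `donor_id`, `gene` and a positive
#'   level column.
#' @param level Column holding the linear-scale level (tidy-eval); default
#'   `level`.
#' @return Tibble with columns `donor_id`, `gene`, `log2_level`, one row per
#'   donor x gene pair.
#' @export
assemble_log2_matrix <- function(levels, level = level) {
  check_columns(levels, c("donor_id", "gene"), "levels")
  levels <- as_tibble(levels)
  vals <- eval_tidy(enquo(level), levels)
  bad <- which(!is.finite(vals) | vals <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-positive expression level (Log2 undefined) for donor x gene: %s.",
      paste(head(paste0(levels$donor_id[bad], "/", levels$gene[bad]), 5),
            collapse = ", ")
    ))
  }
  dup <- levels |>
    count(.data$donor_id, .data$gene) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Duplicate level for donor x gene: %s.",
      paste(head(paste0(dup$donor_id, "/", dup$gene), 5), collapse = ", ")
    ))
  }
  tibble(
    donor_id = levels$donor_id,
    gene = levels$gene,
    log2_level = log2(vals)
  )
}

#' Full qPCR normalization: plate table to Log2 expression
#'
#' Convenience wrapper chaining [normalization_factors()],
#' [expression_levels()] and [assemble_log2_matrix()].
#'
#' @inheritParams expression_levels
#' @return Tibble with columns `donor_id`, `gene`, `log2_level`.
#' @export
normalize_plates <- function(plates, factors = NULL) {
  plates |>
    expression_levels(factors = factors) |>
    assemble_log2_matrix()
}

#' Pivot a long expression table to a wide donor x gene tibble
#'
#' @param expr Long expression tibble (`donor_id`, `gene`, `log2_level`).
#' @return Wide tibble: one row per donor, one column per gene.
#' @export
expr_to_wide <- function(expr) {
  check_columns(expr, c("donor_id", "gene", "log2_level"), "expr")
  pivot_wider(as_tibble(expr), id_cols = "donor_id",
              names_from = "gene", values_from = "log2_level")
}

#' Pivot a wide donor x gene tibble back to the long canonical form
#'
#' @param wide Wide tibble with a `donor_id` column and one column per gene.
#' @return Long tibble (`donor_id`, `gene`, `log2_level`).
#' @export
expr_to_long <- function(wide) {
  check_columns(wide, "donor_id", "wide")
  pivot_longer(as_tibble(wide), -"donor_id",
               names_to = "gene", values_to = "log2_level")
}
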