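#' Default 8-gene signature panel specification
#'
#' The eight qPCR-validated signature genes with the direction of their shift
#' in High responders: AKAP12, ITM2C, IL13RA1, NELL2, CALB2 and TMEM255B are
#' up-regulated, GADD45B and DPP4 down-regulated. Baselines are on the Log2
#' scale relative to the reference RNA; shifts are additive Log2 effects
#' applied to High responders only.
#'
#' @param shift Absolute Log2 shift magnitude applied with the gene's sign
#'   (default 1, i.e. a two-fold change).
#' @return Tibble with columns `gene`, `baseline_log2`, `high_shift_log2`.
#' @export
default_gene_panel <- function(shift = 1) {
  check_positive_scalar(shift, "shift", allow_zero = TRUE)
  tibble(
    gene = c("AKAP12", "ITM2C", "IL13RA1", "NELL2", "CALB2", "TMEM255B",
             "GADD45B", "DPP4"),
    baseline_log2 = 0,
    high_shift_log2 = c(1, 1, 1, 1, 1, 1, -1, -1) * shift
  )
}

#' The 4-gene barcode signature panel
#'
#' The four up-regulated genes used for combinatorial barcoding, in display
#' order: NELL2, ITM2C, AKAP12, IL13RA1.
#'
#' @return Character vector of length 4.
#' @export
signature_panel <- function() {
  c("NELL2", "ITM2C", "AKAP12", "IL13RA1")
}

#' Simulate percent histamine release for a donor cohort
#'
#' Draws release percentages from a normal distribution truncated to
#' \[0, 100\] via the inverse-CDF method, emulating the unimodal release
#' distribution of a healthy-donor cohort (defaults: mean 24.1%, SD 15.1%).
#'
#' @param n Number of donors (non-negative).
#' @param mean,sd Mean and SD of the untruncated normal, in percent
#'   (`sd > 0`).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Tibble with columns `donor_id`, `release_pct`.
#' @examples
#' simulate_histamine(5, seed = 1)
#' @export
simulate_histamine <- function(n, mean = 24.1, sd = 15.1, seed = NULL) {
  n <- check_count(n, "n")
  check_positive_scalar(sd, "sd")
  maybe_set_seed(seed)
  lo <- pnorm(0, mean, sd)
  hi <- pnorm(100, mean, sd)
  release <- qnorm(runif(n, lo, hi), mean, sd)
  tibble(
    donor_id = sprintf("D%04d", seq_len(n)),
    release_pct = pmin(pmax(release, 0), 100)
  )
}

#' Simulate Log2 expression levels for labelled donors
#'
#' Generates the true (pre-measurement) Log2 expression of each donor x gene:
#' the gene's baseline, plus its High-responder shift when the donor is
#' labelled High, plus Gaussian noise. This is the expression structure the
#' downstream PEEP analysis assumes: control (Ave/Low) donors share one
#' normal distribution per gene and High responders are shifted.
#'
#' @param labels Tibble (`donor_id`, `label`) with labels in
#'   `High`/`Ave`/`Low`.
#' @param gene_specs Tibble (`gene`, `baseline_log2`, `high_shift_log2`);
#'   default [default_gene_panel()].
#' @param noise_sd Donor-level Log2 noise SD (>= 0; default 0.5).
#' @param seed Optional integer seed.
#' @return Long tibble (`donor_id`, `gene`, `true_log2`).
#' @export
simulate_expression <- function(labels, gene_specs = default_gene_panel(),
                                noise_sd = 0.5, seed = NULL) {
  check_columns(labels, c("donor_id", "label"), "labels")
  check_columns(gene_specs, c("gene", "baseline_log2", "high_shift_log2"),
                "gene_specs")
  check_positive_scalar(noise_sd, "noise_sd", allow_zero = TRUE)
  if (anyDuplicated(gene_specs$gene) > 0) {
    abort("Gene identifiers in `gene_specs` must be unique.")
  }
  if (anyDuplicated(labels$donor_id) > 0) {
    abort("Donor identifiers in `labels` must be unique.")
  }
  lab <- as_responder_factor(labels$label, "labels$label")
  if (anyNA(lab)) {
    abort("Every donor must carry a responder label.")
  }
  maybe_set_seed(seed)
  grid <- crossing(
    donor_id = factor(labels$donor_id, levels = labels$donor_id),
    gene = factor(gene_specs$gene, levels = gene_specs$gene)
  ) |>
    arrange(.data$donor_id, .data$gene) |>
    mutate(donor_id = as.character(.data$donor_id),
           gene = as.character(.data$gene))
  grid |>
    left_join(tibble(donor_id = labels$donor_id, label = lab),
              by = "donor_id") |>
    left_join(as_tibble(gene_specs), by = "gene") |>
    mutate(
      true_log2 = .data$baseline_log2 +
        .data$high_shift_log2 * (.data$label == "High") +
        rnorm(dplyr::n(), 0, noise_sd)
    ) |>
    select("donor_id", "gene", "true_log2")
}

#' Emit raw qPCR plate data consistent with known expression levels
#'
#' Inverts the ratio normalization: donors are assigned round-robin to
#' plates; per-plate (and per plate x gene) control quantities Qc and Gc are
#' drawn log-normally with spread `plate_factor_sd`, donor GAPDH quantities
#' Gs log-normally around 10; the target-gene quantity is then set to
#' Qs = 2^true_log2 * NFq * Gs / NFg, so that applying
#' (Qs / NFq) / (Gs / NFg) to the emitted table reproduces 2^true_log2
#' exactly (up to floating point), for any plate-effect magnitude.
#'
#' @param true_expr Long tibble (`donor_id`, `gene`, `true_log2`), all
#'   finite.
#' @param n_plates Number of plates (>= 1; default 3).
#' @param plate_factor_sd Log-scale SD of the multiplicative plate effects
#'   (>= 0; default 0.25). Zero yields NFq = NFg = 1 everywhere.
#' @param seed Optional integer seed.
#' @return Tibble with columns `plate_id`, `donor_id`, `gene`, `Qs`, `Gs`,
#'   `Qc`, `Gc`, one row per donor x gene.
#' @export
emit_plate_data <- function(true_expr, n_plates = 3, plate_factor_sd = 0.25,
                            seed = NULL) {
  check_columns(true_expr, c("donor_id", "gene", "true_log2"), "true_expr")
  n_plates <- check_count(n_plates, "n_plates", min = 1)
  check_positive_scalar(plate_factor_sd, "plate_factor_sd", allow_zero = TRUE)
  if (any(!is.finite(true_expr$true_log2))) {
    abort("All `true_log2` values must be finite.")
  }
  maybe_set_seed(seed)
  donors <- unique(true_expr$donor_id)
  genes <- unique(true_expr$gene)
  plate_of <- setNames(
    sprintf("P%02d", (seq_along(donors) - 1L) %% n_plates + 1L), donors
  )
  plate_ids <- sprintf("P%02d", seq_len(min(n_plates, max(length(donors), 1))))
  # Draw order is fixed (plate controls, then GAPDH controls, then donor Gs)
  # so a given seed pins every emitted number.
  ctrl <- crossing(plate_id = plate_ids, gene = genes) |>
    arrange(.data$plate_id, .data$gene) |>
    mutate(Qc = 5 * rlnorm(dplyr::n(), 0, plate_factor_sd))
  gapdh_ctrl <- tibble(
    plate_id = plate_ids,
    Gc = 5 * rlnorm(length(plate_ids), 0, plate_factor_sd)
  )
  gs_of <- setNames(rlnorm(length(donors), log(10), 0.3), donors)
  ctrl <- left_join(ctrl, gapdh_ctrl, by = "plate_id")
  nf <- normalization_factors(ctrl)
  as_tibble(true_expr) |>
    mutate(plate_id = unname(plate_of[.data$donor_id]),
           Gs = unname(gs_of[.data$donor_id])) |>
    left_join(ctrl, by = c("plate_id", "gene")) |>
    left_join(nf, by = c("plate_id", "gene")) |>
    mutate(Qs = 2^.data$true_log2 * .data$NFq * .data$Gs / .data$NFg) |>
    select("plate_id", "donor_id", "gene", "Qs", "Gs", "Qc", "Gc")
}

#' Simulate a complete synthetic cohort
#'
#' Generates a seeded cohort with the full structure the pipeline consumes:
#' histamine release percentages, responder labels from the mean +/- SD rule
#' refit on the simulated cohort, true Log2 expression with High-responder
#' shifts, and raw qPCR plate data whose normalization reproduces the true
#' levels.
#'
#' @param n_donors Cohort size (default 94, the size of the reference PEEP
#'   cohort).
#' @param release_mean,release_sd Generating release distribution in percent
#'   (defaults 24.1 and 15.1).
#' @param gene_specs Gene panel specification; default
#'   [default_gene_panel()].
#' @param n_plates,plate_factor_sd,noise_sd See [emit_plate_data()] and
#'   [simulate_expression()].
#' @param seed Optional integer seed fixing every emitted number.
#' @return An `mc_cohort` list: `donors` (labelled release tibble),
#'   `true_log2`, `plates`, and the fitted `release_stats`.
#' @examples
#' cohort <- simulate_cohort(n_donors = 20, seed = 1)
#' dplyr::count(cohort$donors, label)
#' @export
simulate_cohort <- function(n_donors = 94, release_mean = 24.1,
                            release_sd = 15.1,
                            gene_specs = default_gene_panel(),
                            n_plates = 3, plate_factor_sd = 0.25,
                            noise_sd = 0.5, seed = NULL) {
  n_donors <- check_count(n_donors, "n_donors")
  maybe_set_seed(seed)
  donors <- simulate_histamine(n_donors, release_mean, release_sd)
  if (n_donors >= 2) {
    donors <- stratify(donors)
    stats <- attr(donors, "release_stats")
  } else {
    donors$label <- factor(character(n_donors), levels = RESPONDER_LEVELS)
    stats <- NULL
  }
  true_log2 <- simulate_expression(donors, gene_specs, noise_sd = noise_sd)
  plates <- emit_plate_data(true_log2, n_plates = n_plates,
                            plate_factor_sd = plate_factor_sd)
  structure(
    list(donors = donors, true_log2 = true_log2, plates = plates,
         release_stats = stats),
    class = "mc_cohort"
  )
}

#' @export
print.mc_cohort <- function(x, ...) {
  counts <- table(x$donors$label)
  cat(sprintf(
    "Synthetic mast-cell cohort: %d donors (High %d / Ave %d / Low %d), %d genes, %d plate rows\n",
    nrow(x$donors), counts[["High"]], counts[["Ave"]], counts[["Low"]],
    length(unique(x$true_log2$gene)), nrow(x$plates)
  ))
  if (!is.null(x$release_stats)) print(x$release_stats)
  invisible(x)
}
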