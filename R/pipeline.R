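# Typed TSV readers with row-level error context, plus the end-to-end driver.

# Read a TSV against a declared schema. `col_types` is a readr cols() spec;
# `key` columns must be jointly unique. Parse failures are reported with the
# offending row and column.
read_table_checked <- function(path, col_types, key = NULL, what = "table") {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  df <- suppressWarnings(
    readr::read_tsv(path, col_types = col_types, na = c("", "NA"),
                    progress = FALSE)
  )
  expected <- names(col_types$cols)
  check_columns(df, expected, what)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(sprintf(
      "Could not parse %s: row %d, column %d expected %s, got '%s' (%d problem%s in total).",
      what, p$row, p$col, p$expected, p$actual, nrow(probs),
      if (nrow(probs) > 1) "s" else ""
    ))
  }
  na_rows <- which(!stats::complete.cases(df[expected]))
  if (length(na_rows) > 0) {
    abort(sprintf(
      "Missing value%s in %s at data row%s %s.",
      if (length(na_rows) > 1) "s" else "", what,
      if (length(na_rows) > 1) "s" else "",
      paste(head(na_rows, 5), collapse = ", ")
    ))
  }
  if (!is.null(key)) {
    dup <- which(duplicated(df[key]))
    if (length(dup) > 0) {
      abort(sprintf(
        "Duplicate %s in %s at data row%s %s.",
        paste(key, collapse = " x "), what,
        if (length(dup) > 1) "s" else "",
        paste(head(dup, 5), collapse = ", ")
      ))
    }
  }
  df
}

#' Read a donor histamine-release table
#'
#' Expects a TSV with columns `donor_id` and `release_pct` (percent in
#' \[0, 100\]).
#'
#' @param path Path to the TSV file.
#' @return Tibble (`donor_id`, `release_pct`).
#' @export
read_histamine_tsv <- function(path) {
  df <- read_table_checked(
    path,
    readr::cols(donor_id = readr::col_character(),
                release_pct = readr::col_double()),
    key = "donor_id", what = "histamine table"
  )
  out_of_range <- which(df$release_pct < 0 | df$release_pct > 100)
  if (length(out_of_range) > 0) {
    abort(sprintf(
      "Release percentages outside [0, 100] at data row%s %s.",
      if (length(out_of_range) > 1) "s" else "",
      paste(head(out_of_range, 5), collapse = ", ")
    ))
  }
  df
}

#' Read a donor label table
#'
#' Expects a TSV with columns `donor_id` and `label`
#' (`High`/`Ave`/`Low`); a `release_pct` column is carried through if
#' present.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `label` as a responder factor.
#' @export
read_labels_tsv <- function(path) {
  df <- read_table_checked(
    path,
    readr::cols(donor_id = readr::col_character(),
                label = readr::col_character(),
                .default = readr::col_double()),
    key = "donor_id", what = "label table"
  )
  df$label <- as_responder_factor(df$label, "label column")
  df
}

#' Read a qPCR plate table
#'
#' Expects a TSV with columns `plate_id`, `donor_id`, `gene`, `Qs`, `Gs`,
#' `Qc`, `Gc`, one row per donor x gene.
#'
#' @param path Path to the TSV file.
#' @return Tibble of plate measurements.
#' @export
read_plates_tsv <- function(path) {
  read_table_checked(
    path,
    readr::cols(plate_id = readr::col_character(),
                donor_id = readr::col_character(),
                gene = readr::col_character(),
                Qs = readr::col_double(), Gs = readr::col_double(),
                Qc = readr::col_double(), Gc = readr::col_double()),
    key = c("donor_id", "gene"), what = "plate table"
  )
}

#' Read a wide Log2 expression table
#'
#' Expects a TSV with a `donor_id` column and one numeric column per gene;
#' returns the long canonical form.
#'
#' @param path Path to the TSV file.
#' @return Long tibble (`donor_id`, `gene`, `log2_level`).
#' @export
read_expr_tsv <- function(path) {
  df <- read_table_checked(
    path,
    readr::cols(donor_id = readr::col_character(),
                .default = readr::col_double()),
    key = "donor_id", what = "expression table"
  )
  if (ncol(df) < 2) {
    abort("Expression table must have at least one gene column.")
  }
  expr_to_long(df)
}

#' Write a long expression table as a wide donor x gene TSV
#'
#' @param expr Long tibble (`donor_id`, `gene`, `log2_level`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(expr, path) {
  readr::write_tsv(expr_to_wide(expr), path)
  invisible(path)
}

default_pipeline_config <- function() {
  list(
    n_donors = 94, release_mean = 24.1, release_sd = 15.1,
    shift = 1, noise_sd = 0.5, n_plates = 3, plate_factor_sd = 0.25,
    histamine = NULL, plates = NULL, expr = NULL, labels = NULL,
    control_groups = c("Ave", "Low"),
    panel = signature_panel(),
    fc_cutoff = 1.2, p_cutoff = 0.05, run_screen = TRUE,
    out_dir = NULL, seed = NULL, quiet = FALSE
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("Config file not found: %s", config))
    }
    ext <- tolower(tools::file_ext(config))
    config <- switch(
      ext,
      yaml = ,
      yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      abort("Config must be a .yaml/.yml or .json file.")
    )
  }
  if (!is.list(config)) {
    abort("`config` must be a list or a path to a YAML/JSON file.")
  }
  unknown <- setdiff(names(config), names(default_pipeline_config()))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config field%s: %s.",
                  if (length(unknown) > 1) "s" else "",
                  paste(unknown, collapse = ", ")))
  }
  modifyList(default_pipeline_config(), config)
}

#' Run the full analysis pipeline
#'
#' Orchestrates stratification, qPCR normalization, PEEP profiling, the
#' optional marker screen, and combinatorial barcoding, from either supplied
#' input tables or a seeded synthetic cohort. All stage outputs are written
#' as TSV (plus a JSON report) when `out_dir` is set; the same config and
#' seed always reproduce byte-identical outputs.
#'
#' Config fields (list or YAML/JSON path): simulation parameters
#' (`n_donors`, `release_mean`, `release_sd`, `shift`, `noise_sd`,
#' `n_plates`, `plate_factor_sd`) used when no input files are given; input
#' paths (`histamine`, `plates` or `expr`, optional `labels`); analysis
#' settings (`control_groups`, `panel`, `fc_cutoff`, `p_cutoff`,
#' `run_screen`); and `out_dir`, `seed`, `quiet`.
#'
#' @param config Pipeline configuration (list, or path to YAML/JSON).
#' @return A `peep_report` list with elements `release_stats`,
#'   `group_counts`, `control_stats`, `group_summary`, `screen`, `barcodes`,
#'   `category_frequencies`, `labels`, `expr`, and `provenance`.
#' @examples
#' report <- run_pipeline(list(n_donors = 30, seed = 1, quiet = TRUE))
#' report$category_frequencies
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  say <- function(...) if (!isTRUE(cfg$quiet)) inform(sprintf(...))
  maybe_set_seed(cfg$seed)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  simulated <- is.null(cfg$histamine) && is.null(cfg$plates) &&
    is.null(cfg$expr)
  if (simulated) {
    say("Simulating cohort of %d donors", cfg$n_donors)
    cohort <- stage("simulate", simulate_cohort(
      n_donors = cfg$n_donors, release_mean = cfg$release_mean,
      release_sd = cfg$release_sd,
      gene_specs = default_gene_panel(cfg$shift),
      n_plates = cfg$n_plates, plate_factor_sd = cfg$plate_factor_sd,
      noise_sd = cfg$noise_sd
    ))
    donors <- cohort$donors
    release_stats <- cohort$release_stats
    plates <- cohort$plates
  } else {
    plates <- if (!is.null(cfg$plates)) {
      stage("read", read_plates_tsv(cfg$plates))
    }
    if (!is.null(cfg$histamine)) {
      hist_tbl <- stage("read", read_histamine_tsv(cfg$histamine))
      say("Stratifying %d donors", nrow(hist_tbl))
      donors <- stage("stratify", stratify(hist_tbl))
      release_stats <- attr(donors, "release_stats")
    } else if (!is.null(cfg$labels)) {
      donors <- stage("read", read_labels_tsv(cfg$labels))
      release_stats <- NULL
    } else {
      abort("Provide either `histamine` or `labels` in the config.")
    }
  }
  labels <- as_tibble(donors)[, intersect(c("donor_id", "release_pct",
                                            "label"), names(donors))]

  expr <- if (!simulated && !is.null(cfg$expr)) {
    stage("read", read_expr_tsv(cfg$expr))
  } else {
    say("Normalizing %d plate rows", nrow(plates))
    stage("normalize", normalize_plates(plates))
  }

  bad_panel <- setdiff(cfg$panel, unique(expr$gene))
  if (length(bad_panel) > 0) {
    abort(sprintf(
      "Panel gene%s absent from the expression data: %s.",
      if (length(bad_panel) > 1) "s" else "",
      paste(bad_panel, collapse = ", ")
    ))
  }

  control_ids <- labels$donor_id[labels$label %in% cfg$control_groups]
  say("Fitting control stats on %d %s donors", length(control_ids),
      paste(cfg$control_groups, collapse = "+"))
  control_stats <- stage("peep", fit_control_stats(expr, control_ids))
  peep <- stage("peep", build_peep(expr, control_stats))
  group_summary <- stage("peep", summarize_groups(peep, labels))

  screen <- if (isTRUE(cfg$run_screen)) {
    stage("screen", screen_genes(expr, labels,
                                 control_groups = cfg$control_groups,
                                 fc_cutoff = cfg$fc_cutoff,
                                 p_cutoff = cfg$p_cutoff))
  }

  say("Barcoding over panel: %s", paste(cfg$panel, collapse = ", "))
  barcodes <- stage("barcode", barcode_cohort(peep, cfg$panel))
  freq <- stage("barcode", category_frequencies(barcodes, labels))

  report <- structure(
    list(
      release_stats = release_stats,
      group_counts = count(labels, .data$label, name = "n", .drop = FALSE),
      control_stats = control_stats,
      group_summary = group_summary,
      screen = screen,
      peep = peep,
      barcodes = barcodes,
      category_frequencies = freq,
      labels = labels,
      expr = expr,
      provenance = list(
        package = "peepbarcode",
        version = as.character(utils::packageVersion("peepbarcode")),
        seed = cfg$seed,
        simulated = simulated,
        config_hash = rlang::hash(cfg[setdiff(names(cfg),
                                              c("out_dir", "quiet"))])
      )
    ),
    class = "peep_report"
  )

  if (!is.null(cfg$out_dir)) {
    write_report(report, cfg$out_dir)
    say("Wrote outputs to %s", cfg$out_dir)
  }
  report
}

#' Write all pipeline stage outputs to a directory
#'
#' Emits `labels.tsv`, `stats.json`, `expr_log2.tsv`, `control_stats.tsv`,
#' `peep_calls.tsv`, `group_summary.tsv`, `screen.tsv` (when run),
#' `barcodes.tsv`, `category_freq.tsv` and `report.json`.
#'
#' @param report A `peep_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!inherits(report, "peep_report")) {
    abort("`report` must be a `peep_report` from run_pipeline().")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(report$labels, p("labels.tsv"))
  if (!is.null(report$release_stats)) {
    jsonlite::write_json(unclass(report$release_stats), p("stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_expr_tsv(report$expr, p("expr_log2.tsv"))
  readr::write_tsv(report$control_stats, p("control_stats.tsv"))
  readr::write_tsv(report$peep, p("peep_calls.tsv"))
  readr::write_tsv(report$group_summary, p("group_summary.tsv"))
  if (!is.null(report$screen)) {
    readr::write_tsv(report$screen, p("screen.tsv"))
  }
  readr::write_tsv(report$barcodes, p("barcodes.tsv"))
  readr::write_tsv(report$category_frequencies, p("category_freq.tsv"))
  json_report <- list(
    release_stats = if (!is.null(report$release_stats)) {
      unclass(report$release_stats)
    },
    group_counts = report$group_counts,
    control_stats = as_tibble(report$control_stats),
    group_summary = as_tibble(report$group_summary),
    screen = report$screen,
    category_frequencies = as_tibble(report$category_frequencies),
    provenance = report$provenance
  )
  jsonlite::write_json(json_report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.peep_report <- function(x, ...) {
  cat("PEEP barcode pipeline report\n")
  if (!is.null(x$release_stats)) print(x$release_stats)
  counts <- x$group_counts
  cat("Group sizes: ",
      paste(sprintf("%s %d", counts$label, counts$n), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("Genes profiled: %d; panel: %s\n",
              nrow(x$control_stats),
              paste(setdiff(names(x$barcodes),
                            c("donor_id", "n_up", "n_norm", "n_down", "code",
                              "category")), collapse = ", ")))
  top <- x$category_frequencies |>
    filter(.data$group == "High", .data$count > 0) |>
    arrange(desc(.data$count))
  if (nrow(top) > 0) {
    cat(sprintf("Most frequent High-responder category: %s (%d/%d)\n",
                as.character(top$category[1]), top$count[1],
                sum(x$group_counts$n[x$group_counts$label == "High"])))
  }
  invisible(x)
}
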