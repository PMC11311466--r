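test_that("control stats give mean, sample SD and symmetric cutoffs", {
  expr <- tibble::tibble(donor_id = c("a", "b"), gene = "G1",
                         log2_level = c(1, 3))
  cs <- fit_control_stats(expr, c("a", "b"))
  expect_equal(cs$m_ctrl, 2)
  expect_equal(cs$sd_ctrl, sqrt(2))
  expect_equal(cs$up_cutoff, 2 + sqrt(2))
  expect_equal(cs$down_cutoff, 2 - sqrt(2))

  flat <- tibble::tibble(donor_id = c("a", "b", "c"), gene = "G1",
                         log2_level = 1.5)
  cs0 <- fit_control_stats(flat, c("a", "b", "c"))
  expect_equal(cs0$sd_ctrl, 0)
  expect_equal(cs0$up_cutoff, cs0$m_ctrl)
  expect_equal(cs0$down_cutoff, cs0$m_ctrl)

  expect_error(fit_control_stats(expr, "a"), "At least 2")
  expect_error(fit_control_stats(expr, c("a", "zz")), "absent")
})

test_that("control estimates converge on the generating distribution", {
  labels <- make_labels(0, 300, 200)
  specs <- tibble::tibble(gene = "G1", baseline_log2 = 1.2,
                          high_shift_log2 = 2)
  expr <- simulate_expression(labels, specs, noise_sd = 0.5, seed = 31) |>
    dplyr::rename(log2_level = true_log2)
  cs <- fit_control_stats(expr, labels$donor_id)
  se <- 0.5 / sqrt(500)
  expect_lt(abs(cs$m_ctrl - 1.2), 3 * se)
})

test_that("status calls use strict inequalities, boundaries Norm", {
  expect_equal(as.character(call_status(2 + sqrt(2), 2 + sqrt(2),
                                        2 - sqrt(2))), "Norm")
  expect_equal(as.character(call_status(2, 2 + sqrt(2), 2 - sqrt(2))),
               "Norm")
  expect_equal(as.character(call_status(2 + sqrt(2) + 1e-12, 2 + sqrt(2),
                                        2 - sqrt(2))), "Up")
  expect_equal(as.character(call_status(2 - sqrt(2) - 1e-12, 2 + sqrt(2),
                                        2 - sqrt(2))), "Down")
  expect_error(call_status(1, 0, 1), ">=")
})

test_that("PEEP separates clearly shifted High donors from controls", {
  labels <- make_labels(6, 8, 4)
  # noise-free: controls alternate at -0.5/+0.5 (all inside mean +/- SD),
  # High donors sit far above the upper cutoff
  control_ids <- labels$donor_id[labels$label != "High"]
  level_of <- setNames(c(rep(3, 6), rep(c(-0.5, 0.5), 6)), labels$donor_id)
  expr <- tidyr::crossing(donor_id = labels$donor_id,
                          gene = c("G1", "G2")) |>
    dplyr::mutate(log2_level = unname(level_of[donor_id]))
  peep <- build_peep(expr, fit_control_stats(expr, control_ids))
  high <- peep$status[!peep$donor_id %in% control_ids]
  ctrl <- peep$status[peep$donor_id %in% control_ids]
  expect_true(all(high == "Up"))
  expect_true(all(ctrl == "Norm"))

  # degenerate inputs
  empty <- build_peep(expr[0, ], fit_control_stats(expr, control_ids))
  expect_equal(nrow(empty), 0)
  cs <- fit_control_stats(expr, control_ids)
  at_mean <- dplyr::mutate(
    expr, log2_level = cs$m_ctrl[match(gene, cs$gene)]
  )
  expect_true(all(build_peep(at_mean, cs)$status == "Norm"))
  expect_error(
    build_peep(dplyr::mutate(expr, gene = paste0(gene, "_x")), cs),
    "No control stats"
  )
})

test_that("group summaries reproduce printed-precision percentages", {
  # 14 of 17 High donors perturbed -> 82.4%; 13 of 17 Up -> 76.5%
  counts <- list(High = c(17, 14, 0), Ave = c(63, 8, 6), Low = c(14, 2, 2))
  peep <- make_peep_gene("NELL2", counts)
  labels <- labels_for_peep(counts)
  gs <- summarize_groups(peep, labels)
  get <- function(grp, col) gs[[col]][gs$group == grp]
  expect_equal(get("High", "pct_perturbed"), 82.4)
  expect_equal(get("High", "pct_up"), 82.4)
  expect_equal(get("High", "pct_down"), 0.0)
  expect_equal(get("Ave", "pct_perturbed"), 22.2)
  expect_equal(get("Low", "pct_perturbed"), 28.6)
  expect_equal(get("Ave+Low", "pct_perturbed"), 23.4)
  expect_equal(get("Total", "pct_perturbed"), 34.0)

  up13 <- make_peep_gene("ITM2C", list(High = c(17, 13, 0)))
  gs13 <- summarize_groups(up13, labels_for_peep(list(High = c(17, 13, 0))))
  expect_equal(gs13$pct_up[gs13$group == "High"], 76.5)

  expect_error(summarize_groups(peep, labels[-1, ]), "Unlabelled")
})

test_that("summary rows are internally additive for any status matrix", {
  set.seed(41)
  labels <- make_labels(9, 21, 12)
  peep <- tidyr::crossing(donor_id = labels$donor_id,
                          gene = c("G1", "G2", "G3")) |>
    dplyr::mutate(status = sample(c("Up", "Norm", "Down"), dplyr::n(),
                                  replace = TRUE))
  gs <- summarize_groups(peep, labels)
  expect_true(all(gs$n_perturbed == gs$n_up + gs$n_down))
  expect_true(all(gs$n_perturbed <= gs$n_group))
  for (g in unique(gs$gene)) {
    sub <- gs[gs$gene == g, ]
    row <- function(grp) sub[sub$group == grp,
                             c("n_group", "n_up", "n_down", "n_perturbed")]
    expect_equal(row("Ave+Low"), row("Ave") + row("Low"),
                 ignore_attr = TRUE)
    expect_equal(row("Total"), row("High") + row("Ave") + row("Low"),
                 ignore_attr = TRUE)
  }
})

test_that("null perturbation rate approaches 2 * (1 - pnorm(1))", {
  n <- 10000
  labels <- make_labels(0, n, 0)
  specs <- tibble::tibble(gene = "G1", baseline_log2 = 0,
                          high_shift_log2 = 0)
  expr <- simulate_expression(labels, specs, noise_sd = 1, seed = 47) |>
    dplyr::rename(log2_level = true_log2)
  peep <- build_peep(expr, fit_control_stats(expr, labels$donor_id))
  rate <- mean(peep$status != "Norm")
  expect_lt(abs(rate - 2 * (1 - pnorm(1))), 0.01) # ~2 Monte-Carlo SE
})

test_that("statuses are invariant to shifting one gene by a constant", {
  labels <- make_labels(5, 10, 5)
  expr <- simulate_expression(labels, default_gene_panel(),
                              noise_sd = 0.5, seed = 53) |>
    dplyr::rename(log2_level = true_log2)
  controls <- labels$donor_id[labels$label != "High"]
  p1 <- build_peep(expr, fit_control_stats(expr, controls))
  shifted <- dplyr::mutate(
    expr, log2_level = log2_level + 5 * (gene == "NELL2")
  )
  p2 <- build_peep(shifted, fit_control_stats(shifted, controls))
  expect_identical(p1$status, p2$status)
})
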