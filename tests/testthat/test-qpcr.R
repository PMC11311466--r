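test_that("standard curves fit and invert exactly on noise-free points", {
  two <- fit_standard_curve(
    tibble::tibble(quantity = c(1, 10), ct = c(30, 26.68))
  )
  expect_equal(two$slope, -3.32, tolerance = 1e-9)
  expect_equal(two$intercept, 30, tolerance = 1e-9)

  # exact recovery of a known line from a dilution series
  truth <- list(slope = -3.45, intercept = 31.2)
  pts <- tibble::tibble(
    quantity = 10^seq(-2, 3),
    ct = truth$intercept + truth$slope * seq(-2, 3)
  )
  fit <- fit_standard_curve(pts)
  expect_equal(fit$slope, truth$slope, tolerance = 1e-9)
  expect_equal(fit$intercept, truth$intercept, tolerance = 1e-9)

  # inverse mapping: intercept -> 1, one slope step -> one decade,
  # and a full round-trip over the dilution series
  expect_equal(ct_to_quantity(fit$intercept, fit), 1, tolerance = 1e-12)
  expect_equal(ct_to_quantity(fit$intercept + fit$slope, fit), 10,
               tolerance = 1e-12)
  expect_equal(ct_to_quantity(pts$ct, fit), pts$quantity, tolerance = 1e-9)

  expect_error(
    fit_standard_curve(tibble::tibble(quantity = c(5, 5), ct = c(30, 31))),
    "distinct"
  )
  expect_error(
    fit_standard_curve(tibble::tibble(quantity = c(0, 10), ct = c(30, 26))),
    "positive"
  )
  rising <- fit_standard_curve(
    tibble::tibble(quantity = c(1, 10), ct = c(26, 30))
  )
  expect_error(ct_to_quantity(28, rising), "negative")
})

test_that("normalization factors are control ratios with per-gene mean one", {
  single <- normalization_factors(
    tibble::tibble(plate_id = "P1", gene = "G1", Qc = 7, Gc = 3)
  )
  expect_equal(single$NFq, 1)
  expect_equal(single$NFg, 1)

  two <- normalization_factors(
    tibble::tibble(plate_id = c("P1", "P2"), gene = "G1",
                   Qc = c(2, 4), Gc = c(1, 1))
  )
  expect_equal(two$NFq, c(2 / 3, 4 / 3), tolerance = 1e-12)

  set.seed(17)
  many <- tidyr::crossing(plate_id = sprintf("P%d", 1:6),
                          gene = c("G1", "G2", "G3")) |>
    dplyr::mutate(Qc = rlnorm(dplyr::n()), Gc = rlnorm(dplyr::n()))
  nf <- normalization_factors(many)
  means <- nf |>
    dplyr::group_by(gene) |>
    dplyr::summarise(mq = mean(NFq), mg = mean(NFg))
  expect_true(all(abs(means$mq - 1) < 1e-9))
  expect_true(all(abs(means$mg - 1) < 1e-9))

  expect_error(
    normalization_factors(
      tibble::tibble(plate_id = c("P1", "P1"), gene = "G1",
                     Qc = c(2, 3), Gc = c(1, 1))
    ),
    "Conflicting"
  )
  expect_error(
    normalization_factors(
      tibble::tibble(plate_id = "P1", gene = "G1", Qc = 0, Gc = 1)
    ),
    "positive"
  )
})

test_that("expression levels follow the ratio normalization", {
  one_plate <- tibble::tibble(
    plate_id = "P1", donor_id = c("d1", "d2"), gene = "G1",
    Qs = c(5, 8), Gs = c(5, 2), Qc = 3, Gc = 4
  )
  lev <- expression_levels(one_plate)
  expect_equal(lev$level, c(1, 4))

  expect_error(
    expression_levels(dplyr::mutate(one_plate, Qs = c(-1, 8))),
    "Non-positive"
  )
  expect_error(
    expression_levels(dplyr::bind_rows(one_plate, one_plate[1, ])),
    "Duplicate"
  )
  # a plate x gene in the sample table without a control factor is rejected
  nf_partial <- normalization_factors(one_plate)[0, ]
  expect_error(expression_levels(one_plate, factors = nf_partial),
               "Missing plate control")
})

test_that("multiplicative plate effects cancel exactly", {
  labels <- make_labels(4, 6, 4)
  expr <- simulate_expression(labels, default_gene_panel(), noise_sd = 0.4,
                              seed = 23)
  plates <- emit_plate_data(expr, n_plates = 3, plate_factor_sd = 0.5,
                            seed = 24)
  base_levels <- expression_levels(plates)

  # rescale one plate: samples and control alike, each channel by its own
  # arbitrary positive constant. The plate's control enters the cross-plate
  # average, so levels are preserved up to one common factor per gene:
  # donor-to-donor ratios (and hence Log2 profiles up to a per-gene shift,
  # which the PEEP layer is invariant to) never change.
  rescaled <- plates |>
    dplyr::mutate(
      Qs = ifelse(plate_id == "P02", Qs * 7.3, Qs),
      Qc = ifelse(plate_id == "P02", Qc * 7.3, Qc),
      Gs = ifelse(plate_id == "P02", Gs * 0.41, Gs),
      Gc = ifelse(plate_id == "P02", Gc * 0.41, Gc)
    )
  ratio <- dplyr::inner_join(expression_levels(rescaled), base_levels,
                             by = c("donor_id", "gene"),
                             suffix = c("_new", "_old")) |>
    dplyr::mutate(r = level_new / level_old) |>
    dplyr::group_by(gene) |>
    dplyr::summarise(spread = diff(range(r)))
  expect_true(all(ratio$spread < 1e-12))

  # and the perturbation calls downstream are bitwise identical
  controls <- labels$donor_id[labels$label != "High"]
  call_of <- function(p) {
    e <- normalize_plates(p)
    build_peep(e, fit_control_stats(e, controls))$status
  }
  expect_identical(call_of(rescaled), call_of(plates))

  # the control channel is scale-free: doubling every Qc changes nothing
  doubled <- dplyr::mutate(plates, Qc = Qc * 2)
  expect_equal(expression_levels(doubled)$level, base_levels$level,
               tolerance = 1e-12)
})

test_that("Log2 assembly enforces sign convention and positivity", {
  lv <- tibble::tibble(
    donor_id = c("d1", "d2", "d3"), gene = "G1", level = c(1, 4, 0.25)
  )
  out <- assemble_log2_matrix(lv)
  expect_equal(out$log2_level, c(0, 2, -2))

  expect_error(
    assemble_log2_matrix(
      tibble::tibble(donor_id = "dX", gene = "GY", level = 0)
    ),
    "dX/GY"
  )
  expect_error(assemble_log2_matrix(dplyr::bind_rows(lv, lv[1, ])),
               "Duplicate")

  # wide/long pivots are inverse of each other
  expr <- tidyr::crossing(donor_id = c("d1", "d2"),
                          gene = c("G1", "G2")) |>
    dplyr::mutate(log2_level = c(1, 2, 3, 4))
  expect_equal(expr_to_long(expr_to_wide(expr)), expr)
})
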