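#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a release_stats object
#'
#' @param x A `release_stats` object.
#' @param ... Unused.
#' @return Tibble with one row per estimated quantity (`term`, `estimate`).
#' @export
tidy.release_stats <- function(x, ...) {
  tibble(
    term = c("mean_pct", "sd_pct", "lower_cutoff_pct", "upper_cutoff_pct"),
    estimate = c(x$mean_pct, x$sd_pct, x$lower_cutoff_pct,
                 x$upper_cutoff_pct)
  )
}

#' Glance at a release_stats object
#'
#' @param x A `release_stats` object.
#' @param ... Unused.
#' @return One-row tibble of the cohort statistics and cutoffs.
#' @export
glance.release_stats <- function(x, ...) {
  tibble(
    mean_pct = x$mean_pct, sd_pct = x$sd_pct,
    lower_cutoff_pct = x$lower_cutoff_pct,
    upper_cutoff_pct = x$upper_cutoff_pct, n = x$n
  )
}

#' Tidy a standard_curve object
#'
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @return Tibble with `term` (`intercept`, `slope`) and `estimate`.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' Glance at a standard_curve object
#'
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @return One-row tibble with `gene`, `slope`, `intercept`, amplification
#'   `efficiency` (10^(-1/slope) - 1) and `n`.
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(
    gene = if (is.null(x$gene)) NA_character_ else x$gene,
    slope = x$slope, intercept = x$intercept,
    efficiency = 10^(-1 / x$slope) - 1, n = x$n
  )
}
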