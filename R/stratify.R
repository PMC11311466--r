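#' Fit cohort histamine-release statistics and responder cutoffs
#'
#' Computes the sample mean and sample standard deviation (n - 1 denominator)
#' of the percent histamine release across a donor cohort, and derives the two
#' responder cutoffs at mean - SD and mean + SD. Donors releasing above the
#' upper cutoff are High responders, below the lower cutoff Low responders,
#' and everyone else (boundaries included) Average.
#'
#' @param data A data frame of donors, one row per donor.
#' @param release Column holding percent histamine release (tidy-eval);
#'   default `release_pct`.
#' @return An object of class `release_stats`: a list with `mean_pct`,
#'   `sd_pct`, `lower_cutoff_pct`, `upper_cutoff_pct` and `n`. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' donors <- tibble::tibble(release_pct = c(5, 20, 35, 60))
#' fit_release_stats(donors)
#' @export
fit_release_stats <- function(data, release = release_pct) {
  check_columns(data, character(), "data")
  values <- eval_tidy(enquo(release), data)
  if (!is.numeric(values)) {
    abort("The release column must be numeric.")
  }
  if (anyNA(values)) {
    abort("Release values must not contain missing values.")
  }
  if (length(values) < 2) {
    abort("At least 2 release values are required to estimate an SD.")
  }
  m <- mean(values)
  s <- sd(values)
  structure(
    list(
      mean_pct = m,
      sd_pct = s,
      lower_cutoff_pct = m - s,
      upper_cutoff_pct = m + s,
      n = length(values)
    ),
    class = "release_stats"
  )
}

#' @export
print.release_stats <- function(x, ...) {
  cat(sprintf(
    "Histamine release: mean %.2f%%, SD %.2f%% (n = %d)\n", x$mean_pct,
    x$sd_pct, x$n
  ))
  cat(sprintf(
    "Responder cutoffs: Low < %.2f%% <= Ave <= %.2f%% < High\n",
    x$lower_cutoff_pct, x$upper_cutoff_pct
  ))
  invisible(x)
}

#' Classify release values into responder groups
#'
#' Applies the mean +/- 1 SD rule: release strictly above the upper cutoff is
#' "High", strictly below the lower cutoff is "Low", and anything in between
#' (cutoffs included) is "Ave". The stats may have been fitted on a different
#' cohort than the one being classified, which is how external samples (e.g.
#' allergic-patient cultures) are referenced against a normal-donor baseline.
#'
#' @param release_pct Numeric vector of percent release values.
#' @param stats A `release_stats` object from [fit_release_stats()].
#' @return Factor with levels `High`, `Ave`, `Low`.
#' @export
classify_responder <- function(release_pct, stats) {
  if (!inherits(stats, "release_stats")) {
    abort("`stats` must be a `release_stats` object from fit_release_stats().")
  }
  if (anyNA(release_pct)) {
    abort("Release values must not contain missing values.")
  }
  out <- ifelse(
    release_pct > stats$upper_cutoff_pct, "High",
    ifelse(release_pct < stats$lower_cutoff_pct, "Low", "Ave")
  )
  factor(out, levels = RESPONDER_LEVELS)
}

#' Label every donor in a cohort by responder group
#'
#' Fits release statistics on the cohort (unless precomputed stats are
#' supplied) and adds a `label` column. The fitted `release_stats` object is
#' attached as the `"release_stats"` attribute of the result.
#'
#' @param data Data frame with one row per donor and a release column.
#' @param stats Optional precomputed `release_stats`; when supplied the cohort
#'   is classified against that external baseline instead of refitting.
#' @param release Column holding percent release (tidy-eval); default
#'   `release_pct`.
#' @return The input tibble with an added `label` factor column; group counts
#'   are available via `dplyr::count(result, label)`.
#' @examples
#' donors <- tibble::tibble(
#'   donor_id = c("a", "b", "c", "d"),
#'   release_pct = c(5, 20, 35, 60)
#' )
#' stratify(donors) |> dplyr::count(label)
#' @export
stratify <- function(data, stats = NULL, release = release_pct) {
  release_quo <- enquo(release)
  if (is.null(stats)) {
    stats <- fit_release_stats(data, release = !!release_quo)
  }
  values <- eval_tidy(release_quo, data)
  out <- as_tibble(data)
  out$label <- classify_responder(values, stats)
  attr(out, "release_stats") <- stats
  out
}
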