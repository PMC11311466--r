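# Internal helpers shared across modules.

# Round half-up to `digits` decimals. base::round() rounds half to even;
# tabulated percentages here follow the half-up convention (14/17 -> 82.4).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stop unless `df` has all of `cols`; `what` names the input in the message.
check_columns <- function(df, cols, what = "input") {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", what))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column%s: %s.",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_positive_scalar <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (allow_zero) x >= 0 else x > 0)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single %s number.", name,
      if (allow_zero) "non-negative" else "positive"
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    x == trunc(x) && x >= min
  if (!ok) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Optionally seed the RNG; NULL leaves the current stream untouched.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    check_count(seed, "seed", min = -.Machine$integer.max)
    set.seed(seed)
  }
  invisible(seed)
}

# Coerce labels to the canonical responder factor, rejecting unknown values.
as_responder_factor <- function(label, what = "label") {
  label <- as.character(label)
  bad <- setdiff(unique(label[!is.na(label)]), RESPONDER_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown responder label%s in `%s`: %s (expected %s).",
      if (length(bad) > 1) "s" else "", what,
      paste(bad, collapse = ", "), paste(RESPONDER_LEVELS, collapse = ", ")
    ))
  }
  factor(label, levels = RESPONDER_LEVELS)
}

as_status_factor <- function(status, what = "status") {
  status <- as.character(status)
  bad <- setdiff(unique(status[!is.na(status)]), STATUS_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown perturbation status%s in `%s`: %s (expected %s).",
      if (length(bad) > 1) "es" else "", what,
      paste(bad, collapse = ", "), paste(STATUS_LEVELS, collapse = ", ")
    ))
  }
  factor(status, levels = STATUS_LEVELS)
}
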