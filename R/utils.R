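# Internal helpers shared across modules.

# Half-up rounding (round() is banker's rounding; printed percentages and the
# m rule both follow the conventional half-up rule).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Completeness percentage
#'
#' Percentage of complete records, rounded half-up to the nearest integer, the
#' convention used when reporting follow-up completeness in trial reports.
#'
#' @param n_complete Number of participants with complete data.
#' @param n_total Number of participants.
#' @return Integer percentage (numeric scalar or vector).
#' @examples
#' completeness_pct(186, 250)
#' @export
completeness_pct <- function(n_complete, n_total) {
  stopifnot(all(n_total > 0), all(n_complete >= 0), all(n_complete <= n_total))
  round_half_up(100 * n_complete / n_total)
}

# Deterministic sub-seed derivation: one master seed fans out into independent
# streams (participants, waves, imputations, bootstrap replicates) so that
# subsetting one unit never reshuffles another's draws. Mixing is a small
# multiplicative hash kept strictly below 2^31 - 1.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + as.numeric(p) %% 2147483647 + 1) %% 2147483629
  }
  as.integer(h %% 2147483587 + 1)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %s.", name, format(min)))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  if (x > max) abort(sprintf("`%s` must be <= %s.", name, format(max)))
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  check_number(x, name, min = min)
  if (x != as.integer(x)) abort(sprintf("`%s` must be a whole number.", name))
  invisible(as.integer(x))
}

# Months -> days from randomisation, used for medication windows.
month_days <- function(months) round(months * 365.25 / 12)
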