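#' EQ-5D-3L utility tariff
#'
#' A tariff (value set) converts a five-digit EQ-5D-3L profile into a
#' population-preference utility. Scoring follows the additive decrement
#' form used by the UK time-trade-off value set: full health (11111) scores
#' exactly 1; any departure from full health subtracts a constant, then a
#' decrement for each dimension at level 2 or 3, then an extra decrement if
#' any dimension is at level 3.
#'
#' @param constant Decrement applied once for any state other than full
#'   health.
#' @param decrements 5 x 2 numeric matrix of per-dimension decrements, rows
#'   named `mobility`, `self_care`, `usual_activities`, `pain_discomfort`,
#'   `anxiety_depression`, columns `level2` and `level3`.
#' @param any_level3 Extra decrement applied once if any dimension is at
#'   level 3 (the "N3" term).
#' @param label Human-readable name of the value set.
#' @return An object of class `eq5d_tariff`.
#' @seealso [uk_eq5d_tariff()] for the packaged UK coefficient set,
#'   [eq5d_utility()] to score states.
#' @export
eq5d_tariff <- function(constant, decrements, any_level3, label = "custom") {
  dims <- eq5d_dimensions()
  check_number(constant, "constant", min = 0)
  check_number(any_level3, "any_level3", min = 0)
  decrements <- as.matrix(decrements)
  if (!all(dim(decrements) == c(5L, 2L))) {
    abort("`decrements` must be a 5 x 2 matrix (dimensions x levels 2-3).")
  }
  if (is.null(rownames(decrements))) rownames(decrements) <- dims
  if (is.null(colnames(decrements))) colnames(decrements) <- c("level2", "level3")
  if (!identical(rownames(decrements), dims)) {
    abort("`decrements` rows must be the five EQ-5D dimensions in order.")
  }
  if (any(decrements < 0)) abort("All tariff decrements must be >= 0.")
  structure(
    list(constant = constant, decrements = decrements,
         any_level3 = any_level3, label = label),
    class = "eq5d_tariff"
  )
}

eq5d_dimensions <- function() {
  c("mobility", "self_care", "usual_activities", "pain_discomfort",
    "anxiety_depression")
}

#' UK EQ-5D-3L value set
#'
#' The UK general-population time-trade-off coefficient set: constant 0.081,
#' per-dimension level-2/level-3 decrements, and an extra 0.269 whenever any
#' dimension is at level 3. Under this set the worst state 33333 scores
#' -0.594.
#'
#' @return An `eq5d_tariff`.
#' @examples
#' eq5d_utility("33333", uk_eq5d_tariff())
#' @export
uk_eq5d_tariff <- function() {
  dec <- matrix(
    c(0.069, 0.314,
      0.104, 0.214,
      0.036, 0.094,
      0.123, 0.386,
      0.071, 0.236),
    nrow = 5, byrow = TRUE,
    dimnames = list(eq5d_dimensions(), c("level2", "level3"))
  )
  eq5d_tariff(constant = 0.081, decrements = dec, any_level3 = 0.269,
              label = "UK TTO value set")
}

#' @export
print.eq5d_tariff <- function(x, ...) {
  cat("<eq5d_tariff>", x$label, "\n")
  cat("  constant:", x$constant, " any-level-3:", x$any_level3, "\n")
  print(x$decrements)
  invisible(x)
}

# Parse states given as "21232" strings (NA-safe) into a 5-column integer
# matrix; also accepts a numeric matrix/data frame of five level columns.
parse_eq5d_states <- function(states) {
  if (is.numeric(states) && is.null(dim(states))) {
    # five-digit profiles that lost their character type (e.g. CSV round
    # trips reading "21232" as 21232)
    states <- ifelse(is.na(states), NA_character_,
                     format(states, scientific = FALSE, trim = TRUE))
  }
  if (is.character(states)) {
    ok <- is.na(states) | grepl("^[123]{5}$", states)
    if (!all(ok)) {
      abort(paste0("Invalid EQ-5D-3L state(s): ",
                   paste(unique(states[!ok]), collapse = ", "),
                   " (need five digits, each in 1-3)."))
    }
    m <- matrix(NA_integer_, nrow = length(states), ncol = 5)
    idx <- !is.na(states)
    if (any(idx)) {
      m[idx, ] <- t(vapply(strsplit(states[idx], ""),
                           function(d) as.integer(d), integer(5)))
    }
  } else {
    m <- as.matrix(states)
    if (ncol(m) != 5) abort("EQ-5D states need five level columns.")
    storage.mode(m) <- "integer"
    vals <- m[!is.na(m)]
    if (any(!vals %in% 1:3)) abort("EQ-5D levels must be in {1, 2, 3}.")
    if (any(!complete.cases(m) & rowSums(!is.na(m)) > 0)) {
      abort("EQ-5D states must have all five levels present (or all NA).")
    }
  }
  colnames(m) <- eq5d_dimensions()
  m
}

#' Score EQ-5D-3L states to utilities
#'
#' Vectorised tariff scoring. Full health maps to exactly 1; all other states
#' subtract the tariff's constant, dimension decrements and any-level-3
#' decrement, so utilities can be negative (states valued worse than dead).
#'
#' @param states Character vector of five-digit states ("21232"), or a
#'   matrix/data frame with five level columns. `NA` states return `NA`.
#' @param tariff An [eq5d_tariff()]; defaults to the UK set.
#' @return Numeric vector of utilities.
#' @examples
#' eq5d_utility(c("11111", "21111", "33333"))
#' @export
eq5d_utility <- function(states, tariff = uk_eq5d_tariff()) {
  stopifnot(inherits(tariff, "eq5d_tariff"))
  m <- parse_eq5d_states(states)
  u <- rep(NA_real_, nrow(m))
  idx <- complete.cases(m)
  if (!any(idx)) return(u)
  mm <- m[idx, , drop = FALSE]
  dec2 <- tariff$decrements[, "level2"]
  dec3 <- tariff$decrements[, "level3"]
  dim_dec <- (mm == 2L) %*% dec2 + (mm == 3L) %*% dec3
  not_full <- rowSums(mm > 1L) > 0L
  any3 <- rowSums(mm == 3L) > 0L
  u[idx] <- 1 - not_full * tariff$constant - as.numeric(dim_dec) -
    any3 * tariff$any_level3
  u
}

#' Enumerate all 243 EQ-5D-3L states under a tariff
#'
#' @param tariff An [eq5d_tariff()].
#' @return A tibble with columns `state` (five-digit string), the five level
#'   columns, and `utility`, sorted by decreasing utility.
#' @export
eq5d_states <- function(tariff = uk_eq5d_tariff()) {
  grid <- expand.grid(
    mobility = 1:3, self_care = 1:3, usual_activities = 1:3,
    pain_discomfort = 1:3, anxiety_depression = 1:3,
    KEEP.OUT.ATTRS = FALSE
  )
  grid <- grid[, eq5d_dimensions()]
  state <- apply(grid, 1, paste0, collapse = "")
  out <- tibble::as_tibble(grid)
  out$state <- state
  out$utility <- eq5d_utility(as.matrix(grid), tariff)
  dplyr::arrange(out[, c("state", eq5d_dimensions(), "utility")],
                 dplyr::desc(.data$utility), .data$state)
}

#' Nearest attainable EQ-5D-3L state for a target utility
#'
#' Maps continuous utilities onto the tariff's attainable grid, used by the
#' synthetic-trial generator so that the pipeline consumes genuine five-digit
#' profiles. Ties are broken towards the better (higher-utility) state, then
#' by state string, so the mapping is deterministic.
#'
#' @param utility Numeric vector of target utilities.
#' @param tariff An [eq5d_tariff()].
#' @return Character vector of five-digit states (`NA` in, `NA` out).
#' @export
nearest_eq5d_state <- function(utility, tariff = uk_eq5d_tariff()) {
  grid <- eq5d_states(tariff) # already sorted: utility desc, then state
  nearest_state_from_grid(utility, grid)
}

# Workhorse for nearest_eq5d_state() with a precomputed state grid, so bulk
# callers (the trial generator) pay for the enumeration once.
nearest_state_from_grid <- function(utility, grid) {
  out <- rep(NA_character_, length(utility))
  idx <- which(!is.na(utility))
  if (length(idx)) {
    pick <- vapply(utility[idx], function(u) {
      which.min(abs(grid$utility - u)) # first hit = better state on ties
    }, integer(1))
    out[idx] <- grid$state[pick]
  }
  out
}

#' Quality-adjusted life-years by the area-under-the-curve method
#'
#' Integrates a utility trajectory by the trapezoidal rule (linear
#' interpolation between measurement times) and converts months to years.
#' No extrapolation: the horizon must coincide with a measurement time.
#'
#' @param times Measurement times in months, strictly increasing, first 0.
#' @param utilities Utilities at `times`. `NA` anywhere inside the horizon
#'   propagates to an `NA` QALY (missing outcomes are the imputation stage's
#'   job, never carried forward here).
#' @param horizon_months Analysis horizon in months; must be one of `times`.
#' @return QALYs (utility-years) as a single number.
#' @examples
#' qaly_auc(c(0, 7, 12), c(0.5, 0.5, 0.7), 12)
#' @export
qaly_auc <- function(times, utilities, horizon_months = max(times)) {
  if (length(times) != length(utilities)) {
    abort("`times` and `utilities` must have equal length.")
  }
  if (length(times) < 2L || times[1] != 0 || any(diff(times) <= 0)) {
    abort("`times` must be strictly increasing and start at 0.")
  }
  check_number(horizon_months, "horizon_months", min = 0, strict_min = TRUE)
  if (horizon_months > max(times) + 1e-9) {
    abort("`horizon_months` lies beyond the last measurement; no extrapolation.")
  }
  hit <- which(abs(times - horizon_months) < 1e-9)
  if (!length(hit)) {
    abort("`horizon_months` must coincide with a measurement time.")
  }
  keep <- seq_len(hit[1])
  t <- times[keep]; u <- utilities[keep]
  sum(diff(t) * (u[-1] + u[-length(u)]) / 2) / 12
}
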