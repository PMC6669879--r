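#' Unit cost table
#'
#' Validates a service-code to unit-cost lookup. Costs are GBP per contact
#' (or per day for bed days) tagged with a price year; an optional uprating
#' table of multipliers re-bases costs collected in other price years.
#'
#' @param costs Data frame with columns `service_code`, `cost`, and
#'   optionally `description`, `unit`, `price_year`.
#' @param uprating Optional data frame (`price_year`, `multiplier`) applied
#'   to entries whose price year differs from the base year.
#' @param base_year Price year the analysis reports in.
#' @return A tibble of class `unit_cost_table`.
#' @export
unit_cost_table <- function(costs, uprating = NULL, base_year = "2014-2015") {
  costs <- tibble::as_tibble(costs)
  if (!all(c("service_code", "cost") %in% names(costs))) {
    abort("`costs` needs `service_code` and `cost` columns.")
  }
  if (any(!is.finite(costs$cost)) || any(costs$cost < 0)) {
    abort("All unit costs must be finite and >= 0.")
  }
  if (anyDuplicated(costs$service_code)) {
    abort("Duplicate service codes in unit cost table.")
  }
  if (!"price_year" %in% names(costs)) costs$price_year <- base_year
  if (is.null(uprating) && any(costs$price_year != base_year)) {
    abort(paste0("Costs tagged with price year(s) other than ", base_year,
                 " need an uprating table."))
  }
  if (!is.null(uprating)) {
    uprating <- tibble::as_tibble(uprating)
    stopifnot(all(c("price_year", "multiplier") %in% names(uprating)))
    mult <- setNames(uprating$multiplier, uprating$price_year)
    needs <- costs$price_year != base_year
    if (any(needs)) {
      missing_years <- setdiff(unique(costs$price_year[needs]), names(mult))
      if (length(missing_years)) {
        abort(paste0("No uprating multiplier for price year(s): ",
                     paste(missing_years, collapse = ", ")))
      }
      costs$cost[needs] <- costs$cost[needs] * unname(mult[costs$price_year[needs]])
      costs$price_year[needs] <- base_year
    }
  }
  structure(costs, class = c("unit_cost_table", class(costs)),
            base_year = base_year)
}

#' Packaged default unit costs
#'
#' Plausible 2014-2015 GBP unit costs for the service categories the
#' synthetic generator produces. These are placeholders in the spirit of
#' national reference costs and are meant to be overridden with a local
#' table for any real analysis.
#'
#' @return A `unit_cost_table`.
#' @export
default_unit_costs <- function() {
  unit_cost_table(tibble::tribble(
    ~service_code,                    ~description,                      ~unit,        ~cost,
    "inpatient_day",                  "Psychiatric inpatient bed day",   "day",        350,
    "outpatient_visit",               "Hospital outpatient attendance",  "attendance", 135,
    "a_and_e",                        "Accident & emergency attendance", "attendance", 124,
    "gp_visit",                       "GP surgery consultation",         "contact",    38,
    "practice_nurse",                 "Practice nurse contact",          "contact",    14,
    "community_mental_health_nurse",  "Community mental health nurse",   "contact",    39,
    "psychiatrist_visit",             "Psychiatrist contact",            "contact",    150,
    "social_worker",                  "Social worker contact",           "contact",    54,
    "talking_therapy_session",        "Talking therapy session (non-trial)", "session", 52
  ))
}

#' Cost resource use against a unit cost table
#'
#' Multiplies reported contacts by unit costs and sums. Items a participant
#' left blank on an otherwise completed questionnaire are counted as zero
#' use, so absent rows simply contribute nothing; unpriced codes are an
#' error (never silently dropped).
#'
#' @param usage Data frame with `service_code` and `n` (counts), or a named
#'   numeric vector of counts.
#' @param table A [unit_cost_table()].
#' @return Total cost in GBP (scalar).
#' @examples
#' cost_services(c(gp_visit = 3, inpatient_day = 2),
#'               unit_cost_table(data.frame(
#'                 service_code = c("gp_visit", "inpatient_day"),
#'                 cost = c(38, 400))))
#' @export
cost_services <- function(usage, table) {
  stopifnot(inherits(table, "unit_cost_table"))
  if (is.numeric(usage) && !is.null(names(usage))) {
    usage <- tibble::tibble(service_code = names(usage), n = as.numeric(usage))
  }
  usage <- tibble::as_tibble(usage)
  if (nrow(usage) == 0L) return(0)
  if (!all(c("service_code", "n") %in% names(usage))) {
    abort("`usage` needs `service_code` and `n` columns.")
  }
  usage <- usage[!is.na(usage$n) & usage$n != 0, , drop = FALSE]
  if (nrow(usage) == 0L) return(0)
  if (any(usage$n < 0)) abort("Usage counts must be >= 0.")
  unpriced <- setdiff(unique(usage$service_code), table$service_code)
  if (length(unpriced)) {
    abort(paste0("Unpriced service code(s): ", paste(unpriced, collapse = ", ")))
  }
  price <- setNames(table$cost, table$service_code)
  sum(usage$n * unname(price[usage$service_code]))
}

#' Therapist cost parameters for micro-costing
#'
#' Parameters of the bottom-up intervention costing: an hourly employment
#' cost (salary plus employer on-costs and overheads), a direct:non-direct
#' time ratio that inflates contact time to cover preparation, supervision
#' and administration, session durations, and the group staffing rule
#' (one therapist for groups of up to `small_group_threshold` patients, two
#' for larger groups).
#'
#' @param hourly_employment_cost GBP per hour of therapist time.
#' @param nondirect_ratio Non-direct hours per direct hour (default 0.91,
#'   i.e. a 1:0.91 direct:non-direct ratio).
#' @param individual_session_minutes,group_session_minutes Session lengths.
#' @param therapists_small_group,therapists_large_group Staffing by size.
#' @param small_group_threshold Largest group run by a single therapist.
#' @param group_session_national_cost GBP per attended group-therapy session
#'   under the national tariff, used by the group-cost sensitivity scenario.
#' @param wage_rate National gross average wage (GBP/hour) for the human
#'   capital valuation of lost work time.
#' @return A list of class `therapist_cost_params`.
#' @export
therapist_cost_params <- function(hourly_employment_cost = 62.2,
                                  nondirect_ratio = 0.91,
                                  individual_session_minutes = 60,
                                  group_session_minutes = 150,
                                  therapists_small_group = 1L,
                                  therapists_large_group = 2L,
                                  small_group_threshold = 3L,
                                  group_session_national_cost = 14,
                                  wage_rate = 13.5) {
  check_number(hourly_employment_cost, "hourly_employment_cost", min = 0)
  check_number(nondirect_ratio, "nondirect_ratio", min = 0)
  check_number(individual_session_minutes, "individual_session_minutes",
               min = 0, strict_min = TRUE)
  check_number(group_session_minutes, "group_session_minutes",
               min = 0, strict_min = TRUE)
  check_count(therapists_small_group, "therapists_small_group", min = 1)
  check_count(therapists_large_group, "therapists_large_group", min = 1)
  check_count(small_group_threshold, "small_group_threshold", min = 1)
  check_number(group_session_national_cost, "group_session_national_cost", min = 0)
  check_number(wage_rate, "wage_rate", min = 0)
  structure(
    list(hourly_employment_cost = hourly_employment_cost,
         nondirect_ratio = nondirect_ratio,
         individual_session_minutes = individual_session_minutes,
         group_session_minutes = group_session_minutes,
         therapists_small_group = as.integer(therapists_small_group),
         therapists_large_group = as.integer(therapists_large_group),
         small_group_threshold = as.integer(small_group_threshold),
         group_session_national_cost = group_session_national_cost,
         wage_rate = wage_rate),
    class = "therapist_cost_params"
  )
}

#' Number of therapists running a group
#'
#' @param n Group size (patients).
#' @param params A [therapist_cost_params()].
#' @return Integer therapist count (vectorised over `n`).
#' @export
therapists_for_group <- function(n, params = therapist_cost_params()) {
  stopifnot(inherits(params, "therapist_cost_params"))
  ifelse(n > params$small_group_threshold,
         params$therapists_large_group, params$therapists_small_group)
}

#' Cost of one attended individual therapy session
#'
#' Direct contact time valued at the hourly employment cost, inflated by the
#' direct:non-direct ratio. Sessions not attended cost zero by construction:
#' only attended individual sessions are charged, on the assumption that
#' therapists redeploy freed time.
#'
#' @param params A [therapist_cost_params()].
#' @return GBP per attended session.
#' @examples
#' cost_individual_session(therapist_cost_params(hourly_employment_cost = 25))
#' @export
cost_individual_session <- function(params = therapist_cost_params()) {
  stopifnot(inherits(params, "therapist_cost_params"))
  params$hourly_employment_cost * (1 + params$nondirect_ratio) *
    params$individual_session_minutes / 60
}

#' Per-invitee cost of one group therapy session
#'
#' Groups are closed and run regardless of turnout, so the full session cost
#' (therapists x weighted hourly cost x duration) is allocated evenly across
#' everyone invited, whether or not they attended.
#'
#' @param n_invited Number of participants invited to the session.
#' @param n_therapists Therapists running it; default applies the group-size
#'   staffing rule to `n_invited`.
#' @param params A [therapist_cost_params()].
#' @return GBP charged to each invitee for this session.
#' @export
cost_group_session <- function(n_invited,
                               n_therapists = therapists_for_group(n_invited, params),
                               params = therapist_cost_params()) {
  stopifnot(inherits(params, "therapist_cost_params"))
  check_count(n_invited, "n_invited", min = 1)
  check_count(n_therapists, "n_therapists", min = 1)
  n_therapists * params$hourly_employment_cost * (1 + params$nondirect_ratio) *
    (params$group_session_minutes / 60) / n_invited
}

#' Medication costs over a costing window
#'
#' Each record carries a daily cost (median dose of the modal drug in its
#' category) and participant-reported start/finish dates; full adherence is
#' assumed, so cost = daily cost x days of overlap with the window. Days are
#' counted inclusively on both ends.
#'
#' @param records Data frame with `daily_cost`, `start`, `finish` (Date or
#'   numeric day offsets) and optionally `category`.
#' @param window_start,window_end Window bounds (same scale as the dates).
#' @return Total GBP over the window.
#' @export
cost_medications <- function(records, window_start, window_end) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) return(0)
  stopifnot(all(c("daily_cost", "start", "finish") %in% names(records)))
  if (any(is.na(records$daily_cost)) || any(records$daily_cost < 0)) {
    abort("Medication `daily_cost` must be present and >= 0.")
  }
  start <- as.numeric(records$start); finish <- as.numeric(records$finish)
  if (any(is.na(start)) || any(is.na(finish))) {
    abort("Medication dates must be parseable.")
  }
  if (any(finish < start)) abort("Medication `finish` precedes `start`.")
  lo <- pmax(start, as.numeric(window_start))
  hi <- pmin(finish, as.numeric(window_end))
  days <- pmax(0, hi - lo + 1)
  sum(records$daily_cost * days)
}

#' Productivity losses by the human capital approach
#'
#' Values hours absent from work plus hours worked unproductively at the
#' national gross average wage. Applies only to participants in paid
#' employment; for others the cost is `NA` (excluded — no wage is imputed).
#' Productivity costs are always reported separately from the health and
#' social care perspective.
#'
#' @param absent_hours,unproductive_hours Non-negative hours (vectorised).
#' @param wage_rate GBP per hour.
#' @param employed Logical; `FALSE` yields `NA`.
#' @return GBP (vector).
#' @export
cost_productivity <- function(absent_hours, unproductive_hours = 0,
                              wage_rate = 13.5, employed = TRUE) {
  n <- max(length(absent_hours), length(unproductive_hours), length(employed))
  absent_hours <- rep_len(absent_hours, n)
  unproductive_hours <- rep_len(unproductive_hours, n)
  employed <- rep_len(employed, n)
  bad <- !is.na(absent_hours) & absent_hours < 0 |
    !is.na(unproductive_hours) & unproductive_hours < 0
  if (any(bad)) abort("Hours must be >= 0.")
  check_number(wage_rate, "wage_rate", min = 0)
  out <- (absent_hours + unproductive_hours) * wage_rate
  out[!employed] <- NA_real_
  out
}

#' Assemble per-participant cost summaries
#'
#' Combines the cost components into the NHS/personal-social-services total
#' (services + intervention + medications). Productivity losses are carried
#' alongside but never enter `total_nhs_pss` — perspective separation is an
#' invariant, not a convention.
#'
#' @param components Data frame with numeric columns `service_cost`,
#'   `intervention_cost`, `medication_cost` and optionally
#'   `productivity_cost` (NA allowed for participants not in work).
#' @return The input as a tibble with `total_nhs_pss` appended.
#' @export
cost_summary <- function(components) {
  components <- tibble::as_tibble(components)
  need <- c("service_cost", "intervention_cost", "medication_cost")
  if (!all(need %in% names(components))) {
    abort(paste0("`components` needs columns: ", paste(need, collapse = ", ")))
  }
  if (!"productivity_cost" %in% names(components)) {
    components$productivity_cost <- NA_real_
  }
  components$total_nhs_pss <- components$service_cost +
    components$intervention_cost + components$medication_cost
  components
}
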