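#' Build the aggregate analysis table
#'
#' Reduces a participant-level trial table to the aggregates the economic
#' analysis works on: baseline covariates, per-interval other-care costs
#' (unit-costed services plus medications), the micro-costed intervention
#' cost (always observed, from therapy records), per-interval QALY
#' contributions, productivity losses, and depression scores. Masked
#' service-use blocks propagate to `NA` aggregates; imputation happens at
#' this aggregate level.
#'
#' @param trial Table from [generate_trial()]/[simulate_trial()] (or real
#'   data in the same layout).
#' @param tariff [eq5d_tariff()] used to score states.
#' @param unit_costs [unit_cost_table()].
#' @param params [therapist_cost_params()]; the default calibrates the
#'   hourly rate to the design's target intervention cost when the design
#'   attribute is present.
#' @param utility_source `"states"` scores the five-digit EQ-5D profiles
#'   (the default and the only option for real data); `"latent"` uses the
#'   generator's continuous utilities, a simulation-only path that avoids
#'   state quantisation.
#' @return Tibble, one row per participant, with interval aggregates and
#'   derived 12-/18-month outcome columns (see [finalise_analysis_table()]).
#' @export
build_analysis_table <- function(trial,
                                 tariff = uk_eq5d_tariff(),
                                 unit_costs = default_unit_costs(),
                                 params = NULL,
                                 utility_source = c("states", "latent")) {
  utility_source <- match.arg(utility_source)
  trial <- tibble::as_tibble(trial)
  design <- attr(trial, "design")
  if (is.null(params)) {
    params <- if (!is.null(design)) {
      calibrate_therapist_rate(design)
    } else {
      therapist_cost_params()
    }
  }
  codes <- intersect(synth_constants()$categories$service_code,
                     unique(sub("_m(0|7|12|18)$", "",
                                grep("_m(0|7|12|18)$", names(trial), value = TRUE))))
  unpriced <- setdiff(codes, unit_costs$service_code)
  if (length(unpriced)) {
    abort(paste0("Unpriced service code(s): ", paste(unpriced, collapse = ", ")))
  }
  price <- setNames(unit_costs$cost, unit_costs$service_code)[codes]
  ivals <- wave_intervals()

  out <- tibble::tibble(
    participant_id = trial$participant_id,
    arm = trial$arm,
    age = trial$age,
    female = trial$female,
    employed = trial$employed,
    hrsd_m0 = trial$hrsd_m0,
    hrsd_m7 = trial$hrsd_m7,
    hrsd_m12 = trial$hrsd_m12,
    hrsd_m18 = trial$hrsd_m18
  )

  # utilities at each wave
  for (lab in ivals$wave) {
    out[[paste0("u_", lab)]] <- if (utility_source == "latent") {
      trial[[paste0("u_lat_", lab)]]
    } else {
      eq5d_utility(trial[[paste0("eq5d_", lab)]], tariff)
    }
  }

  # interval QALY contributions (trapezoid pieces on the 0/7/12/18 grid)
  widths <- c(m7 = 7, m12 = 5, m18 = 6)
  prev <- c(m7 = "m0", m12 = "m7", m18 = "m12")
  for (lab in names(widths)) {
    out[[paste0("qint_", lab)]] <- widths[[lab]] *
      (out[[paste0("u_", prev[[lab]])]] + out[[paste0("u_", lab)]]) / 2 / 12
  }

  # per-interval other-care costs: services + medications; NA when the
  # service-use block is masked
  med_cats <- synth_constants()$medications$category
  have_meds <- all(paste0("med_", med_cats, "_daily") %in% names(trial))
  for (w in seq_len(nrow(ivals))) {
    lab <- ivals$wave[w]
    cnt <- as.matrix(trial[, paste0(codes, "_", lab)])
    svc <- as.numeric(cnt %*% price)
    med <- 0
    if (have_meds) {
      w_lo <- month_days(ivals$start[w]) + 1
      w_hi <- month_days(ivals$end[w])
      med <- rep(0, nrow(trial))
      for (cat in med_cats) {
        daily <- trial[[paste0("med_", cat, "_daily")]]
        s <- trial[[paste0("med_", cat, "_start")]]
        f <- trial[[paste0("med_", cat, "_finish")]]
        days <- pmax(0, pmin(f, w_hi) - pmax(s, w_lo) + 1)
        add <- ifelse(is.na(daily), 0, daily * ifelse(is.na(days), 0, days))
        med <- med + add
      }
    }
    out[[paste0("cost_", lab)]] <- svc + med

    # productivity: absenteeism and presenteeism valued at the wage rate;
    # zero for participants out of paid work (no lost production)
    ab <- trial[[paste0("absent_hours_", lab)]]
    un <- trial[[paste0("unproductive_hours_", lab)]]
    emp <- trial$employed == 1
    prod_ab <- ifelse(emp, ab * params$wage_rate, 0)
    pres <- ifelse(emp, un * params$wage_rate, 0)
    out[[paste0("prod_", lab)]] <- prod_ab
    out[[paste0("presenteeism_", lab)]] <- pres
  }
  names(out)[names(out) == "cost_m0"] <- "cost_bl"
  names(out)[names(out) == "prod_m0"] <- "prod_bl"
  names(out)[names(out) == "presenteeism_m0"] <- "presenteeism_bl"

  # micro-costed intervention (therapy records: always observed)
  ind_cost <- trial$n_individual_attended * cost_individual_session(params)
  per_sess <- ifelse(
    is.na(trial$group_size), 0,
    therapists_for_group(trial$group_size, params) *
      params$hourly_employment_cost * (1 + params$nondirect_ratio) *
      (params$group_session_minutes / 60) / trial$group_size
  )
  grp_cost <- ifelse(is.na(trial$group_size), 0,
                     trial$n_group_sessions * per_sess)
  out$int_individual_cost <- ind_cost
  out$int_group_cost <- grp_cost
  out$intervention_cost <- ind_cost + grp_cost
  out$n_group_attended <- trial$n_group_attended
  out$n_group_sessions <- trial$n_group_sessions

  out <- finalise_analysis_table(out)
  attr(out, "design") <- design
  attr(out, "params") <- params
  out
}

#' Recompute derived outcome columns
#'
#' Derived columns (12-/18-month cost and QALY totals, depression change
#' scores) are functions of the interval aggregates, so they are recomputed
#' here — once when the table is built and again after each imputed copy is
#' completed.
#'
#' @param tab Analysis table (possibly with imputed interval aggregates).
#' @return The table with derived columns refreshed.
#' @export
finalise_analysis_table <- function(tab) {
  tab$cost_other_12 <- tab$cost_m7 + tab$cost_m12
  tab$cost_other_18 <- tab$cost_other_12 + tab$cost_m18
  tab$total_cost_12 <- tab$cost_other_12 + tab$intervention_cost
  tab$total_cost_18 <- tab$cost_other_18 + tab$intervention_cost
  tab$prod_12 <- tab$prod_m7 + tab$prod_m12
  tab$prod_18 <- tab$prod_12 + tab$prod_m18
  tab$qaly_12 <- tab$qint_m7 + tab$qint_m12
  tab$qaly_18 <- tab$qaly_12 + tab$qint_m18
  if (all(c("hrsd_m12", "hrsd_m18") %in% names(tab))) {
    tab$hrsd_change_12 <- tab$hrsd_m0 - tab$hrsd_m12
    tab$hrsd_change_18 <- tab$hrsd_m0 - tab$hrsd_m18
  }
  # societal perspective: NHS/PSS total plus absenteeism costs
  tab$societal_cost_12 <- tab$total_cost_12 + tab$prod_12
  tab$societal_cost_18 <- tab$total_cost_18 + tab$prod_18
  tab
}

# Interval aggregates imputation operates on.
imputable_variables <- function(tab) {
  cand <- c("cost_m7", "cost_m12", "cost_m18",
            "qint_m7", "qint_m12", "qint_m18",
            "prod_m7", "prod_m12", "prod_m18",
            "presenteeism_m7", "presenteeism_m12", "presenteeism_m18",
            "hrsd_m7", "hrsd_m12", "hrsd_m18")
  cand[vapply(cand, function(v) v %in% names(tab) && anyNA(tab[[v]]),
              logical(1))]
}

# Columns finalise_analysis_table() recomputes, plus the follow-up
# utilities (inputs to the interval QALYs, which are imputed directly).
derived_columns <- function() {
  c("u_m7", "u_m12", "u_m18",
    "cost_other_12", "cost_other_18", "total_cost_12", "total_cost_18",
    "prod_12", "prod_18", "qaly_12", "qaly_18",
    "hrsd_change_12", "hrsd_change_18",
    "societal_cost_12", "societal_cost_18")
}

#' Fraction of participants with incomplete 12-month service-use data
#'
#' The denominator of the m-selection rule: a participant is incomplete if
#' either 0-7 or 7-12 month interval cost is unobserved.
#'
#' @param tab Analysis table.
#' @return Proportion in `[0, 1]`.
#' @export
fraction_incomplete <- function(tab) {
  mean(is.na(tab$cost_m7) | is.na(tab$cost_m12))
}

#' Substitute the group-session component of the intervention cost
#'
#' Replaces the micro-costed closed-group allocation with a flat per-session
#' rate — either per attended session (the national-tariff basis used in the
#' group-cost sensitivity scenario) or per scheduled (invited) session.
#' Derived totals are recomputed.
#'
#' @param tab Analysis table.
#' @param per_session GBP per session.
#' @param basis `"attended"` or `"invited"`.
#' @return The table with `int_group_cost`, `intervention_cost` and derived
#'   totals replaced.
#' @export
substitute_group_cost <- function(tab, per_session = 14,
                                  basis = c("attended", "invited")) {
  basis <- match.arg(basis)
  check_number(per_session, "per_session", min = 0)
  n_sess <- if (basis == "attended") tab$n_group_attended else tab$n_group_sessions
  tab$int_group_cost <- n_sess * per_session
  tab$intervention_cost <- tab$int_individual_cost + tab$int_group_cost
  finalise_analysis_table(tab)
}

#' Disaggregated per-participant cost breakdown
#'
#' Category-level costs over a stated window, the complete-case basis of a
#' disaggregated cost table: hospital care, community care, other talking
#' therapy, medications, the intervention, the NHS/PSS total, and (reported
#' separately) productivity losses.
#'
#' @inheritParams build_analysis_table
#' @param horizon_months 12 or 18.
#' @return Tibble with one row per participant and one column per category;
#'   `NA` where the underlying blocks are masked.
#' @export
cost_breakdown <- function(trial,
                           unit_costs = default_unit_costs(),
                           params = NULL,
                           horizon_months = 12) {
  if (!horizon_months %in% c(12, 18)) abort("`horizon_months` must be 12 or 18.")
  trial <- tibble::as_tibble(trial)
  design <- attr(trial, "design")
  if (is.null(params)) {
    params <- if (!is.null(design)) calibrate_therapist_rate(design) else
      therapist_cost_params()
  }
  groups <- list(
    hospital_cost = c("inpatient_day", "outpatient_visit", "a_and_e"),
    community_cost = c("gp_visit", "practice_nurse",
                       "community_mental_health_nurse", "psychiatrist_visit",
                       "social_worker"),
    other_therapy_cost = "talking_therapy_session"
  )
  price <- setNames(unit_costs$cost, unit_costs$service_code)
  labs <- if (horizon_months == 12) c("m7", "m12") else c("m7", "m12", "m18")

  out <- tibble::tibble(
    participant_id = trial$participant_id, arm = trial$arm,
    age = trial$age, female = trial$female, hrsd_m0 = trial$hrsd_m0
  )
  for (g in names(groups)) {
    codes <- groups[[g]]
    tot <- rep(0, nrow(trial))
    for (lab in labs) {
      cnt <- as.matrix(trial[, paste0(codes, "_", lab), drop = FALSE])
      tot <- tot + as.numeric(cnt %*% price[codes])
    }
    out[[g]] <- tot
  }
  ana <- build_analysis_table(trial, unit_costs = unit_costs, params = params)
  svc <- out$hospital_cost + out$community_cost + out$other_therapy_cost
  other <- if (horizon_months == 12) ana$cost_other_12 else ana$cost_other_18
  out$medication_cost <- other - svc
  out$intervention_cost <- ana$intervention_cost
  out$total_nhs_pss <- other + ana$intervention_cost
  out$productivity_cost <- if (horizon_months == 12) ana$prod_12 else ana$prod_18
  out
}
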