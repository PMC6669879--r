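#' Simulation truth for the synthetic trial generator
#'
#' Fixes the effects and nuisance parameters the generator injects. Defaults
#' emulate a two-arm psychotherapy trial in refractory depression: a 0.032
#' QALY gain and a -£909 saving in other health/social care over 12 months
#' in the intervention arm, an intervention costing about £5000 per
#' participant, a one-point advantage on the depression rating scale, and
#' 30% of participants with incomplete follow-up service-use data, missing
#' at random given baseline severity.
#'
#' @param delta_qaly_12m True adjusted QALY difference over 0-12 months
#'   (intervention minus control), in utility-years.
#' @param delta_cost_other_12m True difference in non-intervention health and
#'   social care costs over 0-12 months, GBP. The 12-18 month interval is
#'   generated with a zero arm difference.
#' @param intervention_cost_mean Expected micro-costed intervention cost per
#'   intervention-arm participant, GBP (see [calibrate_therapist_rate()]).
#' @param delta_hrsd_12m True improvement (points, positive = better) on the
#'   depression rating scale at each follow-up wave. Integer values keep the
#'   injected effect exact under score rounding.
#' @param missing_fraction Fraction of participants whose 12-month
#'   service-use record is incomplete.
#' @param missing_mechanism `"MAR-on-baseline"` (probability depends on
#'   baseline severity) or `"MCAR"`.
#' @param utility_noise_sd SD of the occasion-level utility noise.
#' @param subject_sd SD of the participant-level random intercept on
#'   utility.
#' @param utility_severity_slope Utility change per depression point,
#'   linking the severity trajectory to health-related quality of life.
#' @param cost_dispersion Multiplier on the negative-binomial size of every
#'   resource-use count; larger values mean less overdispersion.
#' @param cost_family `"nbinom"` (right-skewed counts, the default) or
#'   `"normal"` (moment-matched symmetric draws, truncated at zero).
#' @param outcome_joint_rate Probability that EQ-5D and depression scores are
#'   masked together with a masked service-use block.
#' @param mar_slope Logit slope of block missingness per baseline severity
#'   point (MAR mechanism only).
#' @param severity_cost_slope Log-linear effect of baseline severity on
#'   resource-use rates (mean-normalised, so expected costs are unchanged).
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(delta_qaly_12m = 0.032,
                      delta_cost_other_12m = -909,
                      intervention_cost_mean = 5000,
                      delta_hrsd_12m = 1,
                      missing_fraction = 0.30,
                      missing_mechanism = c("MAR-on-baseline", "MCAR"),
                      utility_noise_sd = 0.2,
                      subject_sd = 0.15,
                      utility_severity_slope = -0.01,
                      cost_dispersion = 1,
                      cost_family = c("nbinom", "normal"),
                      outcome_joint_rate = 0.8,
                      mar_slope = 0.15,
                      severity_cost_slope = 0.04) {
  missing_mechanism <- match.arg(missing_mechanism)
  cost_family <- match.arg(cost_family)
  check_number(delta_qaly_12m, "delta_qaly_12m")
  check_number(delta_cost_other_12m, "delta_cost_other_12m")
  check_number(intervention_cost_mean, "intervention_cost_mean", min = 0)
  check_number(delta_hrsd_12m, "delta_hrsd_12m")
  check_number(missing_fraction, "missing_fraction", min = 0)
  if (missing_fraction >= 1) abort("`missing_fraction` must be < 1.")
  check_number(utility_noise_sd, "utility_noise_sd", min = 0)
  check_number(subject_sd, "subject_sd", min = 0)
  check_number(utility_severity_slope, "utility_severity_slope")
  check_number(cost_dispersion, "cost_dispersion", min = 0, strict_min = TRUE)
  check_number(outcome_joint_rate, "outcome_joint_rate", min = 0, max = 1)
  structure(
    list(delta_qaly_12m = delta_qaly_12m,
         delta_cost_other_12m = delta_cost_other_12m,
         intervention_cost_mean = intervention_cost_mean,
         delta_hrsd_12m = delta_hrsd_12m,
         missing_fraction = missing_fraction,
         missing_mechanism = missing_mechanism,
         utility_noise_sd = utility_noise_sd,
         subject_sd = subject_sd,
         utility_severity_slope = utility_severity_slope,
         cost_dispersion = cost_dispersion,
         cost_family = cost_family,
         outcome_joint_rate = outcome_joint_rate,
         mar_slope = mar_slope,
         severity_cost_slope = severity_cost_slope),
    class = "sim_truth"
  )
}

#' Trial design for the synthetic generator
#'
#' @param n_intervention,n_control Arm sizes (default 162:88, a 65:35
#'   allocation).
#' @param waves Assessment times in months; the generator emulates the
#'   four-wave 0/7/12/18 schedule.
#' @param seed Master seed; one seed governs a hierarchical stream
#'   (participant, then wave), so adding or removing participants never
#'   reshuffles the draws of others.
#' @param true_effects A [sim_truth()].
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(n_intervention = 162, n_control = 88,
                         waves = c(0, 7, 12, 18), seed = 1L,
                         true_effects = sim_truth()) {
  n_intervention <- check_count(n_intervention, "n_intervention", min = 1)
  n_control <- check_count(n_control, "n_control", min = 1)
  if (n_intervention + n_control < 4) {
    abort("`n_intervention` + `n_control` must be >= 4.")
  }
  if (length(waves) < 2 || waves[1] != 0 || any(diff(waves) <= 0)) {
    abort("`waves` must be strictly increasing and start at 0.")
  }
  seed <- check_count(seed, "seed", min = 0)
  if (!inherits(true_effects, "sim_truth")) {
    abort("`true_effects` must be built with sim_truth().")
  }
  structure(
    list(n_intervention = n_intervention, n_control = n_control,
         waves = waves, seed = seed, true_effects = true_effects),
    class = "trial_design"
  )
}

# Fixed generator constants: wave-level means, severity model, resource-use
# category rates (12-month control-arm means) and dispersions, intervention
# session structure. Exposed for documentation and tests.
synth_constants <- function() {
  list(
    waves = c(0, 7, 12, 18),
    # control-arm mean utility trajectory (refractory depression: low
    # baseline, slow improvement in both arms)
    utility_means = c(m0 = 0.45, m7 = 0.52, m12 = 0.55, m18 = 0.58),
    hrsd_ref = 21,                # centring constant for severity
    hrsd_means = c(m7 = 19, m12 = 18, m18 = 17.5), # control follow-up means
    hrsd_tracking = 0.6,          # follow-up regression on baseline severity
    hrsd_noise_sd = 4,
    # baseline severity: 15 + Binomial(20, 0.3), mean 21
    hrsd0_trials = 20L, hrsd0_prob = 0.3, hrsd0_floor = 15L,
    # resource-use categories: 12-month control-arm mean contacts and
    # negative-binomial size (smaller size = heavier right tail)
    categories = tibble::tribble(
      ~service_code,                   ~mu_ctrl_12m, ~mu_int_12m, ~size,
      "inpatient_day",                  4.0,          NA,          0.30,
      "outpatient_visit",               3.0,          NA,          0.50,
      "a_and_e",                        0.8,          NA,          0.50,
      "gp_visit",                       8.0,          NA,          1.00,
      "practice_nurse",                 3.0,          NA,          1.00,
      "community_mental_health_nurse",  6.0,          NA,          0.50,
      "psychiatrist_visit",             2.0,          NA,          0.50,
      "social_worker",                  1.5,          NA,          0.50,
      "talking_therapy_session",        9.1,          3.4,         0.50
    ),
    # intervention session structure
    n_individual_offered = 29L, n_group_sessions = 27L,
    individual_attend_mean = 22.8, group_attend_mean = 19.3,
    attend_precision = 6,         # beta-binomial concentration
    target_group_size = 7L,
    # work absence (per 6 months, employed participants)
    absent_hours_mean = 35, unproductive_hours_mean = 25,
    absence_shape = 0.5,
    employed_prob = 0.45, female_prob = 0.66,
    # medications: category, probability of use, daily-cost range, mean
    # duration in days
    medications = tibble::tribble(
      ~category,         ~p_use, ~cost_lo, ~cost_hi, ~mean_days,
      "antidepressant",   0.75,   0.03,     0.30,     500,
      "antipsychotic",    0.20,   0.10,     1.50,     350,
      "sleeping_tablet",  0.15,   0.05,     0.40,     120,
      "painkiller",       0.30,   0.02,     0.20,     200
    )
  )
}

# Follow-up intervals covered by each assessment wave (months); the baseline
# questionnaire covers the 6 months before randomisation.
wave_intervals <- function() {
  tibble::tibble(
    wave = c("m0", "m7", "m12", "m18"),
    start = c(-6, 0, 7, 12),
    end = c(0, 7, 12, 18)
  )
}

# Balanced partition of n participants into groups of ~target size.
balanced_group_sizes <- function(n, target = 7L) {
  k <- ceiling(n / target)
  base <- n %/% k
  extra <- n %% k
  c(rep(base + 1L, extra), rep(base, k - extra))
}

# Normalising constant so the severity multiplier exp(slope*(sev-ref)) has
# expectation 1 over the baseline severity distribution (closed form over
# the finite binomial support).
severity_multiplier_norm <- function(slope, const = synth_constants()) {
  k <- 0:const$hrsd0_trials
  sev <- const$hrsd0_floor + k
  sum(dbinom(k, const$hrsd0_trials, const$hrsd0_prob) *
        exp(slope * (sev - const$hrsd_ref)))
}

# Direct (non-severity-mediated) utility effect at months 7 and 12 solving
# the 12-month QALY target, given the mediated lift from the depression
# effect. AUC weights for u7 and u12 over 0-12 months are 6 and 2.5 twelfths.
direct_utility_effect <- function(truth, const = synth_constants()) {
  mediated <- -truth$utility_severity_slope * truth$delta_hrsd_12m
  truth$delta_qaly_12m * 12 / 8.5 - mediated
}

#' True arm differences implied by a simulation truth
#'
#' Closed-form expected adjusted differences the generator injects, for
#' comparison with pipeline estimates. Cost differences assume the packaged
#' default unit costs and a therapist rate calibrated with
#' [calibrate_therapist_rate()].
#'
#' @param truth A [sim_truth()].
#' @param horizon_months 12 or 18.
#' @return List with `delta_cost`, `delta_qaly`, `delta_hrsd`.
#' @export
truth_deltas <- function(truth, horizon_months = 12) {
  stopifnot(inherits(truth, "sim_truth"))
  mediated <- -truth$utility_severity_slope * truth$delta_hrsd_12m
  e <- direct_utility_effect(truth, const)
  dq <- if (horizon_months == 12) {
    truth$delta_qaly_12m
  } else if (horizon_months == 18) {
    (11.5 * (e + mediated) + 3 * mediated) / 12
  } else {
    abort("`horizon_months` must be 12 or 18.")
  }
  list(delta_cost = truth$intervention_cost_mean + truth$delta_cost_other_12m,
       delta_qaly = dq,
       delta_hrsd = truth$delta_hrsd_12m)
}

#' Calibrate the therapist hourly rate to a target intervention cost
#'
#' Solves the hourly employment cost so that the expected micro-costed
#' intervention cost per intervention participant equals
#' `truth$intervention_cost_mean`, given the session structure (29 offered
#' individual sessions with the configured mean attendance; 27 group
#' sessions charged per invitee under the actual group partition and
#' staffing rule).
#'
#' @param design A [trial_design()].
#' @param params Template [therapist_cost_params()] supplying everything but
#'   the hourly rate.
#' @return A `therapist_cost_params` with the calibrated hourly rate.
#' @export
calibrate_therapist_rate <- function(design, params = therapist_cost_params()) {
  stopifnot(inherits(design, "trial_design"))
  const <- synth_constants()
  sizes <- balanced_group_sizes(design$n_intervention, const$target_group_size)
  # expected cost per participant at hourly rate 1
  per_invitee_unit <- therapists_for_group(sizes, params) *
    (1 + params$nondirect_ratio) * (params$group_session_minutes / 60) / sizes
  mean_group_unit <- sum(per_invitee_unit * sizes) / sum(sizes)
  unit <- (1 + params$nondirect_ratio) *
    (params$individual_session_minutes / 60) * const$individual_attend_mean +
    const$n_group_sessions * mean_group_unit
  params$hourly_employment_cost <- design$true_effects$intervention_cost_mean / unit
  params
}

# Per-interval count means by arm and category, plus the arm scale factors
# that inject the configured other-care cost difference (all of it in the
# two 0-12 month intervals; zero difference in months 12-18 and at baseline).
category_rates <- function(truth, const = synth_constants(),
                           prices = default_unit_costs()) {
  cats <- const$categories
  price <- setNames(prices$cost, prices$service_code)[cats$service_code]
  if (any(is.na(price))) abort("Generator category missing from unit costs.")
  tt <- cats$service_code == "talking_therapy_session"
  base_spend <- sum(price[!tt] * cats$mu_ctrl_12m[!tt])
  tt_delta_12 <- price[tt] * (cats$mu_int_12m[tt] - cats$mu_ctrl_12m[tt])
  g12 <- 1 + (truth$delta_cost_other_12m - tt_delta_12) / base_spend
  g18 <- 1 + (0 - tt_delta_12 * 0.5) / (base_spend * 0.5)
  if (g12 < 0 || g18 < 0) {
    abort("`delta_cost_other_12m` too large in magnitude for the category rates.")
  }
  list(categories = cats, price = price, g12 = g12, g18 = g18)
}

draw_count <- function(mu, size, family) {
  if (mu <= 0) return(0)
  if (family == "nbinom") {
    rnbinom(1L, size = size, mu = mu)
  } else {
    max(0, rnorm(1L, mu, sqrt(mu + mu^2 / size)))
  }
}

#' Generate a synthetic two-arm trial
#'
#' Produces one row per participant with baseline covariates, EQ-5D-3L
#' states at each wave (latent utilities mapped to the nearest attainable
#' state under the UK tariff; the latent values are kept in `u_lat_*`
#' columns), depression scores, right-skewed resource-use counts per
#' follow-up interval, medication records, work absence, and intervention
#' attendance. No missingness is applied; see [apply_missingness()].
#'
#' @param design A [trial_design()].
#' @return A tibble, one row per participant, with the design attached as
#'   attribute `"design"`.
#' @export
generate_trial <- function(design) {
  if (!inherits(design, "trial_design")) {
    abort("`design` must be built with trial_design().")
  }
  if (!identical(as.numeric(design$waves), c(0, 7, 12, 18))) {
    abort("`waves`: the generator emulates the 0/7/12/18 month schedule.")
  }
  truth <- design$true_effects
  const <- synth_constants()
  tariff <- uk_eq5d_tariff()
  grid <- eq5d_states(tariff)
  u_min <- min(grid$utility)

  rates <- category_rates(truth, const)
  sev_norm <- severity_multiplier_norm(truth$severity_cost_slope, const)
  e_direct <- direct_utility_effect(truth, const)

  n_int <- design$n_intervention
  n <- n_int + design$n_control
  sizes <- balanced_group_sizes(n_int, const$target_group_size)
  group_id <- rep(seq_along(sizes), sizes)
  group_size <- rep(sizes, sizes)

  p_ind <- const$individual_attend_mean / const$n_individual_offered
  p_grp <- const$group_attend_mean / const$n_group_sessions
  nu <- const$attend_precision

  ivals <- wave_intervals()
  frac <- (ivals$end - ivals$start) / 12 # interval length as share of a year
  wave_labs <- ivals$wave

  # plain vectors for the hot per-participant loop
  cat_code <- rates$categories$service_code
  cat_mu_ctrl <- rates$categories$mu_ctrl_12m
  cat_mu_int <- rates$categories$mu_int_12m
  cat_size <- rates$categories$size
  cat_is_tt <- cat_code == "talking_therapy_session"
  med_cat <- const$medications$category
  med_p <- const$medications$p_use
  med_lo <- const$medications$cost_lo
  med_hi <- const$medications$cost_hi
  med_days <- const$medications$mean_days
  med_cap <- month_days(18)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(design$seed, i, 1L))
    arm_int <- i <= n_int

    age <- min(75L, max(18L, as.integer(round(rnorm(1, 45, 12)))))
    female <- rbinom(1, 1, const$female_prob)
    employed <- rbinom(1, 1, const$employed_prob)
    hrsd0 <- const$hrsd0_floor +
      rbinom(1, const$hrsd0_trials, const$hrsd0_prob)
    sev_c <- hrsd0 - const$hrsd_ref

    # depression trajectory (arm effect = improvement at every follow-up)
    hrsd_fu <- const$hrsd_means + const$hrsd_tracking * sev_c -
      (if (arm_int) truth$delta_hrsd_12m else 0) +
      rnorm(3, 0, const$hrsd_noise_sd)
    hrsd_fu <- pmin(52, pmax(0, round(hrsd_fu)))

    # latent utilities: wave mean + severity + subject intercept + noise +
    # direct arm effect at months 7 and 12
    b_i <- rnorm(1, 0, truth$subject_sd)
    hrsd_w <- c(hrsd0, hrsd_fu)
    direct <- c(0, e_direct, e_direct, 0) * arm_int
    u_lat <- const$utility_means +
      truth$utility_severity_slope * (hrsd_w - const$hrsd_ref) +
      b_i + direct + rnorm(4, 0, truth$utility_noise_sd)
    u_lat <- pmin(1, pmax(u_min, u_lat))
    states <- nearest_state_from_grid(u_lat, grid)

    # resource-use counts per interval x category
    mult <- exp(truth$severity_cost_slope * sev_c) / sev_norm
    counts <- list()
    for (w in seq_len(4)) {
      g <- if (!arm_int || w == 1) 1 else if (w <= 3) rates$g12 else rates$g18
      for (k in seq_along(cat_code)) {
        mu12 <- if (arm_int && w > 1 && cat_is_tt[k]) cat_mu_int[k] else
          cat_mu_ctrl[k]
        mu <- mu12 * frac[w] * mult * (if (cat_is_tt[k]) 1 else g)
        size <- cat_size[k] * frac[w] * truth$cost_dispersion
        counts[[paste0(cat_code[k], "_", wave_labs[w])]] <-
          draw_count(mu, size, truth$cost_family)
      }
    }

    # medications (identical process in both arms)
    meds <- list()
    for (k in seq_along(med_cat)) {
      if (runif(1) < med_p[k]) {
        daily <- runif(1, med_lo[k], med_hi[k])
        start <- -round(runif(1, 0, 300))
        finish <- min(med_cap, start + round(rexp(1, 1 / med_days[k])))
      } else {
        daily <- NA_real_; start <- NA_real_; finish <- NA_real_
      }
      meds[[paste0("med_", med_cat[k], "_daily")]] <- daily
      meds[[paste0("med_", med_cat[k], "_start")]] <- start
      meds[[paste0("med_", med_cat[k], "_finish")]] <- finish
    }

    # work absence (hours per interval; employed participants only)
    absence <- list()
    for (w in seq_len(4)) {
      len6 <- (ivals$end[w] - ivals$start[w]) / 6
      if (employed) {
        ab <- rgamma(1, const$absence_shape,
                     rate = const$absence_shape / (const$absent_hours_mean * len6))
        un <- rgamma(1, const$absence_shape,
                     rate = const$absence_shape / (const$unproductive_hours_mean * len6))
      } else {
        ab <- NA_real_; un <- NA_real_
      }
      absence[[paste0("absent_hours_", wave_labs[w])]] <- ab
      absence[[paste0("unproductive_hours_", wave_labs[w])]] <- un
    }

    # intervention attendance
    if (arm_int) {
      pi_i <- rbeta(1, p_ind * nu, (1 - p_ind) * nu)
      pg_i <- rbeta(1, p_grp * nu, (1 - p_grp) * nu)
      n_ind_att <- rbinom(1, const$n_individual_offered, pi_i)
      n_grp_att <- rbinom(1, const$n_group_sessions, pg_i)
      gid <- group_id[i]; gsz <- group_size[i]
    } else {
      n_ind_att <- 0L; n_grp_att <- 0L; gid <- NA_integer_; gsz <- NA_integer_
    }

    rows[[i]] <- c(
      list(participant_id = i,
           arm = if (arm_int) "intervention" else "control",
           age = age, female = female, employed = employed,
           hrsd_m0 = hrsd0,
           hrsd_m7 = hrsd_fu[1], hrsd_m12 = hrsd_fu[2], hrsd_m18 = hrsd_fu[3],
           eq5d_m0 = states[1], eq5d_m7 = states[2], eq5d_m12 = states[3],
           eq5d_m18 = states[4],
           u_lat_m0 = u_lat[1], u_lat_m7 = u_lat[2], u_lat_m12 = u_lat[3],
           u_lat_m18 = u_lat[4]),
      counts, meds, absence,
      list(n_individual_offered = if (arm_int) const$n_individual_offered else 0L,
           n_individual_attended = n_ind_att,
           n_group_sessions = if (arm_int) const$n_group_sessions else 0L,
           n_group_attended = n_grp_att,
           group_id = gid, group_size = gsz,
           missing_block_m7 = FALSE, missing_block_m12 = FALSE,
           missing_block_m18 = FALSE)
    )
  }
  out <- dplyr::bind_rows(rows)
  out$arm <- factor(out$arm, levels = c("control", "intervention"))
  attr(out, "design") <- design
  out
}

# Columns forming the service-use block of one follow-up wave.
block_columns <- function(wave_lab) {
  codes <- synth_constants()$categories$service_code
  c(paste0(codes, "_", wave_lab),
    paste0(c("absent_hours_", "unproductive_hours_"), wave_lab))
}

#' Mask service-use blocks to emulate incomplete follow-up
#'
#' Selects participants at rate `truth$missing_fraction` — completely at
#' random or, under MAR, with probability increasing in baseline severity
#' (the logistic intercept is solved so the marginal rate matches) — and
#' masks their service-use blocks monotonically from month 7 or month 12
#' onward. Every selected participant has an incomplete 12-month record,
#' matching how the fraction of incomplete service-use information is
#' defined. EQ-5D and depression scores at the masked waves are masked
#' jointly with probability `truth$outcome_joint_rate`.
#'
#' @param full A trial table from [generate_trial()] with no masked entries.
#' @param truth A [sim_truth()].
#' @param seed Seed for the masking stream.
#' @return The table with masked blocks (`NA`) and `missing_block_m*` flags.
#' @export
apply_missingness <- function(full, truth, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  full <- tibble::as_tibble(full)
  flags <- c("missing_block_m7", "missing_block_m12", "missing_block_m18")
  if (any(unlist(full[, flags]))) {
    abort("`full` already has masked service-use blocks.")
  }
  f <- truth$missing_fraction
  if (f == 0) return(full)

  sev_c <- full$hrsd_m0 - synth_constants()$hrsd_ref
  p <- if (truth$missing_mechanism == "MCAR") {
    rep(f, nrow(full))
  } else if (truth$missing_mechanism == "MAR-on-baseline") {
    slope <- truth$mar_slope
    intercept <- uniroot(
      function(c0) mean(plogis(c0 + slope * sev_c)) - f,
      lower = -30, upper = 30, tol = 1e-12
    )$root
    plogis(intercept + slope * sev_c)
  } else {
    abort("Unknown missingness mechanism.")
  }

  wave_labs <- c("m7", "m12", "m18")
  n <- nrow(full)
  miss <- logical(n); start <- integer(n); mask_out <- logical(n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, full$participant_id[i], 99L))
    miss[i] <- runif(1) < p[i]
    start[i] <- sample.int(2L, 1L, prob = c(0.6, 0.4)) # month 7 or month 12
    mask_out[i] <- runif(1) < truth$outcome_joint_rate
  }
  out <- full
  for (w in seq_along(wave_labs)) {
    lab <- wave_labs[w]
    rows <- miss & start <= w
    if (!any(rows)) next
    for (col in block_columns(lab)) out[[col]][rows] <- NA_real_
    out[[paste0("missing_block_", lab)]][rows] <- TRUE
    orows <- rows & mask_out
    out[[paste0("eq5d_", lab)]][orows] <- NA_character_
    out[[paste0("u_lat_", lab)]][orows] <- NA_real_
    out[[paste0("hrsd_", lab)]][orows] <- NA_real_
  }
  attr(out, "design") <- attr(full, "design")
  out
}

#' Generate and mask in one call
#'
#' @param design A [trial_design()].
#' @return Masked trial table (identical to [generate_trial()] output when
#'   `missing_fraction` is zero).
#' @export
simulate_trial <- function(design) {
  full <- generate_trial(design)
  masked <- apply_missingness(full, design$true_effects,
                              seed = derive_seed(design$seed, 7919L))
  attr(masked, "design") <- design
  masked
}

#' Session-level attendance log
#'
#' Expands the per-participant attendance counts into one row per offered
#' session (individual) or scheduled group session, with invited/attended
#' flags — the long format a therapy-records export would take. Attended
#' session indices are drawn reproducibly from the participant's stream.
#'
#' @param trial A table from [generate_trial()].
#' @return Tibble: `participant_id`, `session_type`, `session_index`,
#'   `invited`, `attended`.
#' @export
attendance_log <- function(trial) {
  design <- attr(trial, "design")
  if (is.null(design)) abort("`trial` must carry its design attribute.")
  rows <- list()
  ids <- trial$participant_id[trial$arm == "intervention"]
  for (i in ids) {
    r <- trial[trial$participant_id == i, ]
    set.seed(derive_seed(design$seed, i, 5L))
    ind_att <- sort(sample.int(r$n_individual_offered, r$n_individual_attended))
    grp_att <- sort(sample.int(r$n_group_sessions, r$n_group_attended))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      participant_id = i,
      session_type = rep(c("individual", "group"),
                         c(r$n_individual_offered, r$n_group_sessions)),
      session_index = c(seq_len(r$n_individual_offered),
                        seq_len(r$n_group_sessions)),
      invited = TRUE,
      attended = c(seq_len(r$n_individual_offered) %in% ind_att,
                   seq_len(r$n_group_sessions) %in% grp_att)
    )
  }
  dplyr::bind_rows(rows)
}

#' Write a synthetic trial to disk
#'
#' Writes `participants.csv`, `attendance.csv` and `design.json` under
#' `dir`.
#'
#' @param trial Table from [generate_trial()] or [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- attr(trial, "design")
  paths <- c(participants = file.path(dir, "participants.csv"),
             attendance = file.path(dir, "attendance.csv"),
             design = file.path(dir, "design.json"))
  utils::write.csv(trial, paths["participants"], row.names = FALSE)
  utils::write.csv(attendance_log(trial), paths["attendance"], row.names = FALSE)
  if (!is.null(design)) {
    jsonlite::write_json(
      list(n_intervention = design$n_intervention,
           n_control = design$n_control, waves = design$waves,
           seed = design$seed,
           true_effects = unclass(design$true_effects)),
      paths["design"], auto_unbox = TRUE, digits = NA
    )
  }
  invisible(paths)
}
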