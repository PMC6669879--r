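test_that("defaults give a 250-participant trial with a 162:88 allocation", {
  d <- trial_design(seed = 1)
  tr <- generate_trial(d)
  expect_equal(nrow(tr), 250)
  expect_equal(sum(tr$arm == "intervention"), 162)
  expect_equal(sum(tr$arm == "control"), 88)
  expect_false(anyNA(tr$eq5d_m12))
  # states are valid five-digit profiles
  expect_true(all(grepl("^[123]{5}$", tr$eq5d_m0)))
  # latent utilities stay in the tariff's attainable range
  u_min <- min(eq5d_states()$utility)
  for (lab in c("m0", "m7", "m12", "m18")) {
    expect_true(all(tr[[paste0("u_lat_", lab)]] >= u_min - 1e-12))
    expect_true(all(tr[[paste0("u_lat_", lab)]] <= 1 + 1e-12))
  }
})

test_that("invalid designs fail naming the offending field", {
  expect_error(trial_design(n_intervention = 0), "n_intervention")
  expect_error(trial_design(n_intervention = 2, n_control = 1), ">= 4")
  expect_error(trial_design(waves = c(0, 7, 7, 18)), "waves")
  expect_error(trial_design(waves = c(1, 7, 12)), "waves")
  expect_error(sim_truth(missing_fraction = 1), "missing_fraction")
  expect_error(sim_truth(cost_dispersion = 0), "cost_dispersion")
  expect_error(generate_trial(list()), "trial_design")
})

test_that("a fixed seed reproduces the table and extra participants do not
          reshuffle existing ones", {
  d1 <- trial_design(20, 10, seed = 5)
  t1 <- generate_trial(d1)
  expect_identical(as.data.frame(generate_trial(d1)), as.data.frame(t1))
  # enlarging the control arm leaves all shared participants untouched
  d2 <- trial_design(20, 20, seed = 5)
  t2 <- generate_trial(d2)
  expect_equal(as.data.frame(t1), as.data.frame(t2[1:30, ]),
               ignore_attr = TRUE)
  # different seed, different data
  t3 <- generate_trial(trial_design(20, 10, seed = 6))
  expect_false(identical(t1$u_lat_m0, t3$u_lat_m0))
})

test_that("attendance emulates the observed session uptake", {
  tr <- generate_trial(trial_design(seed = 2))
  int <- tr[tr$arm == "intervention", ]
  expect_true(all(int$n_individual_attended <= 29))
  expect_true(all(int$n_group_attended <= 27))
  # means close to 22.8 of 29 individual, 19.3 of 27 group
  expect_lt(abs(mean(int$n_individual_attended) - 22.8), 1.5)
  expect_lt(abs(mean(int$n_group_attended) - 19.3), 1.5)
  # control participants have no intervention exposure
  ctl <- tr[tr$arm == "control", ]
  expect_true(all(ctl$n_individual_attended == 0))
  expect_true(all(is.na(ctl$group_size)))
  # balanced closed groups of about seven
  expect_true(all(int$group_size %in% 6:7))
  expect_equal(sum(unique(int[, c("group_id", "group_size")])$group_size),
               162)
})

test_that("the session-level log is consistent with the aggregate counts", {
  tr <- small_trial()
  log <- attendance_log(tr)
  expect_true(all(log$invited))
  agg <- dplyr::summarise(
    dplyr::group_by(log, .data$participant_id, .data$session_type),
    att = sum(.data$attended), .groups = "drop"
  )
  ind <- agg[agg$session_type == "individual", ]
  tr_int <- tr[tr$arm == "intervention", ]
  expect_equal(ind$att[match(tr_int$participant_id, ind$participant_id)],
               tr_int$n_individual_attended)
  grp <- agg[agg$session_type == "group", ]
  expect_equal(grp$att[match(tr_int$participant_id, grp$participant_id)],
               tr_int$n_group_attended)
})

test_that("zero missing fraction leaves the table untouched", {
  tr <- small_trial()
  out <- apply_missingness(tr, sim_truth(missing_fraction = 0), seed = 4)
  expect_identical(as.data.frame(out), as.data.frame(tr))
  d0 <- trial_design(30, 20, seed = 9,
                     true_effects = sim_truth(missing_fraction = 0))
  sim <- simulate_trial(d0)
  expect_false(any(sim$missing_block_m7 | sim$missing_block_m12 |
                     sim$missing_block_m18))
  expect_false(anyNA(sim$inpatient_day_m12))
})

test_that("MCAR masking hits the configured rate", {
  d <- trial_design(3900, 2100, seed = 31,
                    true_effects = sim_truth(missing_fraction = 0.5,
                                             missing_mechanism = "MCAR"))
  tr <- generate_trial(d)
  masked <- apply_missingness(tr, d$true_effects, seed = 8)
  frac <- mean(masked$missing_block_m7 | masked$missing_block_m12)
  expect_lt(abs(frac - 0.5), 0.02)
  # every masked participant has an incomplete 12-month record
  expect_true(all(is.na(masked$inpatient_day_m12[masked$missing_block_m12])))
})

test_that("MAR masking hits the rate and depends on baseline severity", {
  d <- trial_design(3250, 1750, seed = 32) # defaults: 30% MAR
  tr <- generate_trial(d)
  masked <- apply_missingness(tr, d$true_effects, seed = 9)
  miss <- masked$missing_block_m7 | masked$missing_block_m12
  expect_lt(abs(mean(miss) - 0.30), 0.02)
  # masked participants are more severe at baseline
  expect_gt(mean(masked$hrsd_m0[miss]), mean(masked$hrsd_m0[!miss]))
  # logistic regression recovers a positive severity slope
  fit <- glm(miss ~ masked$hrsd_m0, family = binomial())
  z <- coef(summary(fit))[2, "z value"]
  expect_gt(z, 3)
  expect_error(apply_missingness(masked, d$true_effects, seed = 1),
               "already")
})

test_that("generated resource-use moments match the configured rates", {
  d <- trial_design(3900, 2100, seed = 33,
                    true_effects = sim_truth(missing_fraction = 0))
  tr <- generate_trial(d)
  ctl <- tr[tr$arm == "control", ]
  const <- synth_constants()
  for (code in c("inpatient_day", "gp_visit", "talking_therapy_session")) {
    mu12 <- const$categories$mu_ctrl_12m[const$categories$service_code == code]
    x <- ctl[[paste0(code, "_m7")]] + ctl[[paste0(code, "_m12")]]
    se <- sd(x) / sqrt(nrow(ctl))
    expect_lt(abs(mean(x) - mu12), 3 * se)
  }
  # intervention-arm talking therapy drops to its configured rate
  int <- tr[tr$arm == "intervention", ]
  x <- int$talking_therapy_session_m7 + int$talking_therapy_session_m12
  expect_lt(abs(mean(x) - 3.4), 3 * sd(x) / sqrt(nrow(int)))
})

test_that("the calibrated therapist rate prices the intervention on target", {
  d <- trial_design(seed = 34)
  tr <- generate_trial(d)
  ana <- build_analysis_table(tr)
  int_cost <- ana$intervention_cost[ana$arm == "intervention"]
  se <- sd(int_cost) / sqrt(length(int_cost))
  expect_lt(abs(mean(int_cost) - 5000), 3 * se)
  expect_true(all(ana$intervention_cost[ana$arm == "control"] == 0))
})

test_that("with all noise channels off the pipeline recovers the exact
          QALY difference", {
  tr0 <- sim_truth(missing_fraction = 0, utility_noise_sd = 0,
                   subject_sd = 0, utility_severity_slope = 0,
                   delta_hrsd_12m = 0)
  d <- trial_design(40, 20, seed = 3, true_effects = tr0)
  ana <- build_analysis_table(generate_trial(d), utility_source = "latent")
  res <- suppressWarnings(
    cea_analysis(ana, m = 2, B = 1, resample = FALSE,
                 covariates = c("age", "female", "hrsd_m0"), seed = 2)
  )
  expect_equal(res$delta_effect, 0.032, tolerance = 1e-8)
})

test_that("trial export writes participant, attendance and design files", {
  dir <- withr::local_tempdir()
  tr <- small_trial()
  paths <- write_trial(tr, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["participants"]])
  expect_equal(nrow(back), nrow(tr))
  cfg <- jsonlite::read_json(paths[["design"]])
  expect_equal(cfg$n_intervention, 40)
  expect_equal(cfg$true_effects$missing_fraction, 0)
})
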