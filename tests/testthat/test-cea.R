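normal_arm_data <- function(n, delta = 5000, seed = 1) {
  set.seed(seed)
  arm <- factor(rep(c("control", "intervention"), each = n / 2),
                levels = c("control", "intervention"))
  x <- rnorm(n)
  tibble::tibble(
    arm = arm, x = x,
    y = 1000 + 200 * x + delta * (arm == "intervention") + rnorm(n, 0, 800)
  )
}

test_that("the adjusted difference recovers injected arm effects", {
  # null case: equal outcome distributions
  d0 <- normal_arm_data(400, delta = 0, seed = 2)
  fit0 <- adjusted_difference(d0, "y")
  expect_lt(abs(fit0$estimate), 3 * fit0$se)
  # +5000 injected effect at n = 2000
  d1 <- normal_arm_data(2000, delta = 5000, seed = 3)
  fit1 <- adjusted_difference(d1, "y", covariates = "x")
  expect_lt(abs(fit1$estimate - 5000), 3 * fit1$se)
  # a covariate uncorrelated with arm barely moves the coefficient
  d1$noise_cov <- rnorm(2000)
  fit2 <- adjusted_difference(d1, "y", covariates = c("x", "noise_cov"))
  cov_se <- sqrt(vcov(fit2$model)["noise_cov", "noise_cov"])
  expect_lt(abs(fit2$estimate - fit1$estimate), cov_se)
})

test_that("degenerate adjustments fail naming the covariate", {
  d <- normal_arm_data(100, seed = 4)
  d$flat <- 1
  expect_error(adjusted_difference(d, "y", covariates = "flat"), "`flat`")
  d$x2 <- d$x # exact collinearity
  expect_error(adjusted_difference(d, "y", covariates = c("x", "x2")),
               "Collinear")
  d$y[1] <- NA
  expect_error(adjusted_difference(d, "y"), "missing")
})

test_that("the identity resample collapses the cloud to the point estimates", {
  d <- normal_arm_data(120, seed = 5)
  spec <- adjustment_spec("y", "x")
  cl <- bootstrap_cloud(d, spec, spec, B = 1, resample = FALSE, seed = 6)
  expect_equal(nrow(cl), 1)
  fit <- adjusted_difference(d, spec)
  expect_equal(cl$delta_cost, fit$estimate)
  expect_equal(cl$delta_effect, fit$estimate)
})

test_that("the bootstrap preserves arm sizes within every resample and
          brackets the analytic interval", {
  d <- normal_arm_data(2000, seed = 7)
  spec <- adjustment_spec("y", "x")
  cl <- bootstrap_cloud(d, spec, spec, B = 400, seed = 8)
  expect_equal(nrow(cl), 400)
  fit <- adjusted_difference(d, spec)
  boot_ci <- quantile(cl$delta_cost, c(0.025, 0.975))
  ols_ci <- fit$estimate + c(-1.96, 1.96) * fit$se
  # percentile CI close to the analytic CI on normal data (10% of width)
  expect_lt(abs(diff(boot_ci) - diff(ols_ci)) / diff(ols_ci), 0.10)
  expect_lt(abs(mean(boot_ci) - fit$estimate), 0.1 * diff(ols_ci))
})

test_that("the ratio statistic is the quotient with quadrant labelling", {
  r <- icer(7048, 0.032)
  expect_equal(r$icer, 7048 / 0.032)
  expect_equal(r$quadrant, "NE")
  expect_equal(icer(7048, 1)$icer, 7048)
  expect_equal(icer(-500, 0.1)$quadrant, "SE")
  expect_match(icer(-500, 0.1)$interpretation, "dominant")
  expect_match(icer(500, -0.1)$interpretation, "dominated")
  u <- icer(500, 0)
  expect_true(is.na(u$icer))
  expect_match(u$interpretation, "undefined")
  # identity holds to near machine precision on random inputs
  set.seed(9)
  for (i in 1:25) {
    dc <- runif(1, -1e4, 1e4); de <- runif(1, -1, 1)
    if (de == 0) next
    expect_equal(icer(dc, de)$icer * de, dc, tolerance = 1e-9)
  }
})

test_that("the acceptability curve is the exceedance of net monetary
          benefit", {
  # degenerate cloud at the published point: zero at the 30k threshold
  cl <- mock_cloud(7048, 0.032)
  expect_equal(prob_cost_effective(cl, 30000), 0)
  expect_equal(prob_cost_effective(cl, 7048 / 0.032 + 1), 1)
  # lambda = 0: probability equals the fraction of cost-saving replicates
  set.seed(10)
  cl2 <- mock_cloud(rnorm(5000, 100, 300), rnorm(5000, 0.01, 0.05))
  expect_equal(prob_cost_effective(cl2, 0), mean(cl2$delta_cost < 0))
  # very large lambda: tends to the fraction with positive effect
  expect_equal(prob_cost_effective(cl2, 1e12), mean(cl2$delta_effect > 0))
  curve <- ceac(cl2, seq(0, 50000, 500))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  expect_error(ceac(cl2, numeric(0)), "non-empty")
})

test_that("quadrant shares follow the half-open convention and sum to one", {
  expect_equal(quadrant_shares(mock_cloud(10, 0.1)),
               tibble::tibble(ne = 1, nw = 0, se = 0, sw = 0))
  # exact zeros go to the "<= 0" side
  z <- quadrant_shares(mock_cloud(0, 0))
  expect_equal(z$sw, 1)
  set.seed(12)
  sym <- mock_cloud(rnorm(40000), rnorm(40000))
  qs <- quadrant_shares(sym)
  expect_equal(sum(qs$ne, qs$nw, qs$se, qs$sw), 1)
  for (s in unlist(qs)) expect_lt(abs(s - 0.25), 0.02)
  # all cost-increasing replicates lie above the x-axis
  up <- mock_cloud(abs(rnorm(100)) + 0.1, rnorm(100))
  qup <- quadrant_shares(up)
  expect_equal(qup$ne + qup$nw, 1)
})

test_that("the pooled cost difference agrees with the cloud mean", {
  res <- demo_result()
  cloud_se <- sd(res$cloud$delta_cost) / sqrt(nrow(res$cloud))
  expect_lt(abs(res$delta_cost - mean(res$cloud$delta_cost)), 3 * cloud_se +
              2 * res$delta_cost_se / sqrt(res$m))
  expect_equal(nrow(res$cloud), res$m * res$B)
  expect_equal(res$icer$icer, res$delta_cost / res$delta_effect)
})

test_that("tidy, glance and plots expose the result surface", {
  res <- demo_result()
  td <- tidy(res)
  expect_equal(td$term, c("delta_cost", "delta_effect", "icer"))
  expect_equal(td$estimate[1], res$delta_cost)
  gl <- glance(res)
  expect_equal(gl$n_replicates, res$m * res$B)
  expect_true(gl$p_ce_30k >= 0 && gl$p_ce_30k <= 1)
  expect_s3_class(autoplot(res, "plane"), "ggplot")
  expect_s3_class(autoplot(res, "ceac"), "ggplot")
  expect_output(print(res), "ICER")
})

test_that("sensitivity scenarios vary the base case as specified", {
  d <- trial_design(seed = 101)
  ana <- build_analysis_table(simulate_trial(d))
  sc <- run_scenarios(ana, m = 3, B = 50, seed = 5)
  expect_equal(sc$scenario, 0:5)
  expect_false(any(sc$skipped))
  base <- sc$result[[1]]
  # scenario 2 adds non-negative absenteeism costs
  expect_gte(mean(sc$result[[3]]$cloud$delta_cost),
             mean(base$cloud$delta_cost) - 500)
  # scenario 3 shrinks the intervention cost difference
  expect_lt(sc$delta_cost[4], sc$delta_cost[1])
  # scenario 4 uses the 18-month outcomes (additive QALY intervals)
  expect_equal(ana$qaly_18, ana$qaly_12 + ana$qint_m18)
  expect_equal(sc$result[[5]]$horizon_months, 18)
  # scenario 5 reports cost per depression point
  expect_equal(sc$result[[6]]$effect, "hrsd")
  # missing depression scores skip scenario 5 with a reason
  ana2 <- ana
  ana2$hrsd_m12 <- NA_real_
  ana2$hrsd_m7 <- NA_real_
  ana2$hrsd_m18 <- NA_real_
  sc2 <- run_scenarios(ana2, scenarios = 5, m = 2, B = 20, seed = 6)
  expect_true(sc2$skipped[sc2$scenario == 5])
  expect_match(sc2$reason[sc2$scenario == 5], "absent")
})

test_that("substituting the micro-costed per-invitee rate is a no-op", {
  # uniform groups of seven, so one rate reproduces the allocation exactly
  d <- trial_design(14, 7, seed = 51,
                    true_effects = sim_truth(missing_fraction = 0))
  ana <- build_analysis_table(generate_trial(d))
  params <- calibrate_therapist_rate(d)
  rate <- cost_group_session(7, params = params)
  sub <- substitute_group_cost(ana, per_session = rate, basis = "invited")
  expect_equal(sub$intervention_cost, ana$intervention_cost)
  expect_equal(sub$total_cost_12, ana$total_cost_12)
  # attended basis at the national rate lowers group costs
  sub14 <- substitute_group_cost(ana, per_session = 14, basis = "attended")
  int <- ana$arm == "intervention"
  expect_true(all(sub14$int_group_cost[int] < ana$int_group_cost[int]))
})
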