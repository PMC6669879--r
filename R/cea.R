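#' Adjustment specification for incremental analyses
#'
#' Describes one outcome regression: outcome on arm plus pre-specified
#' baseline covariates. The arm indicator is always included; its
#' coefficient is the adjusted mean difference.
#'
#' @param outcome Outcome column name.
#' @param covariates Baseline covariate column names.
#' @param arm Arm column (factor with the control level first).
#' @return List of class `adjustment_spec`.
#' @export
adjustment_spec <- function(outcome, covariates = character(), arm = "arm") {
  structure(list(outcome = outcome, covariates = covariates, arm = arm),
            class = "adjustment_spec")
}

# Response vector and design matrix for one adjustment regression, with
# explicit errors naming degenerate covariates.
adjustment_xy <- function(data, spec) {
  need <- c(spec$outcome, spec$covariates, spec$arm)
  absent <- setdiff(need, names(data))
  if (length(absent)) {
    abort(paste0("Column(s) not in data: ", paste(absent, collapse = ", ")))
  }
  for (v in spec$covariates) {
    vals <- data[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2L) {
      abort(paste0("Covariate `", v, "` is constant; drop it from the adjustment."))
    }
  }
  rhs <- paste(c(spec$arm, spec$covariates), collapse = " + ")
  X <- model.matrix(as.formula(paste("~", rhs)), data = data)
  arm_col <- grep(paste0("^", spec$arm), colnames(X))
  if (length(arm_col) != 1L) {
    abort("`arm` must be a two-level factor (control first).")
  }
  list(X = X, y = data[[spec$outcome]], arm_col = arm_col)
}

#' Covariate-adjusted arm difference
#'
#' Least-squares regression of the outcome on arm and baseline covariates;
#' the arm coefficient is the adjusted mean difference
#' (intervention minus control).
#'
#' @param data One complete dataset (e.g. one imputed copy).
#' @param spec An [adjustment_spec()], or an outcome column name.
#' @param covariates Covariates, if `spec` is given as a column name.
#' @return List: `estimate`, `se`, `term`, `model` (the `lm` fit).
#' @export
adjusted_difference <- function(data, spec, covariates = character()) {
  if (is.character(spec)) spec <- adjustment_spec(spec, covariates)
  stopifnot(inherits(spec, "adjustment_spec"))
  if (anyNA(data[[spec$outcome]])) {
    abort(paste0("`", spec$outcome, "` has missing values; impute or subset first."))
  }
  rhs <- paste(c(spec$arm, spec$covariates), collapse = " + ")
  fml <- as.formula(paste(spec$outcome, "~", rhs))
  xy <- adjustment_xy(data, spec) # validates covariates
  fit <- lm(fml, data = data)
  cf <- coef(fit)
  if (anyNA(cf)) {
    abort(paste0("Collinear term(s) in adjustment: ",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  term <- colnames(xy$X)[xy$arm_col]
  list(estimate = unname(cf[term]), se = sqrt(vcov(fit)[term, term]),
       term = term, model = fit)
}

#' Bootstrap cloud of incremental costs and effects
#'
#' For each completed dataset, draws `B` non-parametric resamples of
#' participants with replacement, stratified by arm with arm sizes fixed
#' (preserving the randomisation ratio), refits both adjustment regressions
#' in every resample, and pools all `m x B` (delta cost, delta effect)
#' pairs into one cloud. Resamples producing a singular fit are redrawn
#' (at most 100 per dataset).
#'
#' @param imputations An `imputation_set`, a list of complete data frames,
#'   or a single complete data frame.
#' @param cost_spec,effect_spec [adjustment_spec()]s for the two outcomes.
#' @param B Resamples per dataset.
#' @param seed Seed (per-dataset sub-streams are derived from it).
#' @param resample If `FALSE`, the identity "resample" is used and the cloud
#'   collapses to the per-dataset point estimates (test hook).
#' @param transform Optional function applied to each completed dataset
#'   before analysis (e.g. [finalise_analysis_table()]).
#' @return Tibble of class `boot_cloud`: `imputation`, `replicate`,
#'   `delta_cost`, `delta_effect`; attributes `B` and `m`.
#' @export
bootstrap_cloud <- function(imputations, cost_spec, effect_spec,
                            B = 1000L, seed = 1L, resample = TRUE,
                            transform = NULL) {
  B <- check_count(B, "B", min = 1)
  sets <- if (inherits(imputations, "imputation_set")) {
    complete_tables(imputations, transform)
  } else if (is.data.frame(imputations)) {
    list(if (is.null(transform)) imputations else transform(imputations))
  } else {
    if (is.null(transform)) imputations else lapply(imputations, transform)
  }
  m <- length(sets)
  out_dc <- out_de <- matrix(NA_real_, nrow = B, ncol = m)
  for (d in seq_len(m)) {
    dat <- sets[[d]]
    cxy <- adjustment_xy(dat, cost_spec)
    exy <- adjustment_xy(dat, effect_spec)
    if (anyNA(cxy$y) || anyNA(exy$y)) {
      abort("Bootstrap outcomes contain missing values; impute first.")
    }
    X <- cxy$X
    p <- ncol(X)
    arm_vals <- dat[[cost_spec$arm]]
    strata <- split(seq_len(nrow(dat)), arm_vals)
    set.seed(derive_seed(seed, d, 31L))
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- if (resample) {
          unlist(lapply(strata, function(s) s[sample.int(length(s),
                                                         replace = TRUE)]),
                 use.names = FALSE)
        } else {
          seq_len(nrow(dat))
        }
        Xb <- X[idx, , drop = FALSE]
        fc <- .lm.fit(Xb, cxy$y[idx])
        if (fc$rank < p) {
          redraws <- redraws + 1L
          if (!resample || redraws > 100L) {
            abort("Singular fit persisted after 100 redraws.")
          }
          next
        }
        fe <- .lm.fit(Xb, exy$y[idx])
        out_dc[b, d] <- fc$coefficients[cxy$arm_col]
        out_de[b, d] <- fe$coefficients[exy$arm_col]
        break
      }
    }
  }
  cloud <- tibble::tibble(
    imputation = rep(seq_len(m), each = B),
    replicate = rep(seq_len(B), times = m),
    delta_cost = as.numeric(out_dc),
    delta_effect = as.numeric(out_de)
  )
  structure(cloud, class = c("boot_cloud", class(cloud)), B = B, m = m)
}

quadrant_of <- function(delta_effect, delta_cost) {
  # half-open convention: "> 0" vs "<= 0" on both axes
  ifelse(delta_effect > 0,
         ifelse(delta_cost > 0, "NE", "SE"),
         ifelse(delta_cost > 0, "NW", "SW"))
}

#' Incremental cost-effectiveness ratio
#'
#' The difference in costs divided by the difference in effects, with its
#' cost-effectiveness-plane quadrant and a dominance-aware interpretation.
#' A zero effect difference leaves the ratio undefined (flagged, not an
#' error).
#'
#' @param delta_cost Incremental cost (GBP).
#' @param delta_effect Incremental effect (QALYs, symptom points, ...).
#' @return One-row tibble: `delta_cost`, `delta_effect`, `icer`, `quadrant`,
#'   `interpretation`.
#' @examples
#' icer(7048, 0.032)
#' @export
icer <- function(delta_cost, delta_effect) {
  check_number(delta_cost, "delta_cost")
  check_number(delta_effect, "delta_effect")
  if (delta_effect == 0) {
    return(tibble::tibble(
      delta_cost = delta_cost, delta_effect = 0, icer = NA_real_,
      quadrant = NA_character_,
      interpretation = "undefined (no difference in effects)"
    ))
  }
  q <- quadrant_of(delta_effect, delta_cost)
  interp <- c(
    NE = "more effective and more costly",
    SE = "dominant (more effective, less costly)",
    NW = "dominated (less effective, more costly)",
    SW = "less effective and less costly"
  )[[q]]
  tibble::tibble(delta_cost = delta_cost, delta_effect = delta_effect,
                 icer = delta_cost / delta_effect, quadrant = q,
                 interpretation = interp)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of bootstrap
#' replicates whose net monetary benefit `lambda * delta_effect -
#' delta_cost` is strictly positive.
#'
#' @param cloud A `boot_cloud` (or any data frame with `delta_cost` and
#'   `delta_effect`).
#' @param lambdas Thresholds in GBP per effect unit (non-empty).
#' @return Tibble: `lambda`, `probability`.
#' @export
ceac <- function(cloud, lambdas = seq(0, 50000, by = 500)) {
  if (length(lambdas) == 0L) abort("`lambdas` must be non-empty.")
  if (nrow(cloud) == 0L) abort("`cloud` is empty.")
  tibble::tibble(
    lambda = as.numeric(lambdas),
    probability = vapply(lambdas, function(l) {
      mean(l * cloud$delta_effect - cloud$delta_cost > 0)
    }, numeric(1))
  )
}

#' Probability cost-effective at one threshold
#'
#' @inheritParams ceac
#' @param lambda Single willingness-to-pay threshold.
#' @return Proportion of replicates with positive net monetary benefit.
#' @export
prob_cost_effective <- function(cloud, lambda) {
  ceac(cloud, lambda)$probability
}

#' Quadrant shares of a bootstrap cloud
#'
#' Proportions of replicates in each cost-effectiveness-plane quadrant,
#' with exact zeros resolved by the half-open convention (`> 0` vs `<= 0`).
#'
#' @param cloud A `boot_cloud`.
#' @return One-row tibble with columns `ne`, `nw`, `se`, `sw` (summing to 1).
#' @export
quadrant_shares <- function(cloud) {
  if (nrow(cloud) == 0L) abort("`cloud` is empty.")
  q <- quadrant_of(cloud$delta_effect, cloud$delta_cost)
  tibble::tibble(
    ne = mean(q == "NE"), nw = mean(q == "NW"),
    se = mean(q == "SE"), sw = mean(q == "SW")
  )
}

# Column names of the two analysis outcomes for a given configuration.
outcome_columns <- function(horizon_months, effect, include_productivity) {
  if (!horizon_months %in% c(12, 18)) abort("`horizon_months` must be 12 or 18.")
  h <- as.character(horizon_months)
  cost <- if (include_productivity) paste0("societal_cost_", h) else
    paste0("total_cost_", h)
  eff <- switch(effect,
                qaly = paste0("qaly_", h),
                hrsd = paste0("hrsd_change_", h),
                abort("`effect` must be 'qaly' or 'hrsd'."))
  list(cost = cost, effect = eff)
}

#' Full incremental cost-effectiveness analysis
#'
#' The end-to-end estimator: choose the number of imputations from the
#' fraction of incomplete service-use records (unless given), impute by
#' chained equations, estimate covariate-adjusted incremental costs and
#' effects on each completed dataset and pool them, run the nested
#' non-parametric bootstrap (B resamples within each imputed copy),
#' and summarise as ICER, cost-effectiveness plane and acceptability
#' curve.
#'
#' @param data Analysis table from [build_analysis_table()] (missing
#'   aggregates allowed).
#' @param horizon_months 12 (primary) or 18.
#' @param effect `"qaly"` (cost-utility) or `"hrsd"` (cost per point
#'   improvement in the depression score).
#' @param covariates Pre-specified baseline adjustment set; the baseline
#'   values of cost, utility and the depression score are included by
#'   default.
#' @param m Number of imputations; default [choose_m()] applied to the
#'   fraction of incomplete 12-month records.
#' @param B Bootstrap replicates per imputed dataset.
#' @param n_cycles Chained-equation cycles.
#' @param seed Master seed for imputation and bootstrap streams.
#' @param lambdas Willingness-to-pay grid for the acceptability curve.
#' @param include_productivity Add absenteeism costs to the cost outcome
#'   (societal perspective scenario).
#' @param complete_case Drop incomplete participants instead of imputing.
#' @param resample Test hook; `FALSE` collapses the bootstrap to the point
#'   estimates.
#' @return Object of class `cea_result`.
#' @export
cea_analysis <- function(data,
                         horizon_months = 12,
                         effect = c("qaly", "hrsd"),
                         covariates = c("age", "female", "hrsd_m0", "u_m0",
                                        "cost_bl"),
                         m = NULL, B = 1000L, n_cycles = 10L, seed = 1L,
                         lambdas = seq(0, 50000, by = 500),
                         include_productivity = FALSE,
                         complete_case = FALSE,
                         resample = TRUE) {
  effect <- match.arg(effect)
  data <- tibble::as_tibble(data)
  cols <- outcome_columns(horizon_months, effect, include_productivity)
  frac <- fraction_incomplete(data)

  cost_spec <- adjustment_spec(cols$cost, covariates)
  effect_spec <- adjustment_spec(cols$effect, covariates)

  if (complete_case) {
    need <- unique(c(cols$cost, cols$effect, covariates))
    cc <- data[complete.cases(data[, need]), , drop = FALSE]
    sets <- list(finalise_analysis_table(cc))
    m_used <- 1L
  } else {
    base <- data[, setdiff(names(data), derived_columns()), drop = FALSE]
    # columns with no observed values cannot support a conditional model;
    # they are dropped here (scenarios needing them are skipped upstream)
    all_na <- vapply(base, function(x) all(is.na(x)), logical(1))
    base <- base[, !all_na, drop = FALSE]
    vars <- imputable_variables(base)
    m_used <- if (is.null(m)) choose_m(frac) else check_count(m, "m", min = 1)
    spec <- imputation_spec(
      vars,
      predictors = intersect(c("arm", "age", "female", "hrsd_m0", "u_m0",
                               "cost_bl", "intervention_cost", "employed"),
                             names(data)),
      m = m_used, n_cycles = n_cycles, seed = derive_seed(seed, 11L)
    )
    imp <- mice_impute(base, spec)
    sets <- complete_tables(imp, finalise_analysis_table)
  }

  est_c <- vapply(sets, function(s) {
    unlist(adjusted_difference(s, cost_spec)[c("estimate", "se")])
  }, numeric(2))
  est_e <- vapply(sets, function(s) {
    unlist(adjusted_difference(s, effect_spec)[c("estimate", "se")])
  }, numeric(2))

  if (m_used >= 2L) {
    pool_c <- rubin_pool(est_c[1, ], est_c[2, ]^2)
    pool_e <- rubin_pool(est_e[1, ], est_e[2, ]^2)
  } else {
    pool_c <- list(estimate = est_c[1, 1], se = est_c[2, 1],
                   variance = est_c[2, 1]^2, within = est_c[2, 1]^2,
                   between = 0, m = 1L, df = Inf)
    pool_e <- list(estimate = est_e[1, 1], se = est_e[2, 1],
                   variance = est_e[2, 1]^2, within = est_e[2, 1]^2,
                   between = 0, m = 1L, df = Inf)
  }

  cloud <- bootstrap_cloud(sets, cost_spec, effect_spec, B = B,
                           seed = derive_seed(seed, 17L), resample = resample)
  ci_cost <- unname(quantile(cloud$delta_cost, c(0.025, 0.975)))
  ci_effect <- unname(quantile(cloud$delta_effect, c(0.025, 0.975)))

  structure(
    list(delta_cost = pool_c$estimate, delta_cost_se = pool_c$se,
         delta_effect = pool_e$estimate, delta_effect_se = pool_e$se,
         icer = icer(pool_c$estimate, pool_e$estimate),
         ci_cost = ci_cost, ci_effect = ci_effect,
         cloud = cloud, ceac = ceac(cloud, lambdas),
         quadrant_shares = quadrant_shares(cloud),
         pooled_cost = pool_c, pooled_effect = pool_e,
         per_dataset = list(cost = est_c, effect = est_e),
         m = m_used, B = B, n = nrow(data),
         fraction_incomplete = frac,
         horizon_months = horizon_months, effect = effect,
         covariates = covariates,
         include_productivity = include_productivity,
         complete_case = complete_case, seed = seed),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  unit <- if (x$effect == "qaly") "QALY" else "HRSD point"
  cat("<cea_result>", x$horizon_months, "months,",
      if (x$complete_case) "complete case," else paste0("m = ", x$m, ","),
      "B =", x$B, "(", nrow(x$cloud), "replicates )\n")
  cat(sprintf("  delta cost:   %9.0f GBP  (95%% CI %0.0f to %0.0f)\n",
              x$delta_cost, x$ci_cost[1], x$ci_cost[2]))
  cat(sprintf("  delta effect: %9.4f %s (95%% CI %0.4f to %0.4f)\n",
              x$delta_effect, unit, x$ci_effect[1], x$ci_effect[2]))
  cat(sprintf("  ICER: %0.0f GBP per %s (%s)\n", x$icer$icer, unit,
              x$icer$interpretation))
  cat(sprintf("  P(cost-effective): %0.3f at 20000, %0.3f at 30000 GBP/%s\n",
              prob_cost_effective(x$cloud, 20000),
              prob_cost_effective(x$cloud, 30000), unit))
  invisible(x)
}

#' @rdname cea_analysis
#' @param x A `cea_result`.
#' @param ... Unused.
#' @export
tidy.cea_result <- function(x, ...) {
  tibble::tibble(
    term = c("delta_cost", "delta_effect", "icer"),
    estimate = c(x$delta_cost, x$delta_effect, x$icer$icer),
    std.error = c(x$delta_cost_se, x$delta_effect_se, NA_real_),
    conf.low = c(x$ci_cost[1], x$ci_effect[1], NA_real_),
    conf.high = c(x$ci_cost[2], x$ci_effect[2], NA_real_)
  )
}

#' @rdname cea_analysis
#' @export
glance.cea_result <- function(x, ...) {
  qs <- x$quadrant_shares
  tibble::tibble(
    delta_cost = x$delta_cost, delta_effect = x$delta_effect,
    icer = x$icer$icer,
    p_ce_20k = prob_cost_effective(x$cloud, 20000),
    p_ce_30k = prob_cost_effective(x$cloud, 30000),
    share_ne = qs$ne, share_nw = qs$nw, share_se = qs$se, share_sw = qs$sw,
    m = x$m, B = x$B, n_replicates = nrow(x$cloud), n = x$n,
    fraction_incomplete = x$fraction_incomplete,
    horizon_months = x$horizon_months, effect = x$effect
  )
}

#' Run the pre-specified sensitivity scenarios
#'
#' Re-runs the analysis under the five standard variations around the base
#' case: (1) complete case instead of imputation; (2) a broader perspective
#' adding absenteeism costs; (3) the group-session cost replaced by a flat
#' national rate per attended session; (4) an 18-month horizon; (5) the
#' depression score as the effect measure. Scenarios whose required columns
#' are absent are skipped with a logged reason.
#'
#' @param data Analysis table (masked aggregates allowed).
#' @param scenarios Subset of 1:5 to run (the base case always runs).
#' @param group_cost_per_session Flat GBP per attended group session for
#'   scenario 3.
#' @param ... Passed to [cea_analysis()] (covariates, B, m, seed, ...).
#' @return Tibble: `scenario`, `label`, `delta_cost`, `delta_effect`,
#'   `icer`, `p_ce_30k`, `skipped`, `reason`, and a `result` list-column of
#'   `cea_result`s.
#' @export
run_scenarios <- function(data, scenarios = 1:5,
                          group_cost_per_session = 14, ...) {
  defs <- list(
    list(id = 0L, label = "base case (12m, imputed, NHS/PSS, QALYs)",
         args = list()),
    list(id = 1L, label = "complete case",
         args = list(complete_case = TRUE)),
    list(id = 2L, label = "including absenteeism costs",
         args = list(include_productivity = TRUE)),
    list(id = 3L, label = "national group-session cost",
         args = list(substitute_group = TRUE)),
    list(id = 4L, label = "18-month horizon",
         args = list(horizon_months = 18)),
    list(id = 5L, label = "cost per HRSD point",
         args = list(effect = "hrsd"))
  )
  defs <- defs[c(TRUE, 1:5 %in% scenarios)]
  rows <- lapply(defs, function(def) {
    skipped <- FALSE; reason <- NA_character_; res <- NULL
    if (def$id == 5L &&
        (!"hrsd_m12" %in% names(data) || all(is.na(data$hrsd_m12)))) {
      skipped <- TRUE
      reason <- "depression scores absent from data"
    } else {
      dat <- data
      args <- def$args
      if (isTRUE(args$substitute_group)) {
        dat <- substitute_group_cost(dat, per_session = group_cost_per_session,
                                     basis = "attended")
        args$substitute_group <- NULL
      }
      res <- do.call(cea_analysis, c(list(data = dat), args, list(...)))
    }
    tibble::tibble(
      scenario = def$id, label = def$label,
      delta_cost = if (skipped) NA_real_ else res$delta_cost,
      delta_effect = if (skipped) NA_real_ else res$delta_effect,
      icer = if (skipped) NA_real_ else res$icer$icer,
      p_ce_30k = if (skipped) NA_real_ else
        prob_cost_effective(res$cloud, 30000),
      skipped = skipped, reason = reason,
      result = list(res)
    )
  })
  dplyr::bind_rows(rows)
}
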