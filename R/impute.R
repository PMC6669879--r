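#' Number of imputations from the fraction of incomplete records
#'
#' The rule of thumb that sets the number of imputed datasets roughly equal
#' to the percentage of incomplete cases: `m = round(100 * fraction)` with
#' half-up rounding, floored at 2 so pooling is always defined.
#'
#' @param fraction_incomplete Proportion in `[0, 1)`.
#' @return Integer `m`.
#' @examples
#' choose_m(0.30)
#' @export
choose_m <- function(fraction_incomplete) {
  check_number(fraction_incomplete, "fraction_incomplete", min = 0)
  if (fraction_incomplete >= 1) abort("`fraction_incomplete` must be < 1.")
  max(2L, as.integer(round_half_up(100 * fraction_incomplete)))
}

#' Imputation specification
#'
#' @param variables Character vector of incomplete variables to impute, or a
#'   named character vector/list mapping variable -> method (`"pmm"` for
#'   continuous via predictive mean matching, `"norm"` for a Bayesian
#'   linear-regression draw, `"logreg"` for binary).
#' @param predictors Complete covariates entering every conditional model
#'   (the other imputed variables' current values are always added).
#' @param m Number of imputed datasets.
#' @param n_cycles Chained-equation cycles per dataset.
#' @param k Donor pool size for predictive mean matching.
#' @param seed Master seed; each dataset gets an independent sub-stream.
#' @return A list of class `imputation_spec`.
#' @export
imputation_spec <- function(variables, predictors = character(),
                            m = 5L, n_cycles = 10L, k = 5L, seed = 1L) {
  if (is.list(variables)) variables <- unlist(variables)
  if (is.null(names(variables)) || all(names(variables) == "")) {
    methods <- rep("pmm", length(variables))
    names(methods) <- variables
  } else {
    methods <- variables
    variables <- names(variables)
  }
  bad <- setdiff(unique(methods), c("pmm", "norm", "logreg"))
  if (length(bad)) {
    abort(paste0("Unknown imputation method(s): ", paste(bad, collapse = ", ")))
  }
  m <- check_count(m, "m", min = 1)
  n_cycles <- check_count(n_cycles, "n_cycles", min = 1)
  k <- check_count(k, "k", min = 1)
  structure(
    list(variables = unname(variables), methods = methods,
         predictors = predictors, m = m, n_cycles = n_cycles, k = k,
         seed = check_count(seed, "seed", min = 0)),
    class = "imputation_spec"
  )
}

# Drop aliased columns so the linear system is full rank.
drop_aliased <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
  X
}

# Type-1 predictive mean matching: observed units predicted with the
# least-squares coefficients, missing units with a Bayesian posterior draw;
# each missing unit receives the observed value of one of the k nearest
# donors on the predicted metric.
pmm_draw <- function(Xo, yo, Xm, k) {
  if (sd(yo) == 0) return(rep(yo[1], nrow(Xm)))
  keep <- qr(Xo)$pivot[seq_len(qr(Xo)$rank)]
  Xo <- Xo[, keep, drop = FALSE]; Xm <- Xm[, keep, drop = FALSE]
  qrx <- qr(Xo)
  beta <- qr.coef(qrx, yo)
  res <- yo - Xo %*% beta
  df <- max(1L, nrow(Xo) - qrx$rank)
  sigma2 <- sum(res^2) / rchisq(1L, df)
  R <- qr.R(qrx)
  beta_draw <- beta + backsolve(R, rnorm(ncol(Xo))) * sqrt(sigma2)
  yhat_obs <- as.numeric(Xo %*% beta)
  yhat_mis <- as.numeric(Xm %*% beta_draw)
  kk <- min(k, length(yo))
  # nearest donors via one sort of the observed predictions: for each
  # missing unit only the 2k observed values bracketing its prediction can
  # be among the k closest
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  n_obs <- length(ys)
  pos <- findInterval(yhat_mis, ys)
  vapply(seq_along(yhat_mis), function(j) {
    lo <- max(1L, pos[j] - kk + 1L)
    hi <- min(n_obs, pos[j] + kk)
    cand <- lo:hi
    donors <- cand[order(abs(ys[cand] - yhat_mis[j]))[seq_len(kk)]]
    yo[ord[donors[sample.int(kk, 1L)]]]
  }, numeric(1))
}

# Bayesian linear-regression draw (normal conditional model).
norm_draw <- function(Xo, yo, Xm) {
  keep <- qr(Xo)$pivot[seq_len(qr(Xo)$rank)]
  Xo <- Xo[, keep, drop = FALSE]; Xm <- Xm[, keep, drop = FALSE]
  qrx <- qr(Xo)
  beta <- qr.coef(qrx, yo)
  res <- yo - Xo %*% beta
  df <- max(1L, nrow(Xo) - qrx$rank)
  sigma2 <- sum(res^2) / rchisq(1L, df)
  beta_draw <- beta + backsolve(qr.R(qrx), rnorm(ncol(Xo))) * sqrt(sigma2)
  as.numeric(Xm %*% beta_draw) + rnorm(nrow(Xm), 0, sqrt(sigma2))
}

# Logistic draw for binary variables: approximate posterior on the
# coefficients, then a Bernoulli draw per missing unit.
logreg_draw <- function(Xo, yo, Xm) {
  if (length(unique(yo)) < 2L) return(rep(yo[1], nrow(Xm)))
  keep <- qr(Xo)$pivot[seq_len(qr(Xo)$rank)]
  Xo <- Xo[, keep, drop = FALSE]; Xm <- Xm[, keep, drop = FALSE]
  fit <- suppressWarnings(glm.fit(Xo, yo, family = binomial()))
  beta <- fit$coefficients
  w <- fit$weights
  XtWX <- crossprod(Xo * sqrt(w))
  V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) diag(ncol(Xo)))
  beta_draw <- beta + as.numeric(t(chol(V)) %*% rnorm(ncol(Xo)))
  p <- plogis(as.numeric(Xm %*% beta_draw))
  rbinom(nrow(Xm), 1L, p)
}

#' Multiple imputation by chained equations
#'
#' Fills missing cells by cycling per-variable conditional models: each
#' incomplete variable is regressed on the complete predictors plus the
#' current values of the other incomplete variables, and its missing cells
#' are replaced by draws (predictive mean matching by default, which keeps
#' imputed costs on the observed support and respects their skew). The whole
#' cycle is repeated `n_cycles` times for each of `m` datasets with
#' independent sub-seeds. Observed cells are never altered.
#'
#' @param data Data frame whose missingness is confined to the declared
#'   variables.
#' @param spec An [imputation_spec()].
#' @return Object of class `imputation_set`: list with `imputations` (list
#'   of `m` completed tibbles), the `spec`, and per-dataset sub-seeds.
#' @export
mice_impute <- function(data, spec) {
  stopifnot(inherits(spec, "imputation_spec"))
  data <- tibble::as_tibble(data)
  vars <- spec$variables
  missing_elsewhere <- setdiff(names(which(vapply(data, anyNA, logical(1)))),
                               vars)
  if (length(missing_elsewhere)) {
    abort(paste0("Missing values outside declared variables: ",
                 paste(missing_elsewhere, collapse = ", ")))
  }
  miss <- lapply(setNames(vars, vars), function(v) which(is.na(data[[v]])))
  all_missing <- vars[vapply(vars, function(v) length(miss[[v]]) == nrow(data),
                             logical(1))]
  if (length(all_missing)) {
    abort(paste0("Variable(s) 100% missing, conditional model inestimable: ",
                 paste(all_missing, collapse = ", ")))
  }
  preds <- setdiff(spec$predictors, vars)
  absent <- setdiff(preds, names(data))
  if (length(absent)) {
    abort(paste0("Predictor(s) not in data: ", paste(absent, collapse = ", ")))
  }
  any_missing <- any(vapply(miss, length, integer(1)) > 0)
  sub_seeds <- vapply(seq_len(spec$m), function(d) derive_seed(spec$seed, d),
                      integer(1))

  sets <- vector("list", spec$m)
  for (d in seq_len(spec$m)) {
    work <- data
    if (any_missing) {
      set.seed(sub_seeds[d])
      for (v in vars) { # initialise from the observed margin
        idx <- miss[[v]]
        if (length(idx)) {
          obs <- data[[v]][-idx]
          work[[v]][idx] <- sample(obs, length(idx), replace = TRUE)
        }
      }
      for (cycle in seq_len(spec$n_cycles)) {
        for (v in vars) {
          idx <- miss[[v]]
          if (!length(idx)) next
          rhs <- c(preds, setdiff(vars, v))
          X <- model.matrix(~ ., data = work[, rhs, drop = FALSE])
          Xo <- X[-idx, , drop = FALSE]; Xm <- X[idx, , drop = FALSE]
          yo <- work[[v]][-idx]
          imp <- switch(spec$methods[[v]],
                        pmm = pmm_draw(Xo, yo, Xm, spec$k),
                        norm = norm_draw(Xo, yo, Xm),
                        logreg = logreg_draw(Xo, yo, Xm))
          work[[v]][idx] <- imp
        }
      }
    }
    sets[[d]] <- work
  }
  structure(list(imputations = sets, spec = spec, sub_seeds = sub_seeds,
                 miss = miss),
            class = "imputation_set")
}

#' Completed datasets from an imputation set
#'
#' @param imp An `imputation_set`.
#' @param transform Optional function applied to each completed copy (used
#'   to refresh derived columns, e.g. [finalise_analysis_table()]).
#' @return List of `m` tibbles.
#' @export
complete_tables <- function(imp, transform = NULL) {
  stopifnot(inherits(imp, "imputation_set"))
  out <- imp$imputations
  if (!is.null(transform)) out <- lapply(out, transform)
  out
}

#' @export
print.imputation_set <- function(x, ...) {
  n_miss <- sum(vapply(x$miss, length, integer(1)))
  cat("<imputation_set> m =", x$spec$m, "datasets,",
      length(x$spec$variables), "variables,", n_miss, "imputed cells\n")
  invisible(x)
}

#' Pool estimates across imputed datasets
#'
#' Combining rules for multiply imputed analyses: the pooled estimate is the
#' mean of the per-dataset estimates; the total variance adds the
#' between-imputation variance (inflated by `1 + 1/m`) to the mean
#' within-imputation variance.
#'
#' @param estimates Per-dataset point estimates (length `m >= 2`).
#' @param variances Per-dataset squared standard errors.
#' @return List: `estimate`, `variance`, `se`, `within`, `between`, `m`,
#'   `df` (the classical degrees of freedom; `Inf` when the between
#'   component is zero).
#' @examples
#' rubin_pool(c(1, 2, 3), c(0, 0, 0))
#' @export
rubin_pool <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2L) abort("Pooling needs at least 2 imputed datasets.")
  if (length(variances) != m) {
    abort("`estimates` and `variances` must have equal length.")
  }
  qbar <- mean(estimates)
  within <- mean(variances)
  between <- var(estimates)
  total <- within + (1 + 1 / m) * between
  df <- if (between > 0) {
    (m - 1) * (1 + within / ((1 + 1 / m) * between))^2
  } else {
    Inf
  }
  list(estimate = qbar, variance = total, se = sqrt(total),
       within = within, between = between, m = m, df = df)
}
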