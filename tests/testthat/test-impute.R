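test_that("the m rule rounds the incomplete percentage half-up with floor 2", {
  expect_equal(choose_m(0.30), 30L)
  expect_equal(choose_m(0), 2L)
  expect_equal(choose_m(0.125), 13L)
  expect_equal(choose_m(0.01), 2L)
  expect_error(choose_m(1), "< 1")
  expect_error(choose_m(-0.1), ">=")
})

test_that("pooling follows the combining rules exactly", {
  p <- rubin_pool(c(1, 2, 3), c(0, 0, 0))
  expect_equal(p$estimate, 2)
  expect_equal(p$between, 1)
  expect_equal(p$variance, 4 / 3)
  # identical estimates: between-variance zero, total = within
  p2 <- rubin_pool(c(5, 5, 5, 5), c(2, 2, 2, 2))
  expect_equal(p2$between, 0)
  expect_equal(p2$variance, 2)
  expect_equal(p2$df, Inf)
  expect_error(rubin_pool(1, 2), "at least 2")
  # hand formula on a general fixture
  est <- c(1.2, 0.8, 1.5); v <- c(0.3, 0.4, 0.5)
  p3 <- rubin_pool(est, v)
  expect_equal(p3$variance, mean(v) + (1 + 1 / 3) * var(est))
})

make_mar_table <- function(n, seed, slope = 1.5) {
  set.seed(seed)
  x <- rnorm(n)
  y <- 2 + 1.5 * x + rnorm(n)
  z <- 5 - x + rnorm(n)
  miss <- runif(n) < plogis(-1 + slope * x)
  tibble::tibble(x = x, y = ifelse(miss, NA, y), z = z)
}

test_that("a complete table yields m identical copies", {
  tab <- make_mar_table(50, 1)
  tab$y <- 1 # no missing anywhere
  spec <- imputation_spec("y", predictors = "x", m = 3, seed = 2)
  imp <- mice_impute(tab, spec)
  expect_length(imp$imputations, 3)
  for (cp in complete_tables(imp)) expect_identical(cp, tab)
})

test_that("observed cells are never altered and imputations vary", {
  tab <- make_mar_table(300, 3)
  spec <- imputation_spec("y", predictors = c("x", "z"), m = 4, seed = 5)
  imp <- mice_impute(tab, spec)
  obs <- which(!is.na(tab$y))
  mis <- which(is.na(tab$y))
  for (cp in complete_tables(imp)) {
    expect_identical(cp$y[obs], tab$y[obs])
    expect_identical(cp$x, tab$x)
    expect_false(anyNA(cp$y))
  }
  # between-dataset variability strictly positive on imputed cells
  drawn <- sapply(complete_tables(imp), function(cp) cp$y[mis])
  expect_gt(mean(apply(drawn, 1, sd)), 0)
  # reproducible under the same seed
  imp2 <- mice_impute(tab, spec)
  expect_identical(complete_tables(imp), complete_tables(imp2))
})

test_that("degenerate imputation requests fail loudly", {
  tab <- make_mar_table(50, 4)
  tab$y <- NA_real_
  expect_error(mice_impute(tab, imputation_spec("y", predictors = "x")),
               "100%")
  tab2 <- make_mar_table(50, 5)
  tab2$w <- ifelse(runif(50) < 0.2, NA, 1)
  expect_error(mice_impute(tab2, imputation_spec("y", predictors = "x")),
               "outside declared")
  expect_error(imputation_spec(c(y = "banana")), "Unknown")
})

test_that("MCAR imputation recovers the known mean within 3 pooled SE", {
  set.seed(11)
  n <- 2000
  x <- rnorm(n)
  y <- 3 + 2 * x + rnorm(n)
  miss <- runif(n) < 0.2
  tab <- tibble::tibble(x = x, y = ifelse(miss, NA, y))
  imp <- mice_impute(tab, imputation_spec("y", predictors = "x",
                                          m = 10, seed = 13))
  est <- vapply(complete_tables(imp), function(cp) mean(cp$y), numeric(1))
  vr <- vapply(complete_tables(imp), function(cp) var(cp$y) / n, numeric(1))
  pooled <- rubin_pool(est, vr)
  expect_lt(abs(pooled$estimate - 3), 3 * pooled$se)
})

test_that("under MAR the complete-case mean is biased and imputation
          corrects it", {
  tab <- make_mar_table(3000, 21)
  truth <- 2 # E[y] since E[x] = 0
  cc <- tab$y[!is.na(tab$y)]
  cc_se <- sd(cc) / sqrt(length(cc))
  expect_gt(abs(mean(cc) - truth), 3 * cc_se) # missingness tracks x, so bias
  imp <- mice_impute(tab, imputation_spec("y", predictors = c("x", "z"),
                                          m = 15, seed = 23))
  est <- vapply(complete_tables(imp), function(cp) mean(cp$y), numeric(1))
  vr <- vapply(complete_tables(imp),
               function(cp) var(cp$y) / nrow(cp), numeric(1))
  pooled <- rubin_pool(est, vr)
  expect_lt(abs(pooled$estimate - truth), 3 * pooled$se)
  expect_lt(abs(pooled$estimate - truth), abs(mean(cc) - truth))
})

test_that("binary variables impute through the logistic conditional", {
  set.seed(31)
  n <- 800
  x <- rnorm(n)
  b <- rbinom(n, 1, plogis(x))
  tab <- tibble::tibble(x = x,
                        b = ifelse(runif(n) < 0.25, NA, b))
  imp <- mice_impute(tab, imputation_spec(c(b = "logreg"), predictors = "x",
                                          m = 5, seed = 33))
  for (cp in complete_tables(imp)) {
    expect_true(all(cp$b %in% 0:1))
  }
  est <- vapply(complete_tables(imp), function(cp) mean(cp$b), numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.06)
})

test_that("as missingness vanishes pooled estimates approach complete-data
          estimates", {
  set.seed(41)
  n <- 1000
  x <- rnorm(n)
  y <- 1 + x + rnorm(n)
  full_mean <- mean(y)
  for (rate in c(0.02, 0.1)) {
    tab <- tibble::tibble(x = x, y = ifelse(seq_len(n) <= rate * n, NA, y))
    imp <- mice_impute(tab, imputation_spec("y", predictors = "x",
                                            m = 5, seed = 43))
    est <- mean(vapply(complete_tables(imp), function(cp) mean(cp$y),
                       numeric(1)))
    expect_lt(abs(est - full_mean), 0.2 * sqrt(rate / 0.02))
  }
})
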