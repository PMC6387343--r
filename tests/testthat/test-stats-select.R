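test_that("median dichotomization follows the >= tie rule", {
  out <- dichotomize_llfdi(data.frame(llfdi = c(60, 70, 80, 90)))
  expect_identical(as.character(out$group), c("HFS", "HFS", "VHFS", "VHFS"))
  # the median value itself is classified as very high functional status
  out2 <- dichotomize_llfdi(data.frame(llfdi = c(50, 60, 72.31, 80, 95)))
  expect_identical(as.character(out2$group[out2$llfdi == 72.31]), "VHFS")
  expect_error(dichotomize_llfdi(data.frame(llfdi = rep(70, 5))),
               class = "imuperf_config_error")
  # no ties at the median: group sizes differ by at most 1
  x <- withr::with_seed(2, runif(160, 44, 100))
  out3 <- dichotomize_llfdi(data.frame(llfdi = x))
  expect_lte(abs(diff(table(out3$group))), 1)
})

test_that("preprocessing log-transforms jerk scores and z-scores features", {
  tbl <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:6),
    cst_sts_njs_ap = exp(1:6),
    cst_sts_duration_mean = c(1, 1.2, 0.9, 1.4, 1.1, 1.3),
    cst30_repetitions_manual = c(10, 12, 14, 11, 13, 15)
  )
  pre <- preprocess_features(tbl)
  for (col in c("cst_sts_njs_ap", "cst_sts_duration_mean")) {
    expect_lt(abs(mean(pre[[col]])), 1e-12)
    expect_lt(abs(sd(pre[[col]]) - 1), 1e-12)
  }
  # the jerk column was logged before scaling: z-scores of 1..6
  expect_equal(pre$cst_sts_njs_ap, as.numeric(scale(1:6)), tolerance = 1e-12)
  # standard clinical measures pass through untouched
  expect_identical(pre$cst30_repetitions_manual, tbl$cst30_repetitions_manual)
  # non-positive jerk and constant columns are structured errors
  tbl_bad <- tbl
  tbl_bad$cst_sts_njs_ap[2] <- -1
  expect_error(preprocess_features(tbl_bad), regexp = "cst_sts_njs_ap",
               class = "imuperf_config_error")
  tbl_const <- tbl
  tbl_const$cst_sts_duration_mean <- 1
  expect_error(preprocess_features(tbl_const), class = "imuperf_config_error")
})

test_that("spline knots sit at the stated empirical quantiles", {
  x <- withr::with_seed(3, rnorm(200))
  y <- withr::with_seed(4, rbinom(200, 1, 0.5))
  res <- check_linearity_rcs(x, y)
  kn <- quantile(x, c(0.1, 0.5, 0.9), names = FALSE)
  expect_equal(c(res$knot1, res$knot2, res$knot3), kn, tolerance = 1e-12)
  expect_true(res$converged)
})

test_that("spline linearity check flags a strongly quadratic logit", {
  withr::with_seed(5, {
    x <- rnorm(2000)
    p <- stats::plogis(-1 + 1.5 * x^2)
    y <- rbinom(2000, 1, p)
  })
  res <- check_linearity_rcs(x, y)
  expect_lt(res$p_nonlinear, 0.05)
})

test_that("spline linearity check is calibrated under a linear logit", {
  # under a purely linear association the nonlinearity p-value is null
  pvals <- vapply(1:40, function(s) {
    withr::with_seed(1000 + s, {
      x <- rnorm(300)
      y <- rbinom(300, 1, stats::plogis(0.8 * x))
    })
    check_linearity_rcs(x, y)$p_nonlinear
  }, numeric(1))
  # type-I rate at 0.05 within a generous binomial band for 40 draws
  expect_lte(sum(pvals < 0.05, na.rm = TRUE), 7)
})

test_that("VIF pruning matches the brute-force regression oracle", {
  withr::with_seed(6, {
    n <- 200
    x1 <- rnorm(n); x2 <- rnorm(n)
    x3 <- x1 + x2 + rnorm(n, sd = 0.01)
    x4 <- rnorm(n)
    tbl <- tibble::tibble(x1 = x1, x2 = x2, x3 = x3, x4 = x4)
  })
  rep <- iterative_vif_prune(tbl)
  # exactly one member of the collinear triple removed; survivors clean
  expect_identical(nrow(rep$removed), 1L)
  expect_true(rep$removed$feature %in% c("x1", "x2", "x3"))
  expect_true(all(rep$vif_final < 10))
  expect_true("x4" %in% rep$surviving)
  # the computed VIFs agree with explicit per-feature R^2 regressions
  X <- as.matrix(tbl)
  expect_equal(unname(imuperf:::compute_vif(X)), oracle_vif(X),
               tolerance = 1e-10)
})

test_that("independent features survive pruning; duplicates go first", {
  tbl <- withr::with_seed(7, tibble::as_tibble(
    setNames(as.data.frame(matrix(rnorm(200 * 5), 200)), paste0("f", 1:5))))
  expect_identical(nrow(iterative_vif_prune(tbl)$removed), 0L)
  tbl$dup <- tbl$f1
  rep <- iterative_vif_prune(tbl)
  expect_identical(rep$removed$feature[1], "f1") # first of the pair in order
  expect_identical(rep$removed$vif[1], Inf)
})

test_that("univariable screen keeps discriminative features and is calibrated", {
  # strong feature: selected essentially always
  for (s in 1:5) {
    withr::with_seed(100 + s, {
      y <- rbinom(160, 1, 0.5)
      x <- rnorm(160, mean = y) # d = 1
    })
    scr <- univariable_screen(tibble::tibble(x = x), y)
    expect_true(scr$selected[scr$feature == "x"])
  }
  # null feature: selection rate near the nominal 15%
  hits <- vapply(1:100, function(s) {
    withr::with_seed(200 + s, {
      y <- rbinom(100, 1, 0.5)
      x <- rnorm(100)
    })
    univariable_screen(tibble::tibble(x = x), y)$selected[1]
  }, logical(1))
  expect_gte(mean(hits), 0.15 - 3 * sqrt(0.15 * 0.85 / 100))
  expect_lte(mean(hits), 0.15 + 3 * sqrt(0.15 * 0.85 / 100))
  # empty candidate set in, empty out
  scr0 <- univariable_screen(tibble::tibble(.rows = 10), rbinom(10, 1, 0.5))
  expect_identical(nrow(scr0), 0L)
  expect_identical(attr(scr0, "selected"), character(0))
})

test_that("a saturated 2x2 logistic model reproduces the ad/bc odds ratio", {
  x <- c(rep(1, 40), rep(0, 40))
  y <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  fit <- fit_logistic_model(tibble::tibble(x = x), y, "x")
  or <- fit$coefficients$odds_ratio[fit$coefficients$term == "x"]
  expect_equal(unname(or), 9, tolerance = 1e-6)
})

test_that("stepwise backward keeps the predictive feature and drops noise", {
  kept <- vapply(1:5, function(s) {
    withr::with_seed(300 + s, {
      n <- 500
      y <- rbinom(n, 1, 0.5)
      tbl <- tibble::as_tibble(setNames(
        as.data.frame(matrix(rnorm(n * 5), n)), paste0("null", 1:5)))
      tbl$signal <- rnorm(n, mean = 0.8 * y)
    })
    fit <- suppressWarnings(stepwise_backward(tbl, y))
    "signal" %in% fit$features
  }, logical(1))
  expect_gte(mean(kept), 0.8)
  # all-null candidates usually collapse to the intercept-only model
  empty <- vapply(1:10, function(s) {
    withr::with_seed(400 + s, {
      y <- rbinom(200, 1, 0.5)
      tbl <- tibble::as_tibble(setNames(
        as.data.frame(matrix(rnorm(200 * 3), 200)), paste0("n", 1:3)))
    })
    fit <- stepwise_backward(tbl, y)
    fit$intercept_only
  }, logical(1))
  expect_gte(mean(empty), 0.7)
})

test_that("glm coefficients agree with an independent likelihood optimizer", {
  withr::with_seed(8, {
    n <- 300
    X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
    y <- rbinom(n, 1, stats::plogis(0.5 * X[, 1] - 0.8 * X[, 3]))
  })
  fit <- fit_logistic_model(tibble::as_tibble(X), y, c("a", "b", "c"))
  beta_hat <- fit$coefficients$estimate
  beta_oracle <- oracle_logistic(X, y)
  expect_equal(unname(beta_hat), unname(beta_oracle), tolerance = 1e-6)
})

test_that("tidy and glance summarise a fitted model", {
  withr::with_seed(9, {
    y <- rbinom(120, 1, 0.5)
    tbl <- tibble::tibble(x = rnorm(120, 0.8 * y))
  })
  fit <- fit_logistic_model(tbl, y, "x")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "odds.ratio", "conf.low",
                    "conf.high", "p.value") %in% names(td)))
  expect_equal(td$odds.ratio, exp(td$estimate), tolerance = 1e-12)
  expect_true(all(td$conf.low <= td$conf.high))
  gl <- glance(fit)
  expect_identical(gl$nobs, 120L)
  expect_gte(gl$auc, 0.5)
})
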