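# a cohort-shaped table built from an explicit 2x2: 22 ISS (13 hypertensive),
# 40 without ISS (14 hypertensive)
hypertension_cohort <- tibble::tibble(
  hypertension = c(rep(1, 13), rep(0, 9), rep(1, 14), rep(0, 26)),
  iss = rep(c(1, 0), c(22, 40)),
  co = 0
)

test_that("the chi-square screen reproduces the hypertension association", {
  res <- univariate_screen(hypertension_cohort, "iss",
                           variables = "hypertension")
  expect_identical(res$test, "chi-square")
  expect_equal(res$p_value, 0.067, tolerance = 0.01)
  expect_identical(c(res$count_1, res$count_0), c(13L, 14L))
  expect_true(res$candidate) # 0.067 < 0.1 screening threshold
})

test_that("chi-square p-values match the chi-square survival function", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      x <- rbinom(60, 1, runif(1, 0.2, 0.8))
      y <- rbinom(60, 1, 0.5)
      tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1))
      if (any(outer(rowSums(tab), colSums(tab)) / sum(tab) < 5)) next
      res <- univariate_screen(tibble::tibble(v = x, iss = y, co = 0), "iss",
                               variables = "v")
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      stat <- sum((tab - expected)^2 / expected)
      expect_equal(res$p_value, pchisq(stat, 1, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  })
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  tables <- list(matrix(c(1, 2, 9, 8), 2), matrix(c(2, 1, 3, 12), 2),
                 matrix(c(5, 0, 6, 9), 2), matrix(c(3, 7, 8, 2), 2),
                 matrix(c(0, 4, 10, 11), 2))
  for (tab in tables) {
    p_pkg <- fisher.test(tab)$p.value
    expect_equal(p_pkg, enum_fisher(tab), tolerance = 1e-10)
    # and the screen picks Fisher for these small tables
    x <- rep(c(1, 0, 1, 0), as.vector(tab))
    y <- rep(c(1, 1, 0, 0), as.vector(tab))
    res <- univariate_screen(tibble::tibble(v = x, iss = y, co = 0), "iss",
                             variables = "v")
    expect_identical(res$test, "fisher")
    expect_equal(res$p_value, enum_fisher(table(factor(x, levels = 1:0),
                                                factor(y, levels = 1:0))),
                 tolerance = 1e-10)
  }
})

test_that("identical groups give p = 1 and constants warn", {
  co <- tibble::tibble(v = rep(1:10, 4), iss = rep(0:1, each = 20), co = 0)
  res <- univariate_screen(co, "iss", variables = "v")
  expect_equal(res$p_value, 1)
  expect_warning(
    univariate_screen(tibble::tibble(v = rep(1, 40), iss = rep(0:1, 20),
                                     co = 0), "iss", variables = "v"),
    "constant")
})

test_that("pooled-variance is the default and Welch differs", {
  withr::with_seed(2, {
    co <- tibble::tibble(v = c(rnorm(15, 0, 1), rnorm(25, 0.8, 3)),
                         iss = rep(c(0, 1), c(15, 25)), co = 0)
  })
  p_pooled <- univariate_screen(co, "iss", variables = "v")$p_value
  p_welch <- univariate_screen(co, "iss", variables = "v",
                               welch = TRUE)$p_value
  expect_equal(p_pooled, t.test(v ~ iss, co, var.equal = TRUE)$p.value)
  expect_false(isTRUE(all.equal(p_pooled, p_welch)))
})

test_that("collinearity filter collapses duplicated metrics", {
  co <- make_cohort(62, seed = 3)
  kept <- collinearity_filter(co, c("max_curvature", "range_curvature"))
  expect_identical(kept, "max_curvature")
  # orthogonal features all survive
  withr::with_seed(4, {
    ortho <- tibble::tibble(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  })
  expect_identical(collinearity_filter(ortho, c("a", "b", "c")),
                   c("a", "b", "c"))
  # three mutually collinear features leave exactly one
  tri <- tibble::tibble(a = 1:50, b = 2 * (1:50) + 0.5, c = -3 * (1:50))
  expect_length(collinearity_filter(tri, c("a", "b", "c")), 1)
  # the smaller univariate p wins within a pair
  expect_identical(
    collinearity_filter(tri, c("a", "b"), p_values = c(a = 0.5, b = 0.01)),
    "b")
})

test_that("logistic ORs recover the generator truth at large n", {
  co <- make_cohort(2000, iss_prevalence = 0.355,
                    coef = c(max_curvature = 0.0807), seed = 7)
  fit <- suppressWarnings(fit_logistic(co, "max_curvature", "iss"))
  or <- fit$odds_ratio[fit$variable == "max_curvature"]
  expect_gt(or, 1.05)
  expect_lt(or, 1.12)
  expect_true(all(fit$conf_low <= fit$odds_ratio &
                    fit$odds_ratio <= fit$conf_high))
  expect_equal(fit$odds_ratio, exp(fit$estimate))
})

test_that("a single binary predictor reproduces the cross-product ratio", {
  tab <- hypertension_cohort
  fit <- suppressWarnings(fit_logistic(tab, "hypertension", "iss"))
  or <- fit$odds_ratio[fit$variable == "hypertension"]
  expect_equal(or, (13 * 26) / (9 * 14), tolerance = 1e-6)
})

test_that("Wald CIs achieve near-nominal coverage in simulation", {
  hits <- vapply(1:200, function(i) {
    co <- make_cohort(500, iss_prevalence = 0.355,
                      coef = c(max_curvature = 0.0807), seed = 3000 + i)
    fit <- suppressWarnings(fit_logistic(co, "max_curvature", "iss"))
    row <- fit[fit$variable == "max_curvature", ]
    row$conf_low <= 1.084 && 1.084 <= row$conf_high
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("null-coefficient fits are calibrated (|z| < 1.96 about 95%)", {
  sig <- vapply(1:200, function(i) {
    co <- make_cohort(200, iss_prevalence = 0.355,
                      coef = c(max_curvature = 0), seed = 4000 + i)
    fit <- suppressWarnings(fit_logistic(co, "max_curvature", "iss"))
    fit$p_value[fit$variable == "max_curvature"] < 0.05
  }, logical(1))
  expect_lt(mean(sig), 0.10)
})

test_that("perfect separation raises an error naming the variable", {
  co <- tibble::tibble(v = c(1:10, 21:30), iss = rep(0:1, each = 10), co = 0)
  expect_error(suppressWarnings(fit_logistic(co, "v", "iss")),
               "separation.*`v`")
  expect_error(fit_logistic(tibble::tibble(v = 1:10, iss = 1, co = 0),
                            "v", "iss"), "single class")
})

test_that("AUC equals brute-force pair counting on random instances", {
  expect_equal(roc_evaluate(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  withr::with_seed(6, {
    for (rep in 1:25) {
      n <- sample(10:50, 1)
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      s <- sample(seq(0, 1, 0.05), n, replace = TRUE) # forces ties
      expect_equal(roc_evaluate(s, y)$auc, brute_auc(s, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("perfect and null scores bracket the AUC", {
  r <- roc_evaluate(c(rep(0, 20), rep(1, 20)), rep(c(0, 1), each = 20))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  withr::with_seed(8, {
    s <- runif(2000)
    y <- rbinom(2000, 1, 0.5)
  })
  expect_lt(abs(roc_evaluate(s, y)$auc - 0.5), 0.03)
  expect_error(roc_evaluate(1:5, rep(1, 5)), "both classes")
})

test_that("the chosen cutoff maximizes Youden's J", {
  withr::with_seed(9, {
    s <- c(rnorm(50, 0), rnorm(50, 1.5))
    y <- rep(0:1, each = 50)
  })
  r <- roc_evaluate(s, y)
  expect_equal(max(r$curve$youden_j), r$sensitivity + r$specificity - 1,
               tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(10, {
    s <- runif(80)
    y <- rbinom(80, 1, 0.5)
  })
  expect_equal(roc_evaluate(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("run_inference chains screen, filter, fit and ROC", {
  co <- make_cohort(300, iss_prevalence = 0.355, seed = 12)
  res <- suppressWarnings(run_inference(co, "iss"))
  expect_true(all(res$retained %in% names(co)))
  expect_false(all(c("max_curvature", "range_curvature") %in% res$retained))
  expect_s3_class(res$model, "vt_logistic")
  expect_gt(res$roc$auc, 0.5)
})
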