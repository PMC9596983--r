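test_that("z-scoring uses the population-SD convention and stores transform", {
  out <- standardize(tibble::tibble(a = c(1, 2, 3)))
  expect_equal(out$a, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  tr <- attr(out, "transform")
  again <- apply_standardize(tr, tibble::tibble(a = c(1, 2, 3)))
  expect_equal(mean(again$a), 0, tolerance = 1e-12)
})

test_that("the stored transform does not leak into shifted test data", {
  withr::with_seed(1, {
    train <- tibble::tibble(a = rnorm(100), b = rnorm(100))
  })
  ztr <- standardize(train)
  tr <- attr(ztr, "transform")
  shifted <- tibble::tibble(a = train$a + 3, b = train$b)
  zte <- apply_standardize(tr, shifted)
  expect_gt(abs(mean(zte$a)), 2) # the shift survives: no re-fitting on test
  expect_equal(mean(zte$b), mean(ztr$b), tolerance = 1e-12)
})

test_that("zero-variance columns are dropped with a warning", {
  expect_warning(out <- standardize(tibble::tibble(a = rep(2, 5), b = 1:5)),
                 "zero-variance")
  expect_false("a" %in% names(out))
})

test_that("balanced input passes through borderline-SMOTE unchanged", {
  X <- tibble::tibble(a = rnorm(20), b = rnorm(20))
  y <- rep(0:1, each = 10)
  res <- borderline_smote(X, y, k = 3, seed = 1)
  expect_identical(res$X, X)
  expect_identical(res$y, y)
})

test_that("SMOTE balances classes exactly and stays in the minority hull", {
  for (seed in 1:100) {
    withr::with_seed(seed, {
      X <- tibble::tibble(a = c(rnorm(30), rnorm(12, 1.5)),
                          b = c(rnorm(30), rnorm(12, 1.5)))
    })
    y <- rep(c(0, 1), c(30, 12))
    res <- suppressWarnings(borderline_smote(X, y, k = 5, seed = seed))
    expect_identical(sum(res$y == 1), sum(res$y == 0))
    prov <- res$provenance
    synth <- res$X[-seq_len(42), ]
    for (col in c("a", "b")) {
      lo <- pmin(X[[col]][prov$parent], X[[col]][prov$neighbor])
      hi <- pmax(X[[col]][prov$parent], X[[col]][prov$neighbor])
      expect_true(all(synth[[col]] >= lo - 1e-12 & synth[[col]] <= hi + 1e-12))
    }
    expect_true(all(y[prov$parent] == 1, y[prov$neighbor] == 1))
  }
})

test_that("noise minority points are never synthesis seeds", {
  # two tight clusters far apart; one minority point isolated deep inside the
  # majority cluster has all k neighbours majority -> noise
  X <- tibble::tibble(
    a = c(rnorm(30, 0, 0.1), 0, rnorm(10, 5, 0.1)),
    b = c(rnorm(30, 0, 0.1), 0, rnorm(10, 5, 0.1))
  )
  y <- c(rep(0, 30), 1, rep(1, 10))
  res <- suppressWarnings(borderline_smote(X, y, k = 5, seed = 3))
  expect_false(31L %in% res$provenance$parent)
})

test_that("SMOTE rejects a minority class smaller than k + 1", {
  X <- tibble::tibble(a = rnorm(20), b = rnorm(20))
  y <- rep(c(0, 1), c(17, 3))
  expect_error(borderline_smote(X, y, k = 5, seed = 1), "k \\+ 1")
})

test_that("RFE recovers planted informative features", {
  hits <- vapply(1:50, function(i) {
    withr::with_seed(i, {
      X <- as.data.frame(matrix(rnorm(1000 * 10), 1000, 10))
      names(X) <- c(paste0("inf", 1:5), paste0("noise", 1:5))
      eta <- as.matrix(X[, 1:5]) %*% rep(0.8, 5)
      y <- rbinom(1000, 1, plogis(eta))
    })
    sel <- rfe(X, y, n_target = 5)
    sum(paste0("inf", 1:5) %in% sel)
  }, numeric(1))
  expect_gte(mean(hits >= 4), 0.90)
})

test_that("RFE identity and duplicate-column behaviour", {
  withr::with_seed(2, {
    X <- tibble::tibble(a = rnorm(100), b = rnorm(100))
    y <- rbinom(100, 1, plogis(X$a))
  })
  expect_identical(rfe(X, y, n_target = 2), c("a", "b"))
  expect_warning(sel <- rfe(X, y, n_target = 5), ">=")
  expect_identical(sel, c("a", "b"))
  # duplicated column: exactly one survives, earlier column preferred
  X2 <- tibble::tibble(a = X$a, a_copy = X$a, b = X$b)
  sel2 <- rfe(X2, y, n_target = 2)
  expect_identical(sum(c("a", "a_copy") %in% sel2), 1L)
  expect_true("a" %in% sel2)
})

test_that("a separable cohort yields test AUC 1 for the best model", {
  withr::with_seed(3, {
    co <- tibble::tibble(
      f1 = rnorm(120), f2 = rnorm(120), iss = NA, co = 0
    )
    co$iss <- as.integer(co$f1 > 0.2)
  })
  cfg <- benchmark_config(features = c("f1", "f2"), folds = 5,
                          models = list(logistic = model_logistic()),
                          seed = 5)
  b <- suppressWarnings(run_benchmark(co, cfg))
  expect_equal(max(b$reports$test_auc), 1)
})

test_that("label-permuted cohorts give chance-level test AUC for all models", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("glmnet")
  skip_if_not_installed("ranger")
  skip_if_not_installed("xgboost")
  co <- make_cohort(400, iss_prevalence = 0.355, seed = 21)
  co$iss <- withr::with_seed(22, sample(co$iss)) # break all associations
  cfg <- benchmark_config(
    features = iss_predictor_preset(), folds = 5,
    models = list(logistic = model_logistic(),
                  enet = model_enet(grid = list(list(alpha = 0.5, lambda = 0.01))),
                  svm = model_svm(grid = list(list(cost = 1, gamma = 0.1))),
                  rf = model_rf(grid = list(list(mtry_frac = 0.5, min_node = 5))),
                  xgb = model_xgb(grid = list(list(max_depth = 3, eta = 0.3)))),
    seed = 23)
  b <- suppressWarnings(run_benchmark(co, cfg))
  expect_true(all(abs(b$reports$test_auc - 0.5) <= 0.1))
})

test_that("identical seeds and configs give bitwise-identical reports", {
  co <- make_cohort(150, iss_prevalence = 0.355, seed = 31)
  cfg <- benchmark_config(features = iss_predictor_preset(), folds = 5,
                          rfe_target = 4,
                          models = list(logistic = model_logistic(),
                                        rf = model_rf(grid = list(list(mtry_frac = 0.5,
                                                                       min_node = 5)))),
                          seed = 33)
  b1 <- suppressWarnings(run_benchmark(co, cfg))
  b2 <- suppressWarnings(run_benchmark(co, cfg))
  expect_identical(b1$reports, b2$reports)
})

test_that("train-only SMOTE never synthesizes from test rows", {
  co <- make_cohort(150, iss_prevalence = 0.3, seed = 41)
  cfg <- benchmark_config(features = iss_predictor_preset(), folds = 5,
                          smote_placement = "train_only",
                          models = list(logistic = model_logistic()),
                          seed = 43)
  b <- suppressWarnings(run_benchmark(co, cfg))
  # provenance indices refer to rows of the TRAINING partition only, whose
  # size is n - |test|; all parents must lie inside it
  n_train <- 150 - length(b$provenance$test_rows)
  expect_true(all(b$provenance$smote$parent <= n_train))
  expect_true(all(b$provenance$smote$neighbor <= n_train))
  expect_identical(sum(b$provenance$smote$parent < 1), 0L)
})

test_that("stratified folding fails loudly when a class is too small", {
  expect_error(vesseltort:::make_stratified_folds(rep(c(0, 1), c(36, 4)), 10, 1),
               "stratified")
  # and the benchmark surfaces the SMOTE minimum when the minority is tiny
  co <- tibble::tibble(f1 = rnorm(40), iss = rep(c(0, 1), c(36, 4)), co = 0)
  cfg <- benchmark_config(features = "f1", folds = 10, smote_k = 5,
                          models = list(logistic = model_logistic()),
                          seed = 5)
  expect_error(suppressWarnings(run_benchmark(co, cfg)), "minority")
})

test_that("YAML configs construct the equivalent benchmark config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "features: [height, DM, max_curvature]",
    "outcome: iss",
    "split:", "  test_fraction: 0.25",
    "cv:", "  folds: 4",
    "smote:", "  k: 3", "  placement: before_split",
    "rfe:", "  n_target: 2",
    "models:",
    "  logistic: {}",
    "seed: 17"), f)
  cfg <- read_benchmark_config(f)
  expect_identical(cfg$folds, 4L)
  expect_identical(cfg$smote_placement, "before_split")
  expect_identical(cfg$rfe_target, 2L)
  expect_identical(names(cfg$models), "logistic")
  co <- make_cohort(120, iss_prevalence = 0.35, seed = 51)
  b <- suppressWarnings(run_benchmark(co, cfg))
  expect_identical(nrow(b$reports), 1L)
})

test_that("tidiers and plots expose benchmark results", {
  co <- make_cohort(100, iss_prevalence = 0.35, seed = 61)
  cfg <- benchmark_config(features = c("max_curvature", "DM"), folds = 4,
                          models = list(logistic = model_logistic()), seed = 63)
  b <- suppressWarnings(run_benchmark(co, cfg))
  expect_identical(generics::tidy(b), b$reports)
  gl <- generics::glance(b)
  expect_identical(gl$n_models, 1L)
  p <- ggplot2::autoplot(b)
  expect_s3_class(p, "ggplot")
  d <- withr::local_tempdir()
  write_benchmark(b, d)
  expect_true(file.exists(file.path(d, "model_reports.csv")))
  expect_true(file.exists(file.path(d, "provenance.yaml")))
})
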