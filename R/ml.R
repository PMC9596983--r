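#' Z-score standardization with a stored transform
#'
#' Learns per-column centers and scales on a fitting partition and applies
#' them unchanged to any other partition, so no information leaks from
#' held-out data into the preprocessing. The scale is the population
#' standard deviation (divisor `n`), so `c(1, 2, 3)` maps to
#' `c(-1.2247, 0, 1.2247)`.
#'
#' Binary 0/1 columns are left untouched by default. A column with zero SD
#' on the fitting partition is dropped with a warning.
#'
#' @param data Data frame of features (fitting partition).
#' @param columns Columns to standardize; default every numeric non-0/1
#'   column.
#' @return `standardize()`: the transformed tibble with the transform
#'   attached as attribute `transform` (a `vt_zscore`).
#'   `apply_standardize()`: a tibble with the stored transform applied.
#' @examples
#' tr <- standardize(tibble::tibble(a = c(1, 2, 3)))
#' apply_standardize(attr(tr, "transform"), tibble::tibble(a = c(4, 5)))
#' @export
standardize <- function(data, columns = NULL) {
  data <- tibble::as_tibble(data)
  if (is.null(columns)) {
    columns <- names(data)[vapply(data, function(x) {
      is.numeric(x) && !all(x %in% c(0, 1))
    }, logical(1))]
  }
  center <- vapply(columns, function(cl) mean(data[[cl]]), numeric(1))
  n <- nrow(data)
  scale <- vapply(columns, function(cl) {
    stats::sd(data[[cl]]) * sqrt((n - 1) / n)
  }, numeric(1))
  dead <- columns[scale == 0 | !is.finite(scale)]
  if (length(dead) > 0) {
    warning("Dropping zero-variance column(s): ",
            paste(dead, collapse = ", "), call. = FALSE)
    data <- data[, setdiff(names(data), dead)]
    keep <- !(columns %in% dead)
    columns <- columns[keep]
    center <- center[keep]
    scale <- scale[keep]
  }
  transform <- structure(list(columns = columns, center = center,
                              scale = scale, dropped = dead),
                         class = "vt_zscore")
  out <- apply_standardize(transform, data)
  attr(out, "transform") <- transform
  out
}

#' @rdname standardize
#' @param transform A `vt_zscore` returned by `standardize()`.
#' @export
apply_standardize <- function(transform, data) {
  stopifnot(inherits(transform, "vt_zscore"))
  data <- tibble::as_tibble(data)
  data <- data[, setdiff(names(data), transform$dropped)]
  for (i in seq_along(transform$columns)) {
    cl <- transform$columns[i]
    data[[cl]] <- (data[[cl]] - transform$center[i]) / transform$scale[i]
  }
  data
}

#' Borderline-SMOTE oversampling of the minority class
#'
#' Implements Borderline-SMOTE (variant 1). A minority point is *in danger*
#' when, among its `k` nearest neighbours over the whole sample, the number
#' of majority points `m` satisfies `k/2 <= m < k`; points with all `k`
#' neighbours in the majority class are treated as noise and never used as
#' synthesis seeds. Synthetic points are drawn uniformly at random on the
#' segment between a danger point and one of its `k` nearest minority-class
#' neighbours, cycling through the danger points until the classes balance
#' exactly.
#'
#' If no minority point qualifies as borderline, all non-noise minority
#' points are used as seeds instead (with a warning), so balancing still
#' succeeds.
#'
#' @param X Data frame or matrix of numeric features.
#' @param y Binary 0/1 outcome vector.
#' @param k Neighbour count for both the danger test and the synthesis
#'   pool.
#' @param seed Integer seed for the random gaps and neighbour picks.
#' @return A list with `X` (tibble, original rows then synthetic rows), `y`,
#'   and `provenance`: tibble with one row per synthetic point (`parent`,
#'   `neighbor` original-row indices and the interpolation `gap`).
#' @examples
#' set.seed(7)
#' X <- tibble::tibble(a = c(rnorm(30), rnorm(10, 2)),
#'                     b = c(rnorm(30), rnorm(10, 2)))
#' y <- rep(c(0, 1), c(30, 10))
#' res <- borderline_smote(X, y, k = 5, seed = 1)
#' table(res$y)
#' @export
borderline_smote <- function(X, y, k = 5, seed = 1) {
  X <- tibble::as_tibble(X)
  stopifnot(all(y %in% c(0, 1)), nrow(X) == length(y))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == n0) {
    return(list(X = X, y = y,
                provenance = tibble::tibble(parent = integer(),
                                            neighbor = integer(),
                                            gap = numeric())))
  }
  minority <- if (n1 < n0) 1 else 0
  min_idx <- which(y == minority)
  if (length(min_idx) < k + 1) {
    stop("Borderline-SMOTE needs at least k + 1 = ", k + 1,
         " minority samples; got ", length(min_idx), ".", call. = FALSE)
  }
  M <- as.matrix(X)
  D <- as.matrix(stats::dist(M))
  diag(D) <- Inf

  # danger test over neighbours of ANY class
  m_majority <- vapply(min_idx, function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    sum(y[nb] != minority)
  }, numeric(1))
  danger <- min_idx[m_majority >= k / 2 & m_majority < k]
  noise <- min_idx[m_majority == k]
  if (length(danger) == 0) {
    warning("No borderline minority points; seeding from all non-noise ",
            "minority points.", call. = FALSE)
    danger <- setdiff(min_idx, noise)
    if (length(danger) == 0) danger <- min_idx
  }

  # k nearest minority neighbours of each seed
  Dmin <- D[, min_idx, drop = FALSE]
  need <- abs(n0 - n1)
  withr::with_seed(as.integer(seed), {
    seeds <- rep_len(danger, need)
    synth <- matrix(NA_real_, need, ncol(M))
    prov <- tibble::tibble(parent = integer(need), neighbor = integer(need),
                           gap = numeric(need))
    for (s in seq_len(need)) {
      i <- seeds[s]
      nbs <- min_idx[order(Dmin[i, ])][seq_len(min(k, length(min_idx) - 1L))]
      j <- nbs[sample.int(length(nbs), 1)]
      gap <- stats::runif(1)
      synth[s, ] <- M[i, ] + gap * (M[j, ] - M[i, ])
      prov$parent[s] <- i
      prov$neighbor[s] <- j
      prov$gap[s] <- gap
    }
    Xs <- tibble::as_tibble(as.data.frame(synth))
    names(Xs) <- names(X)
    list(X = dplyr::bind_rows(X, Xs), y = c(y, rep(minority, need)),
         provenance = prov)
  })
}

#' Recursive feature elimination
#'
#' Iteratively refits the model and drops the feature with the smallest
#' importance (absolute coefficient for linear models) until `n_target`
#' features remain. Ties — including exactly duplicated columns, which leave
#' one coefficient aliased — are broken by column order: the later column is
#' dropped first.
#'
#' @param X Data frame of features.
#' @param y Binary 0/1 outcome.
#' @param n_target Number of features to retain.
#' @param model A model spec from [model_logistic()] or compatible; must
#'   provide an `importance` function.
#' @param seed Seed passed to stochastic models.
#' @return Character vector of selected feature names, in original column
#'   order.
#' @export
rfe <- function(X, y, n_target, model = model_logistic(), seed = 1) {
  X <- tibble::as_tibble(X)
  if (is.null(model$importance)) {
    stop("Model spec has no importance function; RFE needs one.",
         call. = FALSE)
  }
  if (n_target >= ncol(X)) {
    if (n_target > ncol(X)) {
      warning("`n_target` >= number of features; returning all.",
              call. = FALSE)
    }
    return(names(X))
  }
  keep <- names(X)
  while (length(keep) > n_target) {
    fit <- withr::with_seed(as.integer(seed),
                            model$fit(X[, keep, drop = FALSE], y,
                                      model$default_params))
    imp <- model$importance(fit)
    imp <- imp[match(keep, names(imp))]
    imp[is.na(imp)] <- -Inf  # aliased/duplicated columns go first
    # ties broken by dropping the later column
    worst <- max(which(imp == min(imp)))
    keep <- keep[-worst]
  }
  keep
}

#' Pluggable classifier specs for the benchmark
#'
#' Each spec is a list with `name`, `fit(X, y, params)`,
#' `predict_prob(fit, X)`, optional `importance(fit)`, a `grid` of
#' hyperparameter combinations searched by cross-validation, and
#' `default_params`. Logistic regression is native; the other families wrap
#' the corresponding packages (`glmnet`, `e1071`, `ranger`, `xgboost`) and
#' error early when the package is not installed.
#'
#' @param grid Optional list of named parameter lists overriding the
#'   default hyperparameter grid.
#' @return A `vt_model_spec` list.
#' @name model_specs
NULL

new_model_spec <- function(name, fit, predict_prob, importance = NULL,
                           grid = list(list()), default_params = list()) {
  structure(list(name = name, fit = fit, predict_prob = predict_prob,
                 importance = importance, grid = grid,
                 default_params = default_params),
            class = "vt_model_spec")
}

#' @rdname model_specs
#' @export
model_logistic <- function(grid = NULL) {
  new_model_spec(
    "logistic",
    fit = function(X, y, params) {
      df <- as.data.frame(X)
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()))
    },
    predict_prob = function(fit, X) {
      as.numeric(stats::predict(fit, newdata = as.data.frame(X),
                                type = "response"))
    },
    importance = function(fit) {
      cf <- stats::coef(fit)
      abs(cf[setdiff(names(cf), "(Intercept)")])
    },
    grid = if (is.null(grid)) list(list()) else grid
  )
}

#' @rdname model_specs
#' @export
model_enet <- function(grid = NULL) {
  if (!requireNamespace("glmnet", quietly = TRUE)) {
    stop("Package glmnet is required for the elastic-net model.",
         call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- param_grid(list(alpha = c(0.2, 0.5, 0.8),
                            lambda = c(0.001, 0.01, 0.1)))
  }
  new_model_spec(
    "elastic_net",
    fit = function(X, y, params) {
      alpha <- params$alpha %||% 0.5
      lambda <- params$lambda %||% 0.01
      glmnet::glmnet(as.matrix(X), y, family = "binomial", alpha = alpha,
                     lambda = lambda)
    },
    predict_prob = function(fit, X) {
      as.numeric(stats::predict(fit, newx = as.matrix(X), type = "response"))
    },
    importance = function(fit) {
      cf <- as.matrix(stats::coef(fit))[, 1]
      abs(cf[setdiff(names(cf), "(Intercept)")])
    },
    grid = grid,
    default_params = list(alpha = 0.5, lambda = 0.01)
  )
}

#' @rdname model_specs
#' @export
model_svm <- function(grid = NULL) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("Package e1071 is required for the SVM model.", call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- param_grid(list(cost = c(0.1, 1, 10), gamma = c(0.05, 0.2)))
  }
  new_model_spec(
    "svm",
    fit = function(X, y, params) {
      e1071::svm(as.matrix(X), factor(y, levels = c(0, 1)),
                 kernel = "radial", cost = params$cost %||% 1,
                 gamma = params$gamma %||% (1 / ncol(X)),
                 probability = TRUE)
    },
    predict_prob = function(fit, X) {
      pr <- stats::predict(fit, as.matrix(X), probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    grid = grid,
    default_params = list(cost = 1)
  )
}

#' @rdname model_specs
#' @export
model_rf <- function(grid = NULL) {
  if (!requireNamespace("ranger", quietly = TRUE)) {
    stop("Package ranger is required for the random-forest model.",
         call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- param_grid(list(mtry_frac = c(0.3, 0.6), min_node = c(1, 5)))
  }
  new_model_spec(
    "random_forest",
    fit = function(X, y, params) {
      df <- as.data.frame(X)
      df$.y <- factor(y, levels = c(0, 1))
      ranger::ranger(.y ~ ., data = df, probability = TRUE,
                     num.trees = params$num_trees %||% 300,
                     mtry = max(1L, floor((params$mtry_frac %||% 0.5) * ncol(X))),
                     min.node.size = params$min_node %||% 1,
                     num.threads = 1, seed = params$seed %||% 1)
    },
    predict_prob = function(fit, X) {
      stats::predict(fit, data = as.data.frame(X),
                     num.threads = 1)$predictions[, "1"]
    },
    grid = grid,
    default_params = list(num_trees = 300)
  )
}

#' @rdname model_specs
#' @export
model_xgb <- function(grid = NULL) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("Package xgboost is required for the XGBoost model.", call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- param_grid(list(max_depth = c(2, 4), eta = c(0.1, 0.3)))
  }
  new_model_spec(
    "xgboost",
    fit = function(X, y, params) {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1,
                      max_depth = params$max_depth %||% 3,
                      eta = params$eta %||% 0.3),
        data = dtrain, nrounds = params$nrounds %||% 50, verbose = 0)
    },
    predict_prob = function(fit, X) {
      as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(X),
                                                          nthread = 1)))
    },
    grid = grid,
    default_params = list(nrounds = 50)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all combinations of named parameter vectors as a list of named lists
param_grid <- function(lst) {
  df <- expand.grid(lst, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Benchmark configuration
#'
#' Bundles the protocol parameters: features, outcome, test fraction, fold
#' count, SMOTE settings, RFE target and the model list. `smote_placement`
#' controls where oversampling happens: `"train_only"` (default; no
#' synthetic point ever derives from a test row) or `"before_split"`
#' (oversample the whole dataset before splitting, replicating protocols
#' that preprocess first — optimistic, since test rows then leak into
#' training neighbourhoods).
#'
#' @param features Character vector of feature columns.
#' @param outcome Binary outcome column.
#' @param test_fraction Held-out test fraction in (0, 0.5].
#' @param folds Cross-validation fold count (>= 2).
#' @param smote_k SMOTE neighbour count.
#' @param smote_placement `"train_only"` or `"before_split"`.
#' @param rfe_target Feature count after recursive feature elimination;
#'   `NULL` skips RFE.
#' @param models Named list of model specs (see [model_specs]).
#' @param seed Master seed; all sub-seeds derive from it.
#' @return A `vt_benchmark_config` list.
#' @export
benchmark_config <- function(features, outcome = "iss", test_fraction = 0.2,
                             folds = 10, smote_k = 5,
                             smote_placement = c("train_only", "before_split"),
                             rfe_target = NULL,
                             models = list(logistic = model_logistic()),
                             seed = 1) {
  smote_placement <- match.arg(smote_placement)
  stopifnot(test_fraction > 0, test_fraction <= 0.5, folds >= 2,
            smote_k >= 1, length(models) >= 1)
  structure(list(features = features, outcome = outcome,
                 test_fraction = test_fraction, folds = folds,
                 smote_k = smote_k, smote_placement = smote_placement,
                 rfe_target = rfe_target, models = models,
                 seed = as.integer(seed)),
            class = "vt_benchmark_config")
}

#' Read a benchmark configuration from YAML
#'
#' Expects sections `features`, `outcome`, `split` (`test_fraction`), `cv`
#' (`folds`), `smote` (`k`, `placement`), `rfe` (`n_target`), `models`
#' (names from `logistic`, `elastic_net`, `svm`, `random_forest`,
#' `xgboost`, each optionally with a `grid` list) and `seed`.
#'
#' @param path YAML file path.
#' @return A `vt_benchmark_config`.
#' @export
read_benchmark_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ctor <- list(logistic = model_logistic, elastic_net = model_enet,
               svm = model_svm, random_forest = model_rf,
               xgboost = model_xgb)
  models <- purrr::imap(cfg$models %||% list(logistic = NULL), function(m, nm) {
    if (!nm %in% names(ctor)) stop("Unknown model: ", nm, call. = FALSE)
    grid <- if (!is.null(m$grid)) param_grid(m$grid) else NULL
    ctor[[nm]](grid = grid)
  })
  benchmark_config(
    features = cfg$features,
    outcome = cfg$outcome %||% "iss",
    test_fraction = cfg$split$test_fraction %||% 0.2,
    folds = cfg$cv$folds %||% 10,
    smote_k = cfg$smote$k %||% 5,
    smote_placement = cfg$smote$placement %||% "train_only",
    rfe_target = cfg$rfe$n_target,
    models = models,
    seed = cfg$seed %||% 1
  )
}

#' The six-predictor feature preset for ISS modelling
#'
#' Height, distance metric (DM), maximum curvature, aneurysm neck size,
#' hypertension and hyperlipidemia — the compact predictor set for in-stent
#' stenosis used with synthetic cohorts.
#'
#' @return Character vector of column names.
#' @export
iss_predictor_preset <- function() {
  c("height", "DM", "max_curvature", "aneurysm_neck", "hypertension",
    "hyperlipidemia")
}

make_stratified_folds <- function(y, k, seed) {
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  if (min(length(idx0), length(idx1)) < k) {
    stop("Cannot build ", k, "-fold stratified partitions: minority class ",
         "has only ", min(length(idx0), length(idx1)), " members.",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    f1 <- sample(rep_len(seq_len(k), length(idx1)))
    f0 <- sample(rep_len(seq_len(k), length(idx0)))
  })
  folds <- integer(length(y))
  folds[idx1] <- f1
  folds[idx0] <- f0
  folds
}

binary_metrics <- function(prob, y, cutoff = 0.5) {
  pred <- as.integer(prob > cutoff)
  tibble::tibble(
    accuracy = mean(pred == y),
    sensitivity = if (sum(y == 1) > 0) sum(pred == 1 & y == 1) / sum(y == 1) else NA_real_,
    specificity = if (sum(y == 0) > 0) sum(pred == 0 & y == 0) / sum(y == 0) else NA_real_
  )
}

#' Run the model-comparison benchmark
#'
#' Executes the full protocol on a cohort: z-scoring, borderline-SMOTE
#' oversampling, a stratified train/test split, recursive feature
#' elimination, per-model grid search by stratified cross-validation, and
#' final evaluation on the held-out test split. All preprocessing learned
#' from data (z-scores, SMOTE, RFE) is computed on the training side only
#' when `smote_placement = "train_only"`.
#'
#' Reported per model: mean in-fold (training) AUC across CV folds with a
#' t-interval, mean held-out-fold (validation) AUC, and test AUC, accuracy,
#' sensitivity and specificity at probability cutoff 0.5.
#'
#' @param cohort Data frame of patients.
#' @param config A `vt_benchmark_config`.
#' @return An object of class `vt_benchmark`: list with `reports` (one
#'   tibble row per model), `provenance` (seeds, selected features, grid
#'   winners, SMOTE parentage) and `config`.
#' @export
run_benchmark <- function(cohort, config) {
  stopifnot(inherits(config, "vt_benchmark_config"))
  X <- tibble::as_tibble(cohort)[, config$features, drop = FALSE]
  y <- cohort[[config$outcome]]
  stopifnot(all(y %in% c(0, 1)))
  seed <- config$seed
  prov <- list(seed = seed, smote_placement = config$smote_placement)

  if (config$smote_placement == "before_split") {
    Xz <- standardize(X)
    sm <- borderline_smote(Xz, y, k = config$smote_k, seed = seed + 1L)
    Xall <- sm$X
    yall <- sm$y
    prov$smote <- sm$provenance
    test_id <- stratified_test_split(yall, config$test_fraction, seed + 2L)
    Xtr <- Xall[-test_id, , drop = FALSE]; ytr <- yall[-test_id]
    Xte <- Xall[test_id, , drop = FALSE]; yte <- yall[test_id]
  } else {
    test_id <- stratified_test_split(y, config$test_fraction, seed + 2L)
    ztr <- standardize(X[-test_id, , drop = FALSE])
    tr <- attr(ztr, "transform")
    sm <- borderline_smote(ztr, y[-test_id], k = config$smote_k,
                           seed = seed + 1L)
    Xtr <- sm$X; ytr <- sm$y
    prov$smote <- sm$provenance
    Xte <- apply_standardize(tr, X[test_id, , drop = FALSE])
    yte <- y[test_id]
  }
  prov$test_rows <- test_id

  feats <- names(Xtr)
  if (!is.null(config$rfe_target) && config$rfe_target < length(feats)) {
    feats <- rfe(Xtr, ytr, config$rfe_target, model = model_logistic(),
                 seed = seed + 3L)
  }
  prov$selected_features <- feats
  Xtr <- Xtr[, feats, drop = FALSE]
  Xte <- Xte[, feats, drop = FALSE]

  folds <- make_stratified_folds(ytr, config$folds, seed + 4L)
  if (any(vapply(seq_len(config$folds), function(f) {
    length(unique(ytr[folds == f])) < 2
  }, logical(1)))) {
    stop("A CV fold has a single outcome class even under stratification.",
         call. = FALSE)
  }

  reports <- purrr::imap_dfr(config$models, function(spec, nm) {
    run_one_model(spec, nm, Xtr, ytr, Xte, yte, folds, config, seed)
  })
  prov$winners <- stats::setNames(reports$winner_params, reports$model)
  reports$winner_params <- NULL
  structure(list(reports = reports, provenance = prov, config = config),
            class = "vt_benchmark")
}

stratified_test_split <- function(y, fraction, seed) {
  withr::with_seed(as.integer(seed), {
    id1 <- which(y == 1)
    id0 <- which(y == 0)
    sort(c(sample(id1, max(1L, round(fraction * length(id1)))),
           sample(id0, max(1L, round(fraction * length(id0))))))
  })
}

run_one_model <- function(spec, nm, Xtr, ytr, Xte, yte, folds, config, seed) {
  k <- config$folds
  grid <- spec$grid
  grid_scores <- vapply(seq_along(grid), function(g) {
    params <- grid[[g]]
    mean(vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- withr::with_seed(seed + 100L * g + f,
                              spec$fit(Xtr[tr, , drop = FALSE], ytr[tr], params))
      roc_evaluate(spec$predict_prob(fit, Xtr[!tr, , drop = FALSE]),
                   ytr[!tr])$auc
    }, numeric(1)))
  }, numeric(1))
  best_g <- which.max(grid_scores)
  params <- grid[[best_g]]

  fold_train_auc <- numeric(k)
  fold_val_auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- withr::with_seed(seed + 100L * best_g + f,
                            spec$fit(Xtr[tr, , drop = FALSE], ytr[tr], params))
    fold_train_auc[f] <- roc_evaluate(
      spec$predict_prob(fit, Xtr[tr, , drop = FALSE]), ytr[tr])$auc
    fold_val_auc[f] <- roc_evaluate(
      spec$predict_prob(fit, Xtr[!tr, , drop = FALSE]), ytr[!tr])$auc
  }
  ci <- t_interval(fold_train_auc)

  final <- withr::with_seed(seed + 7L, spec$fit(Xtr, ytr, params))
  prob_te <- spec$predict_prob(final, Xte)
  test_auc <- roc_evaluate(prob_te, yte)$auc
  mets <- binary_metrics(prob_te, yte)
  tibble::tibble(
    model = nm,
    cv_auc_mean = mean(fold_train_auc),
    cv_auc_lo = ci[1], cv_auc_hi = ci[2],
    val_auc = mean(fold_val_auc),
    test_auc = test_auc,
    accuracy = mets$accuracy,
    sensitivity = mets$sensitivity,
    specificity = mets$specificity,
    winner_params = list(params)
  )
}

t_interval <- function(x, level = 0.95) {
  m <- mean(x)
  se <- stats::sd(x) / sqrt(length(x))
  q <- stats::qt(1 - (1 - level) / 2, df = length(x) - 1)
  c(max(0, m - q * se), min(1, m + q * se))
}

#' @export
print.vt_benchmark <- function(x, ...) {
  cat("<vt_benchmark>", nrow(x$reports), "models;",
      length(x$provenance$selected_features), "features:",
      paste(x$provenance$selected_features, collapse = ", "), "\n")
  print(x$reports)
  invisible(x)
}

#' @rdname run_benchmark
#' @param x,object A `vt_benchmark`.
#' @param ... Unused.
#' @method tidy vt_benchmark
#' @export
tidy.vt_benchmark <- function(x, ...) x$reports

#' @rdname run_benchmark
#' @method glance vt_benchmark
#' @export
glance.vt_benchmark <- function(x, ...) {
  best <- x$reports[which.max(x$reports$test_auc), ]
  tibble::tibble(n_models = nrow(x$reports), best_model = best$model,
                 best_test_auc = best$test_auc,
                 n_features = length(x$provenance$selected_features))
}

#' @rdname run_benchmark
#' @method autoplot vt_benchmark
#' @export
autoplot.vt_benchmark <- function(object, ...) {
  long <- tidyr::pivot_longer(object$reports,
                              c("cv_auc_mean", "val_auc", "test_auc"),
                              names_to = "stage", values_to = "auc")
  long$stage <- factor(long$stage, c("cv_auc_mean", "val_auc", "test_auc"),
                       c("CV (training)", "CV (validation)", "test"))
  ggplot2::ggplot(long, ggplot2::aes(.data$model, .data$auc,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "AUC-ROC", fill = NULL)
}

#' Write benchmark outputs
#'
#' One CSV row per model plus a JSON provenance record (seeds, selected
#' features, grid winners).
#'
#' @param benchmark A `vt_benchmark`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(benchmark$reports),
                   file.path(dir, "model_reports.csv"), row.names = FALSE)
  prov <- benchmark$provenance
  prov$smote <- as.list(prov$smote)
  writeLines(yaml::as.yaml(prov), file.path(dir, "provenance.yaml"))
  invisible(dir)
}
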