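#' Univariate screening of cohort variables against a binary outcome
#'
#' Runs the conventional first-stage association screen: a two-sided
#' pooled-variance t-test for continuous variables and a Pearson chi-square
#' test (without continuity correction) for binary variables, switching to
#' Fisher's exact test when any expected cell count is below 5. Variables
#' with p below `screen_p` are flagged as candidates for the multivariable
#' model.
#'
#' Variable type is auto-detected (a numeric column with only values 0/1 is
#' binary) unless given explicitly. A constant variable yields p = 1 with a
#' warning.
#'
#' @param cohort Data frame, one row per patient.
#' @param outcome Name of the binary outcome column (e.g. `"iss"` or
#'   `"co"`).
#' @param variables Character vector of columns to screen; default all
#'   except the outcome columns `iss`/`co`.
#' @param screen_p Screening threshold; conventionally 0.1.
#' @param welch Use Welch's t-test instead of pooled variance.
#' @return A tibble with one row per variable: `variable`, `type`, `test`,
#'   group summaries (`mean_0`, `sd_0`, `mean_1`, `sd_1` for continuous;
#'   `count_0`, `count_1` exposed counts for binary), `p_value` and
#'   `candidate` (p < `screen_p`).
#' @examples
#' cohort <- make_cohort(n = 62, seed = 1)
#' univariate_screen(cohort, "iss") |> dplyr::filter(candidate)
#' @export
univariate_screen <- function(cohort, outcome = "iss", variables = NULL,
                              screen_p = 0.1, welch = FALSE) {
  if (!outcome %in% names(cohort)) {
    stop("Outcome column `", outcome, "` not found.", call. = FALSE)
  }
  y <- cohort[[outcome]]
  if (!all(y %in% c(0, 1))) stop("Outcome must be binary 0/1.", call. = FALSE)
  if (is.null(variables)) {
    variables <- setdiff(names(cohort), c("iss", "co"))
  }
  purrr::map_dfr(variables, function(v) {
    x <- cohort[[v]]
    binary <- all(x %in% c(0, 1))
    if (stats::var(x) == 0 || length(unique(x)) == 1) {
      warning("Variable `", v, "` is constant; p set to 1.", call. = FALSE)
      return(tibble::tibble(variable = v,
                            type = if (binary) "binary" else "continuous",
                            test = "none", mean_0 = mean(x[y == 0]),
                            sd_0 = 0, mean_1 = mean(x[y == 1]), sd_1 = 0,
                            count_0 = NA_integer_, count_1 = NA_integer_,
                            p_value = 1))
    }
    if (binary) {
      tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        test <- "fisher"
        p <- stats::fisher.test(tab)$p.value
      } else {
        test <- "chi-square"
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
      }
      tibble::tibble(variable = v, type = "binary", test = test,
                     mean_0 = NA_real_, sd_0 = NA_real_, mean_1 = NA_real_,
                     sd_1 = NA_real_, count_0 = sum(x == 1 & y == 0),
                     count_1 = sum(x == 1 & y == 1), p_value = p)
    } else {
      p <- tryCatch(stats::t.test(x ~ y, var.equal = !welch)$p.value,
                    error = function(e) {
                      # constant within both groups: p reflects the mean gap
                      if (mean(x[y == 1]) == mean(x[y == 0])) 1 else 0
                    })
      tibble::tibble(variable = v, type = "continuous",
                     test = if (welch) "welch-t" else "t-test",
                     mean_0 = mean(x[y == 0]), sd_0 = stats::sd(x[y == 0]),
                     mean_1 = mean(x[y == 1]), sd_1 = stats::sd(x[y == 1]),
                     count_0 = NA_integer_, count_1 = NA_integer_,
                     p_value = p)
    }
  }) |>
    dplyr::mutate(candidate = .data$p_value < screen_p)
}

#' Drop collinear candidate predictors
#'
#' Scans candidate pairs in deterministic (given) order and drops one member
#' of every pair with absolute Pearson correlation above `threshold`,
#' keeping the member with the smaller univariate p-value (ties keep the
#' earlier column). With a chain of mutually collinear features exactly one
#' survives.
#'
#' @param cohort Data frame of patients.
#' @param candidates Character vector of candidate predictor columns
#'   (>= 2).
#' @param p_values Optional named numeric vector of univariate p-values used
#'   to pick which member of a collinear pair to keep; default keeps the
#'   earlier column.
#' @param threshold Absolute correlation above which a pair is collinear.
#' @return Character vector of retained columns, in input order.
#' @export
collinearity_filter <- function(cohort, candidates, p_values = NULL,
                                threshold = 0.9) {
  if (length(candidates) < 2) return(candidates)
  keep <- candidates
  i <- 1L
  while (i < length(keep)) {
    j <- i + 1L
    while (j <= length(keep)) {
      r <- suppressWarnings(stats::cor(cohort[[keep[i]]], cohort[[keep[j]]]))
      if (is.finite(r) && abs(r) > threshold) {
        pi_ <- if (!is.null(p_values)) p_values[[keep[i]]] else 0
        pj_ <- if (!is.null(p_values)) p_values[[keep[j]]] else 1
        drop <- if (pj_ < pi_) i else j
        keep <- keep[-drop]
        if (drop == i) {
          j <- i + 1L
        }
      } else {
        j <- j + 1L
      }
    }
    i <- i + 1L
  }
  keep
}

#' Multivariable binary logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit of a binary outcome on the retained
#' predictors, reported per variable as coefficient, odds ratio, Wald 95%
#' confidence interval on the OR scale, and p-value. Perfect separation is
#' detected (fitted probabilities collapsing to 0/1) and reported as an
#' error naming the separating variable.
#'
#' @param cohort Data frame of patients.
#' @param predictors Character vector of predictor columns.
#' @param outcome Binary outcome column name.
#' @param conf_level Confidence level for the Wald intervals.
#' @return A tibble of class `vt_logistic` with one row per predictor (the
#'   intercept row included, named `(Intercept)`): `variable`, `estimate`
#'   (log-odds), `std_error`, `odds_ratio`, `conf_low`, `conf_high`,
#'   `p_value`. The fitted `glm` is attached as attribute `fit`.
#' @examples
#' cohort <- make_cohort(n = 200, seed = 2)
#' fit_logistic(cohort, c("max_curvature", "DM", "hypertension"), "iss")
#' @export
fit_logistic <- function(cohort, predictors, outcome = "iss",
                         conf_level = 0.95) {
  y <- cohort[[outcome]]
  if (length(unique(y)) < 2) {
    stop("Outcome has a single class; cannot fit.", call. = FALSE)
  }
  if (nrow(cohort) <= 5 * length(predictors)) {
    warning("Fewer than 5 events per predictor candidate; estimates may be ",
            "unstable.", call. = FALSE)
  }
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- suppressWarnings(stats::glm(fml, data = cohort, family = stats::binomial()))
  probs <- stats::fitted(fit)
  if (any(probs < 1e-10) || any(probs > 1 - 1e-10)) {
    # extreme fitted probabilities are only fatal when a predictor actually
    # separates the classes (heavy-tailed predictors can saturate legitimately)
    sep <- separating_variable(cohort, predictors, y)
    if (!is.na(sep)) {
      stop("Perfect separation detected (variable `", sep, "`).",
           call. = FALSE)
    }
    if (!fit$converged) {
      stop("Perfect separation detected (fit did not converge).",
           call. = FALSE)
    }
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    variable = rownames(sm),
    estimate = unname(sm[, 1]),
    std_error = unname(sm[, 2]),
    odds_ratio = exp(unname(sm[, 1])),
    conf_low = exp(unname(sm[, 1] - z * sm[, 2])),
    conf_high = exp(unname(sm[, 1] + z * sm[, 2])),
    p_value = unname(sm[, 4])
  )
  class(out) <- c("vt_logistic", class(out))
  attr(out, "fit") <- fit
  attr(out, "converged") <- fit$converged
  out
}

separating_variable <- function(cohort, predictors, y) {
  for (v in predictors) {
    x <- cohort[[v]]
    if (max(x[y == 0]) <= min(x[y == 1]) || max(x[y == 1]) <= min(x[y == 0])) {
      return(v)
    }
  }
  NA_character_
}

#' @rdname fit_logistic
#' @param x A `vt_logistic`.
#' @param ... Unused.
#' @method glance vt_logistic
#' @export
glance.vt_logistic <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble::tibble(n = length(fit$y), null_deviance = fit$null.deviance,
                 deviance = fit$deviance, aic = fit$aic,
                 converged = attr(x, "converged"))
}

#' ROC evaluation of a risk score
#'
#' Computes the area under the ROC curve by the rank (Mann-Whitney)
#' statistic with midrank tie handling — equivalent to the trapezoidal area
#' over all thresholds — and picks the operating cutoff maximizing Youden's
#' J = sensitivity + specificity - 1.
#'
#' @param scores Numeric risk scores (higher = more likely positive).
#' @param labels Binary 0/1 outcome labels; both classes must be present.
#' @return An object of class `vt_roc`: list with `auc`, `cutoff`,
#'   `sensitivity`, `specificity` at the cutoff, and `curve` (tibble of
#'   threshold, sensitivity, specificity, youden_j).
#' @examples
#' roc <- roc_evaluate(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' roc$auc # 0.75
#' @export
roc_evaluate <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    stop("Labels must be binary 0/1 with both classes present.",
         call. = FALSE)
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores))
  # candidate cutoffs midway between consecutive distinct scores, plus ends
  cuts <- c(min(thr) - 1, if (length(thr) > 1) (thr[-1] + thr[-length(thr)]) / 2,
            max(thr) + 1)
  curve <- purrr::map_dfr(cuts, function(ct) {
    pred <- as.integer(scores > ct)
    tibble::tibble(threshold = ct,
                   sensitivity = sum(pred == 1 & labels == 1) / n1,
                   specificity = sum(pred == 0 & labels == 0) / n0)
  }) |>
    dplyr::mutate(youden_j = .data$sensitivity + .data$specificity - 1)
  bestrow <- which.max(curve$youden_j)
  structure(list(auc = auc, cutoff = curve$threshold[bestrow],
                 sensitivity = curve$sensitivity[bestrow],
                 specificity = curve$specificity[bestrow], curve = curve),
            class = "vt_roc")
}

#' @export
print.vt_roc <- function(x, ...) {
  cat(sprintf("<vt_roc> AUC %.3f; cutoff %.4g (sens %.2f, spec %.2f)\n",
              x$auc, x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' @rdname roc_evaluate
#' @param x,object A `vt_roc`.
#' @param ... Unused.
#' @method tidy vt_roc
#' @export
tidy.vt_roc <- function(x, ...) x$curve

#' @rdname roc_evaluate
#' @method glance vt_roc
#' @export
glance.vt_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, cutoff = x$cutoff,
                 sensitivity = x$sensitivity, specificity = x$specificity)
}

#' @rdname roc_evaluate
#' @method autoplot vt_roc
#' @export
autoplot.vt_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", object$auc))
}

#' Full inference stage on a cohort
#'
#' Chains the screening, collinearity-filter and logistic stages: screens
#' all variables, retains candidates at `screen_p`, collapses collinear
#' pairs, optionally force-includes clinically relevant variables, fits the
#' multivariable logistic model and evaluates its ROC.
#'
#' @inheritParams univariate_screen
#' @param force_include Variables always entered into the multivariable
#'   model regardless of screening.
#' @param collinearity_threshold Passed to [collinearity_filter()].
#' @return A list with `screen` (tibble), `retained` (character),
#'   `model` (`vt_logistic` tibble) and `roc` (`vt_roc`).
#' @export
run_inference <- function(cohort, outcome = "iss", screen_p = 0.1,
                          force_include = character(),
                          collinearity_threshold = 0.9) {
  screen <- univariate_screen(cohort, outcome, screen_p = screen_p)
  cand <- union(screen$variable[screen$candidate], force_include)
  if (length(cand) == 0) {
    stop("No variable passed the univariate screen.", call. = FALSE)
  }
  pv <- stats::setNames(screen$p_value, screen$variable)
  retained <- collinearity_filter(cohort, cand, p_values = pv,
                                  threshold = collinearity_threshold)
  model <- fit_logistic(cohort, retained, outcome)
  fitvals <- stats::predict(attr(model, "fit"), type = "response")
  roc <- roc_evaluate(fitvals, cohort[[outcome]])
  list(screen = screen, retained = retained, model = model, roc = roc)
}
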