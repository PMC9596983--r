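#' Generate a synthetic patient cohort with known outcome structure
#'
#' Draws a per-patient table emulating a flow-diverter treatment cohort:
#' demographics, comorbidities, aneurysm and procedure characteristics, and
#' the vessel-tortuosity metrics of the stented parent-artery segment,
#' together with binary complete-occlusion (`co`) and in-stent-stenosis
#' (`iss`) outcomes.
#'
#' Continuous features are drawn from two-parameter families moment-matched
#' to the target mean and SD: lognormal for strictly positive, right-skewed
#' metrics (maximum curvature has SD larger than its mean, implying strong
#' skew), logit-normal for the distance metric DM (bounded in (0, 1)), and
#' normal otherwise. `range_curvature` duplicates `max_curvature` exactly
#' (their summaries coincide in real vessel data because the minimum
#' curvature of a tortuous segment is essentially 0), providing a built-in
#' collinear pair; `l` is derived as `DM * L`.
#'
#' The ISS outcome is drawn from a logistic model
#' `logit P(iss = 1) = alpha + sum(coef * feature)` whose intercept `alpha`
#' is calibrated by root-finding on the realized features so that the
#' expected prevalence equals `iss_prevalence`. Default coefficients (per
#' 1-unit change, natural scale) encode the established effect directions:
#' risk increases with maximum curvature and hypertension and decreases with
#' DM. The `co` outcome is drawn independently of all features at rate
#' `co_prevalence` (occlusion shows no tortuosity association).
#'
#' @param n Number of patients (>= 20).
#' @param iss_prevalence Target expected ISS prevalence in (0, 1).
#' @param co_prevalence Complete-occlusion rate in (0, 1).
#' @param coef Named numeric vector of logistic coefficients for the ISS
#'   model; names must be generated feature columns. Defaults:
#'   `max_curvature` +0.0807 (odds ratio 1.084 per unit), `DM` -4.61 (odds
#'   ratio 0.01 per unit), `hypertension` +0.7.
#' @param seed Integer seed; the same seed reproduces the identical table.
#' @return A tibble with one row per patient: continuous features (`age`,
#'   `bmi`, `height`, `aneurysm_neck`, `max_diameter`,
#'   `parent_artery_diameter`, `mean_curvature`, `max_curvature`,
#'   `range_curvature`, `mean_torsion`, `max_torsion`, `range_torsion`,
#'   `DM`, `L`, `l`), binary features (`female`, `hypertension`, `diabetes`,
#'   `hyperlipidemia`, `allergy`, `smoking`, `alcohol`, `symptomatic`,
#'   `ruptured`, `parent_stenosis`, `ped_coiling`, `ped_flex`,
#'   `multiple_ped`, `balloon`), and outcomes `iss`, `co` (0/1). The
#'   calibrated intercept and the coefficient vector are attached as
#'   attributes `alpha` and `coef`.
#' @examples
#' cohort <- make_cohort(n = 62, iss_prevalence = 0.355, seed = 1)
#' mean(cohort$iss)
#' @export
make_cohort <- function(n = 62, iss_prevalence = 0.355, co_prevalence = 0.79,
                        coef = NULL, seed = 1) {
  if (n < 20) stop("`n` must be at least 20 for downstream inference.",
                   call. = FALSE)
  if (iss_prevalence <= 0 || iss_prevalence >= 1) {
    stop("`iss_prevalence` must be in (0, 1).", call. = FALSE)
  }
  if (is.null(coef)) {
    coef <- c(max_curvature = 0.0807, DM = -4.61, hypertension = 0.7)
  }

  withr::with_seed(as.integer(seed), {
    rlnorm2 <- function(n, m, s) {
      sigma2 <- log(1 + (s / m)^2)
      stats::rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
    }
    dm_par <- logitnorm_params(0.5, 0.2)
    max_torsion <- stats::rnorm(n, 45.4, 16.2)
    min_torsion <- abs(stats::rnorm(n, 0, 0.15))
    L <- rlnorm2(n, 23.9, 9.5)
    DM <- stats::plogis(stats::rnorm(n, dm_par[1], dm_par[2]))
    max_curvature <- rlnorm2(n, 5.3, 8.9)
    tab <- tibble::tibble(
      age = stats::rnorm(n, 54.2, 9.2),
      bmi = stats::rnorm(n, 25.1, 3.7),
      height = stats::rnorm(n, 162, 7),
      aneurysm_neck = rlnorm2(n, 6.2, 2.8),
      max_diameter = rlnorm2(n, 9.4, 4.7),
      parent_artery_diameter = stats::rnorm(n, 3.8, 0.7),
      mean_curvature = rlnorm2(n, 0.6, 0.5),
      max_curvature = max_curvature,
      range_curvature = max_curvature,
      mean_torsion = stats::rnorm(n, 12.4, 4.2),
      max_torsion = max_torsion,
      range_torsion = max_torsion - min_torsion,
      DM = DM,
      L = L,
      l = DM * L,
      female = stats::rbinom(n, 1, 0.758),
      hypertension = stats::rbinom(n, 1, 0.435),
      diabetes = stats::rbinom(n, 1, 0.081),
      hyperlipidemia = stats::rbinom(n, 1, 0.387),
      allergy = stats::rbinom(n, 1, 0.113),
      smoking = stats::rbinom(n, 1, 0.210),
      alcohol = stats::rbinom(n, 1, 0.145),
      symptomatic = stats::rbinom(n, 1, 0.581),
      ruptured = stats::rbinom(n, 1, 0.048),
      parent_stenosis = stats::rbinom(n, 1, 0.048),
      ped_coiling = stats::rbinom(n, 1, 0.484),
      ped_flex = stats::rbinom(n, 1, 0.597),
      multiple_ped = stats::rbinom(n, 1, 0.129),
      balloon = stats::rbinom(n, 1, 0.226)
    )

    bad <- setdiff(names(coef), names(tab))
    if (length(bad) > 0) {
      stop("Coefficient(s) on features not generated: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }

    eta <- as.matrix(tab[, names(coef), drop = FALSE]) %*% coef
    # calibrate the intercept so the expected prevalence over the realized
    # features equals the request
    alpha <- stats::uniroot(
      function(a) mean(stats::plogis(a + eta)) - iss_prevalence,
      lower = -50, upper = 50, tol = 1e-10)$root
    tab$iss <- stats::rbinom(n, 1, stats::plogis(alpha + eta))
    tab$co <- stats::rbinom(n, 1, co_prevalence)
    attr(tab, "alpha") <- alpha
    attr(tab, "coef") <- coef
    tab
  })
}

.vt_cache <- new.env(parent = emptyenv())

# (mu, sigma) of the logit-normal with the given mean and SD, found by
# moment-matching with numerical quadrature; memoized (the search is far
# more expensive than one cohort draw)
logitnorm_params <- function(m, s) {
  key <- paste(m, s)
  if (!is.null(.vt_cache[[key]])) return(.vt_cache[[key]])
  .vt_cache[[key]] <- logitnorm_params_impl(m, s)
  .vt_cache[[key]]
}

logitnorm_params_impl <- function(m, s) {
  moments <- function(mu, sigma) {
    m1 <- stats::integrate(function(x) stats::plogis(x) *
                             stats::dnorm(x, mu, sigma), -Inf, Inf,
                           rel.tol = 1e-10)$value
    m2 <- stats::integrate(function(x) stats::plogis(x)^2 *
                             stats::dnorm(x, mu, sigma), -Inf, Inf,
                           rel.tol = 1e-10)$value
    c(m1, sqrt(max(m2 - m1^2, 0)))
  }
  obj <- function(p) {
    mm <- moments(p[1], exp(p[2]))
    (mm[1] - m)^2 + (mm[2] - s)^2
  }
  p <- stats::optim(c(stats::qlogis(m), log(1)), obj,
                    control = list(reltol = 1e-14))$par
  c(mu = p[1], sigma = exp(p[2]))
}
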