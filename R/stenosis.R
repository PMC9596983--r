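#' Percent in-stent stenosis from vessel and stent diameters
#'
#' The loss rate of the parent artery diameter at follow-up is
#' `100 * (1 - vessel_d / stent_d)`, where `vessel_d` is the narrowest
#' in-stent lumen diameter and `stent_d` the stent diameter at the same
#' position. A vessel diameter larger than the stent diameter yields a
#' negative percentage; it is returned as-is (flagged by the caller if
#' desired), never clamped.
#'
#' @param vessel_d Narrowest in-stent vessel diameter (mm), > 0. Vectorized.
#' @param stent_d Stent diameter at the same position (mm), > 0. Vectorized.
#' @return Percent stenosis (numeric, same length as the inputs).
#' @examples
#' stenosis_percent(3, 4) # 25
#' @export
stenosis_percent <- function(vessel_d, stent_d) {
  if (any(!is.finite(vessel_d)) || any(!is.finite(stent_d)) ||
      any(vessel_d <= 0) || any(stent_d <= 0)) {
    stop("Diameters must be positive and finite.", call. = FALSE)
  }
  100 * (1 - vessel_d / stent_d)
}

#' Classify in-stent stenosis severity
#'
#' ISS is vessel narrowing of strictly more than 25%; narrowing of strictly
#' more than 50% is graded severe. Severe cases still count as ISS in the
#' binary outcome (`iss_indicator()`), i.e. severe is a subset of ISS.
#' Exactly 25% is classed `none` (the definition is a strict inequality).
#'
#' @param percent Percent stenosis (vectorized, finite).
#' @return `classify_iss()`: factor with levels `none`, `ISS`, `severe`.
#'   `iss_indicator()`: integer 0/1, equal to `percent > 25`.
#' @examples
#' classify_iss(c(25, 25.01, 55)) # none, ISS, severe
#' @export
classify_iss <- function(percent) {
  if (any(!is.finite(percent))) stop("Percent must be finite.", call. = FALSE)
  factor(ifelse(percent > 50, "severe", ifelse(percent > 25, "ISS", "none")),
         levels = c("none", "ISS", "severe"))
}

#' @rdname classify_iss
#' @export
iss_indicator <- function(percent) {
  as.integer(classify_iss(percent) != "none")
}

#' Tabulate stenosis measurements
#'
#' Data-frame-first wrapper: takes a table with columns `vessel_diameter_mm`
#' and `stent_diameter_mm` and appends `percent_stenosis`, `iss_class` and
#' the binary `iss` column.
#'
#' @param data Data frame with `vessel_diameter_mm` and `stent_diameter_mm`.
#' @return The input as a tibble with `percent_stenosis`, `iss_class`, `iss`
#'   appended.
#' @examples
#' tibble::tibble(vessel_diameter_mm = c(4, 3, 1.8),
#'                stent_diameter_mm = 4) |>
#'   measure_stenosis()
#' @export
measure_stenosis <- function(data) {
  if (!all(c("vessel_diameter_mm", "stent_diameter_mm") %in% names(data))) {
    stop("Need columns `vessel_diameter_mm` and `stent_diameter_mm`.",
         call. = FALSE)
  }
  data |>
    tibble::as_tibble() |>
    dplyr::mutate(
      percent_stenosis = stenosis_percent(.data$vessel_diameter_mm,
                                          .data$stent_diameter_mm),
      iss_class = classify_iss(.data$percent_stenosis),
      iss = iss_indicator(.data$percent_stenosis)
    )
}
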