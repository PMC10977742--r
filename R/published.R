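#' Reference parameter estimates for the French population
#'
#' Point estimates of the baseline transition intensities and hazard ratios
#' obtained from the French national health-survey panel (ESPS, nine biennial
#' waves 1998-2014, interval-censored observations from age 3 to the survey
#' age). These are the package's default generating values for synthetic data
#' and its default inputs for projection and lifetime-risk examples.
#'
#' Baseline intensities (per person-year, reference = men aged >= 50 before
#' 1995): NW->OW 0.0480; shared progression 0.0125; OW->NW 0.0271; shared
#' regression 0.0491; diabetes onset 0.0009 (NW), 0.0033 (OW), 0.0081 (OB1),
#' 0.0156 (OB2/OB3). The published 95% confidence intervals are attached as
#' attribute `"ci"` (a data frame on the natural scale).
#'
#' @return A [make_params()] object.
#' @examples
#' p <- default_params()
#' p$baseline["nw_ow"]
#' attr(p, "ci")[1:3, ]
#' @export
default_params <- function() {
  p <- make_params(
    baseline = c(nw_ow = 0.0480, prog = 0.0125, ow_nw = 0.0271, regr = 0.0491,
                 dm_nw = 0.0009, dm_ow = 0.0033, dm_ob1 = 0.0081,
                 dm_ob23 = 0.0156),
    hr = list(
      nw_ow = c(female = 0.72, p1995_2004 = 1.11, p2005_2014 = 1.43,
                age_lt25 = 0.24, age_25_49 = 0.87),
      prog = c(female = 2.00, p1995_2004 = 1.92, p2005_2014 = 2.38,
               age_lt25 = 1.48, age_25_49 = 1.36),
      regr = c(female = 1.69, p1995_2004 = 1.20, p2005_2014 = 1.25,
               age_lt25 = 0.67, age_25_49 = 1.17),
      dm = c(female = 0.81, p1995_2004 = 2.89, p2005_2014 = 3.12,
             age_lt50 = 0.24)
    )
  )
  ci <- data.frame(
    param = param_names(),
    estimate = exp(unname(pack_params(p))),
    lower = c(0.0448, 0.0115, 0.0244, 0.0436, 0.0008, 0.0031, 0.0073, 0.0139,
              0.70, 1.06, 1.35, 0.22, 0.82,
              1.93, 1.81, 2.22, 1.37, 1.28,
              1.60, 1.10, 1.13, 0.52, 1.07,
              0.77, 2.66, 2.84, 0.22),
    upper = c(0.0515, 0.0135, 0.0301, 0.0552, 0.0010, 0.0036, 0.0090, 0.0176,
              0.74, 1.16, 1.52, 0.26, 0.92,
              2.07, 2.02, 2.54, 1.61, 1.44,
              1.79, 1.31, 1.39, 0.87, 1.27,
              0.85, 3.14, 3.44, 0.25),
    stringsAsFactors = FALSE
  )
  attr(p, "ci") <- ci
  p
}

#' Published reference prevalence projections (2022-2027)
#'
#' Projected prevalences (percent of the adult population) of overweight,
#' obesity classes I-III, overall obesity and type 2 diabetes under the
#' status-quo continuation and three intervention scenarios, as reported for
#' the French population. Scenario 1 is a 22% decrease in the intensity of
#' moving up one BMI category from 2022; scenario 2 a 33% increase in the
#' intensity of moving down; scenario 3 combines both. These published values
#' support worked-example arithmetic (relative changes, early-indicator
#' checks); they are not produced by the synthetic pipeline.
#'
#' @return Data frame with columns `scenario` (`status_quo`, `scenario1`,
#'   `scenario2`, `scenario3`), `indicator` (`overweight`, `obesity1`,
#'   `obesity2`, `obesity3`, `obesity_total`, `diabetes`), `year` and
#'   `prevalence` (percent).
#' @seealso [relative_change()], [reference_lifetime_risk()]
#' @export
reference_projection <- function() {
  f <- system.file("extdata", "reference_projection.csv", package = "bmidiab",
                   mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Published lifetime risks of type 2 diabetes for 25-year-olds in 2022
#'
#' Lifetime cumulative risk (percent) of developing type 2 diabetes for
#' cohorts of 25-year-old men and women in 2022, starting from the projected
#' 2022 BMI-category distribution at that age, under the status quo and the
#' three intervention scenarios.
#'
#' @return Data frame with columns `sex` (`M`/`F`), `scenario` and `risk`
#'   (percent).
#' @export
reference_lifetime_risk <- function() {
  f <- system.file("extdata", "reference_lifetime_risk.csv",
                   package = "bmidiab", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Projected 2022 BMI-category distribution of 25-year-olds
#'
#' The model-projected distribution over BMI categories of 25-year-old
#' individuals in 2022, used as the starting mixture for population lifetime
#' risk.
#'
#' @param sex `"M"` or `"F"`.
#' @return Named numeric vector over [BMI_CLASSES] summing to 1 (the printed
#'   men's shares total 100.1% through rounding; they are renormalized).
#' @export
reference_start_distribution <- function(sex = c("M", "F")) {
  sex <- match.arg(sex)
  d <- if (sex == "M") {
    c(NW = 0.732, OW = 0.179, OB1 = 0.066, OB2 = 0.019, OB3 = 0.005)
  } else {
    c(NW = 0.810, OW = 0.097, OB1 = 0.054, OB2 = 0.026, OB3 = 0.013)
  }
  d / sum(d)
}

#' Relative change between two values
#'
#' Percent change of `to` relative to `from`, the quantity used for
#' statements such as "5.2% relative increase in obesity prevalence between
#' 2022 and 2027" or "13.3% decrease of obesity III at two years".
#'
#' @param from,to Numeric vectors (recycled).
#' @return `100 * (to - from) / from`.
#' @examples
#' relative_change(17.3, 18.2)
#' @export
relative_change <- function(from, to) 100 * (to - from) / from
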