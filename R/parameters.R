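#' Model parameter set
#'
#' A parameter set holds 8 baseline transition intensities (per person-year)
#' and 19 hazard ratios, the parsimonious structure used for the French
#' survey analysis:
#'
#' * `nw_ow`: normal weight to overweight;
#' * `prog`: shared progression intensity OW->OB1 = OB1->OB2 = OB2->OB3;
#' * `ow_nw`: overweight to normal weight;
#' * `regr`: shared regression intensity OB1->OW = OB2->OB1 = OB3->OB2;
#' * `dm_nw`, `dm_ow`, `dm_ob1`, `dm_ob23`: type 2 diabetes onset by BMI
#'   category (obesity II and III share one rate).
#'
#' Baselines refer to the covariate reference: men, aged 50 and over, before
#' calendar year 1995. Hazard ratios act multiplicatively (proportional
#' hazards) in four groups: `nw_ow`, `prog` and `regr` each carry
#' `female`, `p1995_2004`, `p2005_2014`, `age_lt25`, `age_25_49`; diabetes
#' onset (`dm`) carries `female`, `p1995_2004`, `p2005_2014` and a single
#' `age_lt50` effect shared across BMI categories. All regressions (including
#' OW->NW) share one covariate group. BMI-transition intensities are
#' identical in the diabetic and non-diabetic layers.
#'
#' @param baseline Named numeric vector of the 8 baseline intensities
#'   (non-negative, finite). Names as above.
#' @param hr Named list of hazard-ratio vectors `nw_ow`, `prog`, `regr`
#'   (each with names `female`, `p1995_2004`, `p2005_2014`, `age_lt25`,
#'   `age_25_49`) and `dm` (names `female`, `p1995_2004`, `p2005_2014`,
#'   `age_lt50`). Defaults to all 1 (no covariate effect).
#' @return An object of class `bmidiab_params`.
#' @examples
#' p <- make_params(baseline = c(nw_ow = 0.05, prog = 0.01, ow_nw = 0.03,
#'                               regr = 0.05, dm_nw = 0.001, dm_ow = 0.003,
#'                               dm_ob1 = 0.008, dm_ob23 = 0.015))
#' pack_params(p)[1:4]
#' @export
make_params <- function(baseline, hr = NULL) {
  bn <- c("nw_ow", "prog", "ow_nw", "regr", "dm_nw", "dm_ow", "dm_ob1", "dm_ob23")
  if (!all(bn %in% names(baseline))) {
    stop("baseline must have names: ", paste(bn, collapse = ", "))
  }
  baseline <- as.numeric(baseline[bn])
  names(baseline) <- bn
  if (any(!is.finite(baseline)) || any(baseline < 0)) {
    stop("baseline intensities must be finite and non-negative")
  }
  hn_bmi <- c("female", "p1995_2004", "p2005_2014", "age_lt25", "age_25_49")
  hn_dm <- c("female", "p1995_2004", "p2005_2014", "age_lt50")
  default_hr <- list(
    nw_ow = stats::setNames(rep(1, 5), hn_bmi),
    prog = stats::setNames(rep(1, 5), hn_bmi),
    regr = stats::setNames(rep(1, 5), hn_bmi),
    dm = stats::setNames(rep(1, 4), hn_dm)
  )
  if (is.null(hr)) hr <- list()
  for (g in names(hr)) {
    if (!g %in% names(default_hr)) stop("unknown hazard-ratio group: ", g)
    v <- hr[[g]]
    miss <- setdiff(names(v), names(default_hr[[g]]))
    if (length(miss)) stop("unknown hazard-ratio name(s) in ", g, ": ",
                           paste(miss, collapse = ", "))
    default_hr[[g]][names(v)] <- as.numeric(v)
  }
  hr <- default_hr
  if (any(!is.finite(unlist(hr))) || any(unlist(hr) <= 0)) {
    stop("hazard ratios must be finite and strictly positive")
  }
  structure(list(baseline = baseline, hr = hr), class = "bmidiab_params")
}

param_names <- function() {
  c(paste0("q_", c("nw_ow", "prog", "ow_nw", "regr",
                   "dm_nw", "dm_ow", "dm_ob1", "dm_ob23")),
    paste0("hr_nw_ow_", c("female", "p1995_2004", "p2005_2014", "age_lt25", "age_25_49")),
    paste0("hr_prog_", c("female", "p1995_2004", "p2005_2014", "age_lt25", "age_25_49")),
    paste0("hr_regr_", c("female", "p1995_2004", "p2005_2014", "age_lt25", "age_25_49")),
    paste0("hr_dm_", c("female", "p1995_2004", "p2005_2014", "age_lt50")))
}

#' Pack a parameter set into the free 27-vector (log scale)
#'
#' Estimation works on the unconstrained log scale; `pack_params()` and
#' [unpack_params()] convert between the structured parameter set and the
#' flat vector of 27 free parameters (8 log-intensities, 19 log-hazard
#' ratios) and round-trip exactly.
#'
#' @param params A [make_params()] object with strictly positive baselines.
#' @return Named numeric vector of length 27 (natural logarithms).
#' @export
pack_params <- function(params) {
  stopifnot(inherits(params, "bmidiab_params"))
  if (any(params$baseline <= 0)) {
    stop("cannot pack a parameter set with zero baseline intensities")
  }
  v <- c(log(params$baseline),
         log(params$hr$nw_ow), log(params$hr$prog),
         log(params$hr$regr), log(params$hr$dm))
  # exact round-trip: reuse the original log vector where exp() has not
  # been disturbed (log(exp(x)) alone can be off by one ulp)
  v0 <- attr(params, "logpar")
  if (!is.null(v0) && length(v0) == 27L) {
    same <- abs(v - v0) < 1e-12 * pmax(1, abs(v0))
    v[same] <- v0[same]
  }
  names(v) <- param_names()
  v
}

#' @rdname pack_params
#' @param v Named or unnamed numeric vector of length 27 in the order of
#'   `pack_params()` output.
#' @export
unpack_params <- function(v) {
  stopifnot(length(v) == 27L, all(is.finite(v)))
  e <- exp(as.numeric(v))
  hn_bmi <- c("female", "p1995_2004", "p2005_2014", "age_lt25", "age_25_49")
  p <- make_params(
    baseline = stats::setNames(e[1:8], c("nw_ow", "prog", "ow_nw", "regr",
                                         "dm_nw", "dm_ow", "dm_ob1", "dm_ob23")),
    hr = list(nw_ow = stats::setNames(e[9:13], hn_bmi),
              prog = stats::setNames(e[14:18], hn_bmi),
              regr = stats::setNames(e[19:23], hn_bmi),
              dm = stats::setNames(e[24:27], c("female", "p1995_2004",
                                               "p2005_2014", "age_lt50")))
  )
  attr(p, "logpar") <- as.numeric(v)
  p
}

#' @export
print.bmidiab_params <- function(x, ...) {
  cat("Ten-state BMI / type 2 diabetes model parameters\n")
  cat("Baseline intensities (per person-year; reference: male, >=50, pre-1995):\n")
  print(round(x$baseline, 5))
  cat("Hazard ratios:\n")
  for (g in names(x$hr)) {
    cat(" ", g, ": ", paste(names(x$hr[[g]]), round(x$hr[[g]], 3),
                            sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
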