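bmi_hr_factor <- function(hr, profile) {
  f <- 1
  if (profile$sex == "F") f <- f * hr[["female"]]
  if (profile$period == "p1995_2004") f <- f * hr[["p1995_2004"]]
  if (profile$period == "p2005_2014") f <- f * hr[["p2005_2014"]]
  if (profile$age_class == "age_lt25") f <- f * hr[["age_lt25"]]
  if (profile$age_class == "age_25_49") f <- f * hr[["age_25_49"]]
  f
}

dm_hr_factor <- function(hr, profile) {
  f <- 1
  if (profile$sex == "F") f <- f * hr[["female"]]
  if (profile$period == "p1995_2004") f <- f * hr[["p1995_2004"]]
  if (profile$period == "p2005_2014") f <- f * hr[["p2005_2014"]]
  if (profile$dm_age_lt50) f <- f * hr[["age_lt50"]]
  f
}

#' Transition-intensity matrix for a covariate profile
#'
#' Builds the 10x10 generator matrix Q of the continuous-time Markov chain
#' for a fully resolved covariate profile. Each allowed off-diagonal entry is
#' the baseline intensity times the applicable hazard ratios; BMI-transition
#' intensities are identical in the diabetic and non-diabetic layers;
#' diabetes-onset entries are exactly 0 while the corresponding activation
#' flag (`dm_active_nw` for normal weight, `dm_active_owob` otherwise) is
#' off; diagonal entries make every row sum to zero.
#'
#' @param params A [make_params()] parameter set.
#' @param profile A [covariate_profile()].
#' @param config A [model_config()] (unused at present; kept so that
#'   alternative activation rules remain expressible).
#' @return A 10x10 matrix with dimnames [STATE_LABELS] (intensities per
#'   person-year).
#' @examples
#' q <- build_intensity_matrix(default_params(),
#'                             covariate_profile("M", 60, 1990))
#' q["NW", "OW"]   # 0.048: baseline, reference profile
#' @export
build_intensity_matrix <- function(params, profile, config = model_config()) {
  stopifnot(inherits(params, "bmidiab_params"))
  b <- params$baseline
  Q <- matrix(0, 10, 10, dimnames = list(STATE_LABELS, STATE_LABELS))
  up <- c(b[["nw_ow"]], b[["prog"]], b[["prog"]], b[["prog"]]) *
    c(bmi_hr_factor(params$hr$nw_ow, profile),
      rep(bmi_hr_factor(params$hr$prog, profile), 3))
  down <- c(b[["ow_nw"]], b[["regr"]], b[["regr"]], b[["regr"]]) *
    bmi_hr_factor(params$hr$regr, profile)
  for (i in 1:4) {
    Q[i, i + 1] <- up[i];       Q[i + 5, i + 6] <- up[i]
    Q[i + 1, i] <- down[i];     Q[i + 6, i + 5] <- down[i]
  }
  dmf <- dm_hr_factor(params$hr$dm, profile)
  dm <- c(b[["dm_nw"]], b[["dm_ow"]], b[["dm_ob1"]], b[["dm_ob23"]],
          b[["dm_ob23"]]) * dmf
  active <- c(profile$dm_active_nw, rep(profile$dm_active_owob, 4))
  for (i in 1:5) Q[i, i + 5] <- if (active[i]) dm[i] else 0
  diag(Q) <- -rowSums(Q)
  Q
}

# Stack of generator matrices, one per row of profile_grid(): 10 x 10 x nprof.
build_Q_array <- function(params, config = model_config(),
                          grid = profile_grid(config)) {
  arr <- array(0, dim = c(10, 10, nrow(grid)))
  for (r in seq_len(nrow(grid))) {
    prof <- covariate_profile(grid$sex[r], grid$rep_age[r],
                              # a representative year inside the period
                              c(config$period_breaks[1] - 1,
                                config$period_breaks)[grid$period[r]],
                              config)
    arr[, , r] <- build_intensity_matrix(params, prof, config)
  }
  arr
}
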